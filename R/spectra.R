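#' Normalize a peak table
#'
#' Sorts by m/z, merges duplicates closer than 1e-6 Da (summing intensity),
#' and validates intensities. The default MALDI reflector acquisition window
#' is 750-4000 Da; peaks outside `window` are dropped with a warning.
#'
#' @param peaks Data frame with numeric columns `mz` and `intensity`
#'   (intensity defaults to 1 when missing).
#' @param window Length-2 acquisition mass window in Da, or `NULL` to keep
#'   everything.
#' @param source Free-text label stored as the `source` attribute.
#' @return Tibble `mz`, `intensity` with strictly increasing `mz`.
#' @export
as_peaklist <- function(peaks, window = c(750, 4000), source = NA_character_) {
  stopifnot("mz" %in% names(peaks))
  mz <- as.numeric(peaks$mz)
  intensity <- if ("intensity" %in% names(peaks)) {
    as.numeric(peaks$intensity)
  } else {
    rep(1, length(mz))
  }
  if (anyNA(mz)) stop("non-numeric m/z value", call. = FALSE)
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("negative intensity", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (length(mz) > 1L) {
    grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
    mz <- as.numeric(tapply(mz, grp, function(x) x[1]))
    intensity <- as.numeric(tapply(intensity, grp, sum))
  }
  if (!is.null(window)) {
    out_of_window <- mz < window[1] | mz > window[2]
    if (any(out_of_window)) {
      warning(sum(out_of_window), " peak(s) outside acquisition window ",
              window[1], "-", window[2], " Da dropped", call. = FALSE)
      mz <- mz[!out_of_window]
      intensity <- intensity[!out_of_window]
    }
  }
  out <- tibble::tibble(mz = mz, intensity = intensity)
  attr(out, "source") <- source
  attr(out, "window") <- window
  out
}

#' Read a centroided peak list
#'
#' Supports two-column TSV/CSV (`mz`, `intensity`; header optional) and MGF.
#' For MGF, ion lines from all `BEGIN IONS` blocks are pooled into one peak
#' list (MALDI MS1 usage). Output is normalized via [as_peaklist()].
#'
#' @param path Input file.
#' @param dialect `"tsv"`, `"csv"` or `"mgf"`; default guessed from the file
#'   extension.
#' @inheritParams as_peaklist
#' @return Tibble `mz`, `intensity`, sorted and deduplicated.
#' @export
read_peaks <- function(path, dialect = NULL, window = c(750, 4000)) {
  stopifnot(file.exists(path))
  if (is.null(dialect)) {
    dialect <- switch(tolower(tools::file_ext(path)),
                      csv = "csv", mgf = "mgf", "tsv")
  }
  dialect <- match.arg(dialect, c("tsv", "csv", "mgf"))
  if (dialect == "mgf") {
    lines <- readLines(path)
    inside <- FALSE
    rows <- list()
    for (k in seq_along(lines)) {
      ln <- trimws(lines[k])
      if (ln == "BEGIN IONS") { inside <- TRUE; next }
      if (ln == "END IONS") { inside <- FALSE; next }
      if (!inside || !nzchar(ln) || grepl("=", ln, fixed = TRUE)) next
      fields <- strsplit(ln, "[\t ]+")[[1]]
      mz <- suppressWarnings(as.numeric(fields[1]))
      if (is.na(mz)) {
        stop("non-numeric m/z at line ", k, " of ", path, call. = FALSE)
      }
      it <- if (length(fields) >= 2L) {
        suppressWarnings(as.numeric(fields[2]))
      } else 1
      rows[[length(rows) + 1L]] <- c(mz, it)
    }
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("mz", "intensity")
  } else {
    delim <- if (dialect == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    has_header <- is.na(suppressWarnings(
      as.numeric(strsplit(first, delim, fixed = TRUE)[[1]][1])
    ))
    df <- as.data.frame(readr::read_delim(
      path, delim = delim, col_names = FALSE, show_col_types = FALSE,
      skip = if (has_header) 1L else 0L,
      col_types = readr::cols(.default = readr::col_character())
    ))
    df[] <- lapply(df, function(x) suppressWarnings(as.numeric(x)))
    if (ncol(df) < 1L) stop("empty peak list: ", path, call. = FALSE)
    names(df)[1] <- "mz"
    if (ncol(df) >= 2L) names(df)[2] <- "intensity"
    bad <- which(is.na(suppressWarnings(as.numeric(df$mz))))
    if (length(bad) > 0L) {
      stop("non-numeric m/z at data line ", bad[1], " of ", path,
           call. = FALSE)
    }
  }
  as_peaklist(df, window = window, source = path)
}

#' Write a peak list to TSV
#'
#' @param peaks Peak tibble.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks[c("mz", "intensity")], path)
  invisible(path)
}

#' Match theoretical modified variants against observed peaks
#'
#' Each variant is matched to the nearest observed peak within `tolerance`
#' of its theoretical MH+; variants with no peak within tolerance are
#' reported absent. A peak matching more than one variant is flagged
#' ambiguous on every variant it matches. Intensity is not used for matching.
#'
#' @param peaks Peak tibble (`mz`, `intensity`).
#' @param variants Tibble from [enumerate_variants()], or any data frame with
#'   an `mh` column of theoretical MH+ values.
#' @param tolerance Matching tolerance in Da (default 0.1, the precision at
#'   which MALDI reflector masses are typically reported).
#' @return `variants` with added columns `matched` (logical), `matched_mz`,
#'   `mass_error` (observed - theoretical) and `ambiguous`.
#' @export
match_variants <- function(peaks, variants, tolerance = 0.1) {
  stopifnot(tolerance > 0)
  if (is.null(variants) || nrow(variants) == 0L) {
    stop("empty variant list", call. = FALSE)
  }
  stopifnot("mh" %in% names(variants))
  out <- tibble::as_tibble(variants)
  if (nrow(peaks) == 0L) {
    out$matched <- FALSE
    out$matched_mz <- NA_real_
    out$mass_error <- NA_real_
    out$ambiguous <- FALSE
    return(out)
  }
  idx <- vapply(out$mh, function(m) {
    d <- abs(peaks$mz - m)
    i <- which.min(d)
    if (d[i] <= tolerance) i else NA_integer_
  }, integer(1))
  out$matched <- !is.na(idx)
  out$matched_mz <- peaks$mz[idx]
  out$mass_error <- out$matched_mz - out$mh
  dup <- idx[!is.na(idx)]
  dup <- dup[duplicated(dup)]
  out$ambiguous <- !is.na(idx) & idx %in% dup
  out
}

#' Detect an 80-Da phosphorylation pair
#'
#' Looks for peaks within `tolerance` of a base MH+ and of base + 79.96633.
#' Three informative outcomes: `"pair"` (both present), `"exclusive"`
#' (phosphorylated peak present, unmodified absent - a fully phosphorylated
#' site), `"none"` (no phospho peak; the unmodified peak alone is reported as
#' `"base_only"`).
#'
#' @param peaks Peak tibble.
#' @param base_mh Theoretical MH+ of the unmodified peptide.
#' @param tolerance Da.
#' @return One-row tibble: `base_mh`, `phospho_mh`, `base_present`,
#'   `phospho_present`, `status`, `base_mz`, `phospho_mz`.
#' @export
detect_phospho_pair <- function(peaks, base_mh, tolerance = 0.1) {
  stopifnot(tolerance > 0, is.numeric(base_mh), length(base_mh) == 1L)
  nearest <- function(target) {
    if (nrow(peaks) == 0L) return(NA_real_)
    d <- abs(peaks$mz - target)
    i <- which.min(d)
    if (d[i] <= tolerance) peaks$mz[i] else NA_real_
  }
  b <- nearest(base_mh)
  p <- nearest(base_mh + delta_phospho)
  status <- if (!is.na(b) && !is.na(p)) {
    "pair"
  } else if (is.na(b) && !is.na(p)) {
    "exclusive"
  } else if (!is.na(b)) {
    "base_only"
  } else {
    "none"
  }
  tibble::tibble(
    base_mh = base_mh, phospho_mh = base_mh + delta_phospho,
    base_present = !is.na(b), phospho_present = !is.na(p),
    status = status, base_mz = b, phospho_mz = p
  )
}

#' Call a 57-Da polyglycylation ladder
#'
#' Scans upward from the unmodified MH+ (rung n = 0), accepting rung n when a
#' peak lies within `tolerance` of `base_mh + n * 57.02146` and tolerating up
#' to `max_gap` consecutive missing rungs. The search is anchored at the
#' unmodified mass even when that rung itself is absent, so a ladder may
#' start above n = 0 (a polyglycylated peptide whose unmodified form is not
#' observed). A call is returned only when at least `min_rungs` rungs are
#' found. The default `min_rungs = 3` guards against coincidental peak pairs
#' 57 Da apart, which are common among tryptic peptides (glycine residue
#' mass).
#'
#' @param peaks Peak tibble.
#' @param base_mh Unmodified peptide MH+ anchoring the ladder.
#' @param tolerance Da (default 0.1).
#' @param max_gap Maximum consecutive missing rungs tolerated (default 1).
#' @param min_rungs Minimum rungs for a call (default 3).
#' @param n_max Largest glycine multiplicity considered (default 30).
#' @return A `ladder_call` object (see [tidy.ladder_call()]), or `NULL` when
#'   no ladder qualifies.
#' @export
call_ladder <- function(peaks, base_mh, tolerance = 0.1, max_gap = 1L,
                        min_rungs = 3L, n_max = 30L) {
  stopifnot(tolerance > 0, max_gap >= 0L, min_rungs >= 2L, n_max >= 1L)
  rungs <- integer(0)
  mzs <- numeric(0)
  miss_run <- 0L
  for (n in 0:n_max) {
    target <- base_mh + n * delta_glycyl
    hit <- NA_real_
    if (nrow(peaks) > 0L) {
      d <- abs(peaks$mz - target)
      i <- which.min(d)
      if (d[i] <= tolerance) hit <- peaks$mz[i]
    }
    if (!is.na(hit)) {
      rungs <- c(rungs, n)
      mzs <- c(mzs, hit)
      miss_run <- 0L
    } else {
      miss_run <- miss_run + 1L
      if (miss_run > max_gap && length(rungs) > 0L) break
    }
  }
  if (length(rungs) < min_rungs) return(NULL)
  k_max <- max(rungs)
  structure(
    list(
      base_mh = base_mh,
      rungs = tibble::tibble(n = rungs, mz = mzs,
                             mass_error = mzs - (base_mh + rungs * delta_glycyl)),
      k_max = k_max,
      gaps = setdiff(0:k_max, rungs),
      tolerance = tolerance
    ),
    class = "ladder_call"
  )
}

#' @export
print.ladder_call <- function(x, ...) {
  cat(sprintf(
    "57-Da ladder on base MH+ %.4f: %d rungs, k_max = %d, gaps at {%s}\n",
    x$base_mh, nrow(x$rungs), x$k_max,
    paste(x$gaps, collapse = ", ")
  ))
  invisible(x)
}
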