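#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is proline
#' ("trypsin strict"). Returns every peptide with at most `max_missed`
#' internal uncleaved K/R sites and length within `[min_len, max_len]`,
#' carrying 1-based inclusive coordinates on the parent. The protein
#' N-terminal methionine is kept (publication residue numbering includes it).
#'
#' @param record Single-row protein tibble (`id`, `sequence`) or a plain
#'   sequence string (then `parent_id` is used as the label).
#' @param max_missed Maximum internal missed cleavages (default 2).
#' @param min_len,max_len Peptide length filter (defaults 1 and `Inf`).
#' @param parent_id Label used when `record` is a bare string.
#' @param masses Add `neutral_mass` and `mh` columns (default TRUE).
#' @return Tibble `parent_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, sorted by `start` then `end`.
#' @examples
#' digest("AKRP", max_missed = 0)  # "AK" then "RP": no cleavage before P
#' @export
digest <- function(record, max_missed = 2L, min_len = 1L, max_len = Inf,
                   parent_id = "seq", masses = TRUE) {
  if (!is.character(record)) {
    parent_id <- record$id[[1]]
    record <- record$sequence[[1]]
  }
  chars <- .check_sequence(record)
  stopifnot(max_missed >= 0L, min_len >= 1L, min_len <= max_len)
  n <- length(chars)

  # cut points: cleavage after position i
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n & chars[cuts + 1L] != "P"]
  bounds <- c(0L, cuts, n)          # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L

  out <- purrr::map_dfr(seq_len(nfrag), function(i) {
    js <- seq(i, min(i + max_missed, nfrag))
    tibble::tibble(
      parent_id = parent_id,
      start = bounds[i] + 1L,
      end = bounds[js + 1L],
      missed_cleavages = js - i
    )
  })
  out$sequence <- substring(record, out$start, out$end)
  len <- out$end - out$start + 1L
  out <- out[len >= min_len & len <= max_len,
             c("parent_id", "start", "end", "sequence", "missed_cleavages")]
  out <- dplyr::arrange(out, .data$start, .data$end)
  if (masses) {
    out$neutral_mass <- vapply(out$sequence, neutral_mass, numeric(1),
                               USE.NAMES = FALSE)
    out$mh <- out$neutral_mass + mass_proton
  }
  out
}

#' Extract a peptide by parent coordinates
#'
#' Returns the subsequence as a one-row peptide tibble regardless of tryptic
#' validity, with flags describing whether its boundaries are tryptic
#' (N-terminus preceded by K/R-not-P or the protein start; C-terminus a
#' K/R-not-P site or the protein end) and whether it is the protein's
#' C-terminal peptide.
#'
#' @param record Protein tibble row or sequence string.
#' @param start,end 1-based inclusive coordinates.
#' @param parent_id Label used when `record` is a bare string.
#' @return One-row tibble: `parent_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `tryptic`, `c_terminal`, `neutral_mass`, `mh`.
#' @export
peptide_by_coords <- function(record, start, end, parent_id = "seq") {
  if (!is.character(record)) {
    parent_id <- record$id[[1]]
    record <- record$sequence[[1]]
  }
  chars <- .check_sequence(record)
  n <- length(chars)
  if (start < 1L || end > n || start > end) {
    stop(sprintf("invalid coordinate range %d..%d on sequence of length %d",
                 start, end, n), call. = FALSE)
  }
  is_cut <- function(i) {               # cleavage after position i?
    i >= 1L && i < n && chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }
  internal <- if (end - start >= 1L) {
    sum(vapply(seq(start, end - 1L), is_cut, logical(1)))
  } else 0L
  tibble::tibble(
    parent_id = parent_id,
    start = as.integer(start),
    end = as.integer(end),
    sequence = substring(record, start, end),
    missed_cleavages = as.integer(internal),
    tryptic = (start == 1L || is_cut(start - 1L)) &&
      (end == n || is_cut(end)),
    c_terminal = end == n,
    neutral_mass = neutral_mass(substring(record, start, end)),
    mh = neutral_mass(substring(record, start, end)) + mass_proton
  )
}
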