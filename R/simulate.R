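#' Generate a random protein with planted signature motifs
#'
#' Draws a background sequence from `background_alphabet` and overwrites
#' `n_motifs` non-overlapping spans with instances of the signature pattern
#' (element lengths sampled within their bounds, residues sampled from each
#' element's class; X residues from the pattern's X alphabet). Ground truth
#' (the planted spans) is emitted alongside the record, and downstream tests
#' consume the (data, truth) pair rather than re-deriving truth.
#'
#' All randomness flows from `seed`; identical arguments give identical
#' output.
#'
#' @param length Protein length.
#' @param n_motifs Number of motif instances to plant (default 1).
#' @param seed Integer seed.
#' @param pattern A [compile_pattern()] object (default strict pattern).
#' @param background_alphabet Residues the background is drawn from; the
#'   default is all 20. Using a pattern-critical-residue-free set such as
#'   `c("A","V","L","I","M","F","W","P","K","R","H")` guarantees the
#'   background itself can never match.
#' @param id Record id.
#' @return List with `record` (tibble `id`, `sequence`) and `truth` (tibble
#'   `start`, `end`, `motif`).
#' @export
sim_protein <- function(length, n_motifs = 1L, seed = 1L,
                        pattern = compile_pattern(),
                        background_alphabet = names(aa_residue_masses),
                        id = "sim") {
  stopifnot(length >= 1L, n_motifs >= 0L)
  withr::with_seed(seed, {
    chars <- sample(background_alphabet, length, replace = TRUE)
    truth <- tibble::tibble(start = integer(0), end = integer(0),
                            motif = character(0))
    if (n_motifs > 0L) {
      if (pattern$min_len > length) {
        stop("motif longer than protein", call. = FALSE)
      }
      used <- rep(FALSE, length)
      for (k in seq_len(n_motifs)) {
        inst <- .sample_motif_instance(pattern)
        w <- nchar(inst)
        starts <- which(vapply(seq_len(length - w + 1L), function(s) {
          !any(used[seq(s, s + w - 1L)])
        }, logical(1)))
        if (length(starts) == 0L) {
          stop("no room to plant motif ", k, call. = FALSE)
        }
        s <- starts[sample.int(length(starts), 1L)]
        chars[seq(s, s + w - 1L)] <- strsplit(inst, "")[[1]]
        used[seq(s, s + w - 1L)] <- TRUE
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          start = s, end = s + w - 1L, motif = inst
        ))
      }
    }
    list(
      record = tibble::tibble(id = id,
                              sequence = paste(chars, collapse = "")),
      truth = dplyr::arrange(truth, .data$start)
    )
  })
}

.sample_motif_instance <- function(pattern) {
  el <- pattern$elements
  paste(unlist(lapply(seq_len(nrow(el)), function(i) {
    len <- sample(seq(el$min[i], el$max[i]), 1L)
    if (len == 0L) return(character(0))
    sample(.class_members(el$class[i], pattern$x_alphabet), len,
           replace = TRUE)
  })), collapse = "")
}

#' Generate a synthetic MALDI reflector peak list
#'
#' Places one peak at each declared true MH+ value with Gaussian calibration
#' jitter, then adds decoy peaks drawn uniformly over the acquisition window
#' but excluded from a +/- `exclusion` neighbourhood of every position in
#' `exclude_mh` - by default the full theoretical rung grid, so planted-absent
#' rungs stay measurably absent. In `hostile` mode decoys sit at half-rung
#' offsets (+28.51 Da) from the excluded grid instead, stressing ladder
#' tie-breaking. Intensities are log-normal. Jitter SD and the matching
#' tolerance used downstream are independent knobs.
#'
#' @param true_mh Numeric vector of true peak MH+ values.
#' @param seed Integer seed (full determinism).
#' @param jitter_sd Calibration jitter SD in Da (default 0.02).
#' @param n_decoys Number of decoy peaks (default 0).
#' @param window Acquisition window in Da (default 750-4000).
#' @param exclusion Half-width of the decoy exclusion zone around each
#'   `exclude_mh` position (default 0.2 Da, i.e. twice the default matching
#'   tolerance).
#' @param exclude_mh Positions decoys must avoid (default `true_mh`; pass a
#'   full ladder grid to keep absent rungs clean).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param hostile Place decoys at half-rung offsets from `exclude_mh`.
#' @return List with `peaks` (normalized peak tibble) and `truth` (tibble
#'   `mz_true`, `mz`, `kind` in signal/decoy).
#' @export
sim_spectrum <- function(true_mh, seed = 1L, jitter_sd = 0.02,
                         n_decoys = 0L, window = c(750, 4000),
                         exclusion = 0.2, exclude_mh = true_mh,
                         intensity_meanlog = log(100),
                         intensity_sdlog = 0.5, hostile = FALSE) {
  if (length(true_mh) > 0L &&
      (min(true_mh) < window[1] || max(true_mh) > window[2])) {
    stop("declared variant masses fall outside the acquisition window",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    signal_mz <- true_mh + stats::rnorm(length(true_mh), 0, jitter_sd)
    decoy_mz <- numeric(0)
    if (n_decoys > 0L) {
      if (hostile) {
        pool <- exclude_mh + delta_glycyl / 2
        pool <- pool[pool >= window[1] & pool <= window[2]]
        decoy_mz <- sample(pool, n_decoys, replace = TRUE) +
          stats::rnorm(n_decoys, 0, jitter_sd)
      } else {
        while (length(decoy_mz) < n_decoys) {
          cand <- stats::runif(n_decoys, window[1], window[2])
          keep <- vapply(cand, function(m) {
            length(exclude_mh) == 0L || min(abs(exclude_mh - m)) > exclusion
          }, logical(1))
          decoy_mz <- c(decoy_mz, cand[keep])
        }
        decoy_mz <- decoy_mz[seq_len(n_decoys)]
      }
    }
    mz <- c(signal_mz, decoy_mz)
    intensity <- stats::rlnorm(length(mz), intensity_meanlog, intensity_sdlog)
    truth <- tibble::tibble(
      mz_true = c(true_mh, rep(NA_real_, length(decoy_mz))),
      mz = mz,
      kind = c(rep("signal", length(signal_mz)),
               rep("decoy", length(decoy_mz)))
    )
    list(
      peaks = suppressWarnings(
        as_peaklist(tibble::tibble(mz = mz, intensity = intensity),
                    window = window, source = "simulated")
      ),
      truth = truth
    )
  })
}

#' Simulate a polyglycylation ladder spectrum for a peptide
#'
#' Convenience wrapper around [sim_spectrum()]: true peaks at
#' `mh_plus(peptide) + n * 57.02146` for each planted multiplicity `n`, with
#' the decoy exclusion grid spanning the full theoretical ladder
#' `0..n_max_grid` so that planted-absent rungs remain absent.
#'
#' @param peptide Peptide sequence.
#' @param glycyl_n Integer vector of planted glycine multiplicities (0 =
#'   unmodified rung).
#' @param n_max_grid Top of the excluded theoretical grid (default 30).
#' @param ... Passed to [sim_spectrum()].
#' @return As [sim_spectrum()], plus `base_mh` and `planted_n` entries.
#' @export
sim_ladder_spectrum <- function(peptide, glycyl_n, n_max_grid = 30L, ...) {
  base <- mh_plus(peptide)
  out <- sim_spectrum(
    true_mh = base + glycyl_n * delta_glycyl,
    exclude_mh = base + (0:n_max_grid) * delta_glycyl,
    ...
  )
  out$base_mh <- base
  out$planted_n <- sort(glycyl_n)
  out
}
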