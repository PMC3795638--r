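#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ladder call into one row per theoretical rung
#'
#' Rungs from 0 to `k_max`, with observed m/z and mass error where a peak was
#' found and `present = FALSE` rows for gaps.
#'
#' @param x A `ladder_call` from [call_ladder()].
#' @param ... Unused.
#' @return Tibble: `n`, `theoretical_mh`, `present`, `mz`, `mass_error`.
#' @method tidy ladder_call
#' @export
tidy.ladder_call <- function(x, ...) {
  grid <- tibble::tibble(
    n = 0:x$k_max,
    theoretical_mh = x$base_mh + (0:x$k_max) * delta_glycyl
  )
  dplyr::left_join(grid, x$rungs, by = "n") |>
    dplyr::mutate(present = !is.na(.data$mz))
}

#' One-row summary of a ladder call
#'
#' @param x A `ladder_call`.
#' @param ... Unused.
#' @return Tibble: `base_mh`, `n_rungs`, `k_max`, `n_gaps`, `max_abs_error`,
#'   `tolerance`.
#' @method glance ladder_call
#' @export
glance.ladder_call <- function(x, ...) {
  tibble::tibble(
    base_mh = x$base_mh,
    n_rungs = nrow(x$rungs),
    k_max = x$k_max,
    n_gaps = length(x$gaps),
    max_abs_error = max(abs(x$rungs$mass_error)),
    tolerance = x$tolerance
  )
}

#' Per-bridge rows of a dimer report
#'
#' @param x A `dimer_report` from [score_dimer()].
#' @param ... Unused.
#' @return The per-bridge classification tibble with partner ids attached.
#' @method tidy dimer_report
#' @export
tidy.dimer_report <- function(x, ...) {
  dplyr::mutate(x$bridges, partner_a = x$partner_a, partner_b = x$partner_b,
                .before = 1L)
}

#' One-row summary of a dimer report
#'
#' @param x A `dimer_report`.
#' @param ... Unused.
#' @return Tibble: partner ids, counts and compatibility score.
#' @method glance dimer_report
#' @export
glance.dimer_report <- function(x, ...) {
  tibble::tibble(
    partner_a = x$partner_a, partner_b = x$partner_b,
    intact = unname(x$counts["intact"]),
    neutral = unname(x$counts["neutral"]),
    repulsive = unname(x$counts["repulsive"]),
    unresolved = unname(x$counts["unresolved"]),
    score = x$score
  )
}

#' Per-column rows of a pairwise alignment
#'
#' @param x A `pairwise_alignment` from [global_align()].
#' @param ... Unused.
#' @return Tibble: `column`, `a`, `b`, `class` in
#'   identical/positive/mismatch/gap.
#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  m <- substitution_matrix(x$matrix)
  ca <- strsplit(x$aligned_a, "")[[1]]
  cb <- strsplit(x$aligned_b, "")[[1]]
  cls <- vapply(seq_along(ca), function(i) {
    if (ca[i] == "-" || cb[i] == "-") return("gap")
    if (ca[i] == cb[i]) return("identical")
    if (m[ca[i], cb[i]] > 0) "positive" else "mismatch"
  }, character(1))
  tibble::tibble(column = seq_along(ca), a = ca, b = cb, class = cls)
}

#' One-row summary of a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return Tibble: `score`, `identity`, `similarity`, `length`, `matrix`,
#'   `gap_open`, `gap_extend`.
#' @method glance pairwise_alignment
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble::tibble(
    score = x$score, identity = x$identity, similarity = x$similarity,
    length = nchar(x$aligned_a), matrix = x$matrix,
    gap_open = x$gap_open, gap_extend = x$gap_extend
  )
}
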