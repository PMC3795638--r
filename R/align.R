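#' Substitution matrix by preset name
#'
#' `"blosum62"` (default) and `"pam250"` are shipped with Biostrings.
#' ClustalW-era defaults used the Gonnet series, which neither preset
#' reproduces exactly; pairwise percentages therefore depend on the preset
#' and gap parameters chosen.
#'
#' @param name Matrix preset name.
#' @return Integer substitution matrix.
#' @export
substitution_matrix <- function(name = c("blosum62", "pam250")) {
  name <- match.arg(tolower(name), c("blosum62", "pam250"))
  e <- new.env()
  utils::data(list = toupper(name), package = "Biostrings", envir = e)
  get(toupper(name), envir = e)
}

#' Optimal global pairwise alignment with affine gaps
#'
#' End-to-end (Needleman-Wunsch) alignment under an affine gap model where a
#' gap of length L costs `gap_open + L * gap_extend`. Alignment itself is a
#' standard step and is delegated to Biostrings; identity and similarity
#' statistics are computed by [identity_similarity()] on the result.
#'
#' @param a,b Sequences (strings) or single-row protein tibbles.
#' @param matrix Substitution matrix preset name (see
#'   [substitution_matrix()]).
#' @param gap_open,gap_extend Affine gap parameters (> 0; defaults 10, 0.5).
#' @return A `pairwise_alignment` object: gapped rows `aligned_a`,
#'   `aligned_b`, `score`, the parameters, and `identity` / `similarity`
#'   percentages (see [identity_similarity()] for the convention).
#' @export
global_align <- function(a, b, matrix = "blosum62", gap_open = 10,
                         gap_extend = 0.5) {
  seq_of <- function(x) if (is.character(x)) x[[1]] else x$sequence[[1]]
  a <- seq_of(a)
  b <- seq_of(b)
  .check_sequence(a, "a")
  .check_sequence(b, "b")
  stopifnot(gap_open > 0, gap_extend > 0)
  m <- substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = m,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  out <- structure(
    list(
      aligned_a = as.character(Biostrings::alignedPattern(pa)),
      aligned_b = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa),
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend
    ),
    class = "pairwise_alignment"
  )
  stats <- identity_similarity(out)
  out$identity <- stats$identity
  out$similarity <- stats$similarity
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("global alignment (%s, open %g, extend %g): score %.1f\n",
              x$matrix, x$gap_open, x$gap_extend, x$score))
  cat(sprintf("identity %.1f%%, similarity %.1f%%\n",
              x$identity, x$similarity))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity and similarity of a pairwise alignment
#'
#' Identity is the fraction of alignment columns with identical residues;
#' similarity additionally counts positive-substitution columns (substitution
#' score > 0 under the alignment's matrix). The default denominator is the
#' full alignment length including gap columns; `denominator = "shorter"`
#' divides by the shorter ungapped sequence length instead. Both values are
#' rounded to one decimal.
#'
#' @param alignment A `pairwise_alignment` object, or a list/data frame with
#'   `aligned_a` and `aligned_b` gapped strings (then `matrix` names the
#'   scoring matrix).
#' @param matrix Matrix preset used for the positive-substitution rule when
#'   `alignment` carries none.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return One-row tibble: `identity`, `similarity`, `length`,
#'   `n_identical`, `n_positive`.
#' @export
identity_similarity <- function(alignment, matrix = NULL,
                                denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  if (is.null(matrix)) {
    matrix <- if (!is.null(alignment$matrix)) alignment$matrix else "blosum62"
  }
  m <- substitution_matrix(matrix)
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  no_gap <- ca != "-" & cb != "-"
  ident <- no_gap & ca == cb
  pos <- no_gap & !ident &
    vapply(seq_along(ca), function(i) {
      no_gap[i] && m[ca[i], cb[i]] > 0
    }, logical(1))
  len <- switch(denominator,
                alignment = length(ca),
                shorter = min(sum(ca != "-"), sum(cb != "-")))
  tibble::tibble(
    identity = round(100 * sum(ident) / len, 1),
    similarity = round(100 * (sum(ident) + sum(pos)) / len, 1),
    length = length(ca),
    n_identical = sum(ident),
    n_positive = sum(pos)
  )
}

#' Classify alignment columns by conservation
#'
#' For each column of a multiple alignment: `invariant` when all rows carry
#' the identical residue with no gap; `conserved` when at least `k` rows
#' share a residue; `divergent` otherwise. Mirrors the conventional
#' black-box / grey-box / unboxed rendering of family alignments.
#'
#' @param block Alignment tibble from [read_alignment()] (>= 2 rows).
#' @param k Minimum number of agreeing rows for `conserved` (default 2).
#' @return Tibble `column`, `class`, `residues` (column string), with one row
#'   per alignment column.
#' @export
classify_columns <- function(block, k = 2L) {
  stopifnot(nrow(block) >= 2L)
  rows <- strsplit(block$aligned, "")
  len <- unique(lengths(rows))
  stopifnot(length(len) == 1L)
  purrr::map_dfr(seq_len(len), function(j) {
    col <- vapply(rows, `[[`, character(1), j)
    residues <- col[col != "-"]
    cls <- if (length(residues) == length(col) &&
               length(unique(residues)) == 1L) {
      "invariant"
    } else if (length(residues) > 0L && max(table(residues)) >= k) {
      "conserved"
    } else {
      "divergent"
    }
    tibble::tibble(column = j, class = cls,
                   residues = paste(col, collapse = ""))
  })
}

#' Map a residue position across a pairwise alignment
#'
#' Given a 1-based position in sequence `a`, returns the 1-based position in
#' `b` aligned to that residue, or `NA` when it is aligned to a gap.
#'
#' @param alignment A `pairwise_alignment` object (or anything with
#'   `aligned_a`/`aligned_b`).
#' @param position_in_a 1-based ungapped position in sequence `a`.
#' @return Integer position in `b`, or `NA_integer_` for a gap.
#' @export
map_position <- function(alignment, position_in_a) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  n_a <- max(pos_a)
  if (position_in_a < 1L || position_in_a > n_a) {
    stop(sprintf("position %d out of range 1..%d", position_in_a, n_a),
         call. = FALSE)
  }
  col <- which(pos_a == position_in_a & ca != "-")[1]
  if (cb[col] == "-") return(NA_integer_)
  as.integer(sum(cb[seq_len(col)] != "-"))
}

#' Reverse a pairwise alignment
#'
#' Swaps the two rows so position maps can be composed in both directions.
#'
#' @param alignment A `pairwise_alignment` object.
#' @return The alignment with `aligned_a` and `aligned_b` exchanged.
#' @export
swap_alignment <- function(alignment) {
  tmp <- alignment$aligned_a
  alignment$aligned_a <- alignment$aligned_b
  alignment$aligned_b <- tmp
  alignment
}
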