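#' Compile the polyglycylation signature pattern
#'
#' The signature proposed for C-terminal polyglycylation sites is the
#' variable-length element sequence
#' `[T/G] X{0,1} [D/E] X{1,3} G [D/E] X{1,2} E{2,4}`,
#' where `X` is a polar or negatively charged residue and the terminal
#' glutamate run holds the candidate glycylation sites. Because "polar or
#' negatively charged" is not a fixed set, the X alphabet is configurable;
#' the default is \{S, T, N, Q, C, Y\} plus \{D, E\}.
#'
#' In `fuzzy` mode up to `max_violations` residue positions across a match
#' may fall outside their element's residue class (element length bounds are
#' never relaxed); each violation is recorded. Strict matches are exactly the
#' fuzzy matches with zero violations.
#'
#' @param x_alphabet Residue set admitted by the `X` elements.
#' @param strictness `"strict"` or `"fuzzy"`.
#' @param max_violations Violation budget in fuzzy mode (default 1).
#' @return A `signature_pattern` object with fields `elements` (tibble:
#'   `class`, `min`, `max`), `x_alphabet`, `strictness`, `max_violations`,
#'   `min_len`, `max_len`.
#' @export
compile_pattern <- function(x_alphabet = c("S", "T", "N", "Q", "C", "Y",
                                           "D", "E"),
                            strictness = c("strict", "fuzzy"),
                            max_violations = 1L) {
  strictness <- match.arg(strictness)
  if (length(x_alphabet) == 0L) {
    stop("x_alphabet must be non-empty", call. = FALSE)
  }
  if (!all(x_alphabet %in% names(aa_residue_masses))) {
    stop("x_alphabet contains invalid residue letters", call. = FALSE)
  }
  elements <- tibble::tibble(
    class = c("TG", "X", "DE", "X", "G", "DE", "X", "E"),
    min = c(1L, 0L, 1L, 1L, 1L, 1L, 1L, 2L),
    max = c(1L, 1L, 1L, 3L, 1L, 1L, 2L, 4L)
  )
  structure(
    list(
      elements = elements,
      x_alphabet = toupper(x_alphabet),
      strictness = strictness,
      max_violations = if (strictness == "strict") 0L else
        as.integer(max_violations),
      min_len = sum(elements$min),
      max_len = sum(elements$max)
    ),
    class = "signature_pattern"
  )
}

#' @export
print.signature_pattern <- function(x, ...) {
  cat(sprintf(
    "[T/G]X{0,1}[D/E]X{1,3}G[D/E]X{1,2}E{2,4} (%s%s); X = {%s}; span %d-%d\n",
    x$strictness,
    if (x$strictness == "fuzzy") paste0(", <=", x$max_violations,
                                        " violations") else "",
    paste(x$x_alphabet, collapse = ","), x$min_len, x$max_len
  ))
  invisible(x)
}

.class_members <- function(class, x_alphabet) {
  switch(class,
         TG = c("T", "G"),
         DE = c("D", "E"),
         G = "G",
         E = "E",
         X = x_alphabet,
         stop("unknown element class: ", class))
}

# Recursive descent over element lengths, longest-first, with a violation
# budget. Collects every feasible (end, violations, lens) completion from
# `pos` at element `ei`.
.match_from <- function(chars, pos, ei, viol, pattern, lens) {
  el <- pattern$elements
  if (ei > nrow(el)) {
    return(list(list(end = pos - 1L, viol = viol, lens = lens)))
  }
  members <- .class_members(el$class[ei], pattern$x_alphabet)
  out <- list()
  for (len in seq(el$max[ei], el$min[ei])) {   # longest first
    if (pos + len - 1L > length(chars)) next
    v <- if (len == 0L) 0L else
      sum(!chars[seq(pos, pos + len - 1L)] %in% members)
    if (viol + v > pattern$max_violations) next
    out <- c(out, .match_from(chars, pos + len, ei + 1L, viol + v, pattern,
                              c(lens, len)))
  }
  out
}

#' Scan sequences for the polyglycylation signature
#'
#' Reports every span (start, end) at which the compiled pattern can be
#' satisfied within its violation budget, left-to-right, overlapping spans
#' allowed. When several element-length assignments produce the same span,
#' the reported assignment is canonical: minimal total violations, ties
#' broken greedy-longest per element (earlier elements take the longest
#' length compatible with a complete match).
#'
#' @param record Protein tibble (one row per record; columns `id`,
#'   `sequence`) or a plain sequence string.
#' @param pattern A [compile_pattern()] object.
#' @return Tibble with one row per match: `id`, `start`, `end`, `match`
#'   (matched substring), `glycyl_sites` (list column: 1-based parent
#'   positions spanned by the terminal E element - the candidate
#'   glycylation sites), `violations` (count) and `violation_detail` (list
#'   column: tibble `element`, `pos`, `residue` for out-of-class positions).
#' @examples
#' p <- compile_pattern()
#' scan_motif("TSDNGESEE", p)
#' @export
scan_motif <- function(record, pattern) {
  stopifnot(inherits(pattern, "signature_pattern"))
  recs <- if (is.character(record)) {
    tibble::tibble(id = "seq", sequence = record)
  } else {
    record
  }
  purrr::map_dfr(seq_len(nrow(recs)), function(r) {
    .scan_one(recs$id[[r]], recs$sequence[[r]], pattern)
  })
}

.scan_one <- function(id, sequence, pattern) {
  chars <- .check_sequence(sequence)
  n <- length(chars)
  empty <- tibble::tibble(
    id = character(0), start = integer(0), end = integer(0),
    match = character(0), glycyl_sites = list(),
    violations = integer(0), violation_detail = list()
  )
  if (n < pattern$min_len) return(empty)
  rows <- list()
  for (start in seq_len(n - pattern$min_len + 1L)) {
    hits <- .match_from(chars, start, 1L, 0L, pattern, integer(0))
    if (length(hits) == 0L) next
    ends <- vapply(hits, `[[`, integer(1), "end")
    for (end in sort(unique(ends))) {
      sub <- hits[ends == end]
      viols <- vapply(sub, `[[`, integer(1), "viol")
      best <- sub[viols == min(viols)]
      # greedy-longest canonical assignment: DFS emitted longest-first, so
      # the first minimal-violation hit is lexicographically largest
      lens <- best[[1]]$lens
      starts_el <- start + cumsum(c(0L, lens[-length(lens)]))
      e_idx <- nrow(pattern$elements)
      e_span <- if (lens[e_idx] > 0L) {
        seq(starts_el[e_idx], starts_el[e_idx] + lens[e_idx] - 1L)
      } else integer(0)
      detail <- purrr::map_dfr(seq_along(lens), function(ei) {
        if (lens[ei] == 0L) return(NULL)
        span <- seq(starts_el[ei], starts_el[ei] + lens[ei] - 1L)
        members <- .class_members(pattern$elements$class[ei],
                                  pattern$x_alphabet)
        bad <- span[!chars[span] %in% members]
        if (length(bad) == 0L) return(NULL)
        tibble::tibble(element = ei, pos = bad, residue = chars[bad])
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, start = start, end = end,
        match = paste(chars[start:end], collapse = ""),
        glycyl_sites = list(e_span),
        violations = min(viols),
        violation_detail = list(detail)
      )
    }
  }
  if (length(rows) == 0L) empty else dplyr::bind_rows(rows)
}
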