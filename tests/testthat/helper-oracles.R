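# Independent oracles used by the property and acceptance tests. These are
# deliberately written as flat brute-force enumerations / textbook dynamic
# programs, sharing no code with the package implementation.

aa20 <- names(ptmladder::aa_residue_masses)

random_protein <- function(n, alphabet = aa20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- motif: flat enumeration of every element-length combination -----------

# vectorized over start positions via class-membership cumulative sums;
# enumerates all element-length combinations explicitly
oracle_motif_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  el <- pattern$elements
  members <- lapply(el$class, function(cl) {
    switch(cl,
           TG = c("T", "G"), DE = c("D", "E"), G = "G", E = "E",
           X = pattern$x_alphabet)
  })
  cums <- lapply(members, function(m) c(0L, cumsum(chars %in% m)))
  combos <- do.call(expand.grid, Map(seq, el$min, el$max))
  hits <- list()
  for (r in seq_len(nrow(combos))) {
    lens <- as.integer(combos[r, ])
    width <- sum(lens)
    if (width > n) next
    starts <- seq_len(n - width + 1L)
    viol <- integer(length(starts))
    off <- 0L
    for (ei in seq_along(lens)) {
      if (lens[ei] > 0L) {
        lo <- starts + off          # element spans lo .. lo+len-1
        hi <- lo + lens[ei] - 1L
        inside <- cums[[ei]][hi + 1L] - cums[[ei]][lo]
        viol <- viol + (lens[ei] - inside)
      }
      off <- off + lens[ei]
    }
    ok <- viol <= pattern$max_violations
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = starts[ok], end = starts[ok] + width - 1L, viol = viol[ok]
      )
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      violations = integer(0)))
  }
  d <- do.call(rbind, hits)
  agg <- stats::aggregate(viol ~ start + end, data = d, FUN = min)
  agg <- agg[order(agg$start, agg$end), ]
  data.frame(start = agg$start, end = agg$end, violations = agg$viol,
             row.names = NULL)
}

# straightforward nested-loop form of the same enumeration; used to validate
# the vectorized oracle on small inputs
oracle_motif_scan_slow <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  el <- pattern$elements
  members <- lapply(el$class, function(cl) {
    switch(cl,
           TG = c("T", "G"), DE = c("D", "E"), G = "G", E = "E",
           X = pattern$x_alphabet)
  })
  combos <- do.call(expand.grid, Map(seq, el$min, el$max))
  hits <- list()
  for (start in seq_len(max(n, 0L))) {
    for (r in seq_len(nrow(combos))) {
      lens <- as.integer(combos[r, ])
      if (start + sum(lens) - 1L > n) next
      pos <- start
      viol <- 0L
      for (ei in seq_along(lens)) {
        if (lens[ei] > 0L) {
          span <- chars[seq(pos, pos + lens[ei] - 1L)]
          viol <- viol + sum(!span %in% members[[ei]])
        }
        pos <- pos + lens[ei]
      }
      if (viol <= pattern$max_violations) {
        hits[[length(hits) + 1L]] <-
          data.frame(start = start, end = pos - 1L, viol = viol)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      violations = integer(0)))
  }
  d <- do.call(rbind, hits)
  agg <- stats::aggregate(viol ~ start + end, data = d, FUN = min)
  agg <- agg[order(agg$start, agg$end), ]
  data.frame(start = agg$start, end = agg$end, violations = agg$viol,
             row.names = NULL)
}

# package scan_motif output reduced to the oracle's comparable form
spans_of <- function(scan_result) {
  d <- scan_result[order(scan_result$start, scan_result$end),
                   c("start", "end", "violations")]
  data.frame(start = as.integer(d$start), end = as.integer(d$end),
             violations = as.integer(d$violations), row.names = NULL)
}

# --- alignment: textbook Gotoh recurrence, plus full path enumeration -------

# affine convention: a gap of length L costs open + L * ext
oracle_align_score <- function(a, b, m, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  p <- length(cb)
  NEG <- -1e9
  M <- A <- B <- matrix(NEG, n + 1L, p + 1L)
  M[1, 1] <- 0
  for (j in seq_len(p)) A[1, j + 1L] <- -(open + j * ext)
  for (i in seq_len(n)) B[i + 1L, 1] <- -(open + i * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      M[i + 1, j + 1] <- m[ca[i], cb[j]] + max(M[i, j], A[i, j], B[i, j])
      A[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             A[i + 1, j] - ext,
                             B[i + 1, j] - open - ext)
      B[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             A[i, j + 1] - open - ext,
                             B[i, j + 1] - ext)
    }
  }
  max(M[n + 1, p + 1], A[n + 1, p + 1], B[n + 1, p + 1])
}

# exhaustive enumeration of every monotone alignment path (tiny inputs only);
# validates the recurrence above
oracle_align_enumerate <- function(a, b, m, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, score + m[ca[i], cb[j]], "M")
    }
    if (j <= length(cb)) {
      rec(i, j + 1L, score - ext - if (prev == "A") 0 else open, "A")
    }
    if (i <= length(ca)) {
      rec(i + 1L, j, score - ext - if (prev == "B") 0 else open, "B")
    }
  }
  rec(1L, 1L, 0, "M")
  best
}

# --- digestion: reference cut points under the K/R-not-P rule ---------------

oracle_cut_after <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  which(vapply(seq_len(n - 1L), function(i) {
    chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }, logical(1)))
}
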