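test_that("pattern compilation validates inputs and derives span bounds", {
  p <- compile_pattern()
  # bounds derived by summing element length bounds (checked by the oracle
  # below on sampled instances)
  expect_identical(p$min_len, 8L)
  expect_identical(p$max_len, 14L)
  expect_identical(p$max_violations, 0L)
  pf <- compile_pattern(strictness = "fuzzy", max_violations = 1)
  expect_identical(pf$max_violations, 1L)
  expect_error(compile_pattern(character(0)), "non-empty")
  expect_error(compile_pattern(c("S", "1")), "invalid")
})

test_that("sampled motif instances span exactly the derived length bounds", {
  p <- compile_pattern()
  withr::with_seed(41, {
    widths <- vapply(1:200, function(i) {
      nchar(ptmladder:::.sample_motif_instance(p))
    }, numeric(1))
    expect_identical(range(widths), c(8, 14))
    # every sampled instance matches strictly over its full span
    for (i in 1:25) {
      inst <- ptmladder:::.sample_motif_instance(p)
      hits <- scan_motif(inst, p)
      expect_true(any(hits$start == 1 & hits$end == nchar(inst)))
    }
  })
})

test_that("the canonical example matches with the expected element split", {
  p <- compile_pattern()
  hits <- scan_motif("TSDNGESEE", p)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 1L)
  expect_identical(hits$end, 9L)
  expect_identical(hits$violations, 0L)
  expect_identical(hits$glycyl_sites[[1]], 8:9)   # terminal EE
})

test_that("the zeta-type C-terminal peptide has no strict signature", {
  p <- compile_pattern()
  expect_identical(nrow(scan_motif("DNLTLWTSDTQGDEAEPQEGGDN", p)), 0L)
  expect_identical(nrow(scan_motif("AAAAAAAA", p)), 0L)
})

test_that("the two oracle formulations agree with each other", {
  strict <- compile_pattern()
  fuzzy1 <- compile_pattern(strictness = "fuzzy", max_violations = 1)
  enriched <- c(aa20, rep(c("T", "G", "D", "E", "S", "N"), 4))
  withr::with_seed(40, {
    for (i in 1:25) {
      s <- random_protein(sample(8:30, 1), alphabet = enriched)
      for (pat in list(strict, fuzzy1)) {
        expect_identical(oracle_motif_scan(s, pat),
                         oracle_motif_scan_slow(s, pat), info = s)
      }
    }
  })
})

test_that("scan agrees with the brute-force oracle, strict and fuzzy", {
  strict <- compile_pattern()
  fuzzy1 <- compile_pattern(strictness = "fuzzy", max_violations = 1)
  # enriched alphabet so matches actually occur
  enriched <- c(aa20, rep(c("T", "G", "D", "E", "S", "N"), 4))
  withr::with_seed(42, {
    n_with_hits <- 0L
    for (i in 1:120) {
      s <- random_protein(sample(8:50, 1), alphabet = enriched)
      if (i %% 2 == 0) {
        # embed a true instance so the comparison exercises real matches
        inst <- ptmladder:::.sample_motif_instance(strict)
        if (nchar(inst) <= nchar(s)) {
          at <- sample.int(nchar(s) - nchar(inst) + 1L, 1)
          substr(s, at, at + nchar(inst) - 1L) <- inst
        }
      }
      for (pat in list(strict, fuzzy1)) {
        got <- spans_of(scan_motif(s, pat))
        want <- oracle_motif_scan(s, pat)
        expect_identical(got, want, info = s)
        n_with_hits <- n_with_hits + (nrow(want) > 0L)
      }
    }
    expect_gt(n_with_hits, 50L)  # the comparison is not vacuous
  })
})

test_that("strict matches are a subset of fuzzy matches for any budget", {
  strict <- compile_pattern()
  enriched <- c(aa20, rep(c("T", "G", "D", "E", "S", "N"), 4))
  withr::with_seed(43, {
    for (i in 1:40) {
      s <- random_protein(sample(10:50, 1), alphabet = enriched)
      sm <- spans_of(scan_motif(s, strict))[, c("start", "end")]
      for (k in c(0L, 1L, 2L)) {
        fz <- compile_pattern(strictness = "fuzzy", max_violations = k)
        fm <- spans_of(scan_motif(s, fz))[, c("start", "end")]
        expect_identical(nrow(dplyr::anti_join(sm, fm,
                                               by = c("start", "end"))), 0L)
      }
    }
  })
})

test_that("fuzzy matches record which positions violate their element class", {
  # G at position 2 is outside the X alphabet: one violation
  fuzzy1 <- compile_pattern(strictness = "fuzzy", max_violations = 1)
  hits <- scan_motif("TGDNGESEE", fuzzy1)
  full <- hits[hits$start == 1 & hits$end == 9, ]
  expect_identical(nrow(full), 1L)
  expect_identical(full$violations, 1L)
  detail <- full$violation_detail[[1]]
  expect_identical(detail$pos, 2L)
  expect_identical(detail$residue, "G")
  # strict mode only admits the shorter violation-free match starting at the G
  sm <- scan_motif("TGDNGESEE", compile_pattern())
  expect_false(any(sm$start == 1))
  expect_true(any(sm$start == 2 & sm$end == 9))
})

test_that("the X alphabet is a real knob", {
  # N excluded from X: the canonical example no longer matches
  narrow <- compile_pattern(x_alphabet = c("S", "T", "D", "E"))
  expect_identical(nrow(scan_motif("TSDNGESEE", narrow)), 0L)
})
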