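peaklist <- function(mz, intensity = NULL) {
  as_peaklist(tibble::tibble(
    mz = mz,
    intensity = intensity %||% rep(1, length(mz))
  ))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("peak lists are sorted, deduplicated and window-filtered", {
  p <- as_peaklist(data.frame(mz = c(1500, 900, 900 + 5e-7, 3000),
                              intensity = c(1, 2, 3, 4)))
  expect_identical(p$mz, c(900, 1500, 3000))
  expect_identical(p$intensity, c(5, 1, 4))   # near-duplicates merged
  expect_warning(
    q <- as_peaklist(data.frame(mz = c(100, 1500), intensity = c(1, 1))),
    "outside acquisition window"
  )
  expect_identical(q$mz, 1500)
  expect_error(as_peaklist(data.frame(mz = 1500, intensity = -1)),
               "negative intensity")
})

test_that("TSV, CSV and MGF peak lists read to identical normalized tables", {
  mz <- c(2087.96, 1404.61, 2167.93)
  it <- c(10, 30, 20)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity", sprintf("%.5f\t%g", mz, it)), tsv)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%.5f,%g", mz, it), csv)   # no header
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=sim", sprintf("%.5f %g", mz, it),
               "END IONS"), mgf)
  a <- read_peaks(tsv)
  b <- read_peaks(csv)
  c3 <- read_peaks(mgf)
  expect_equal(a$mz, sort(mz))
  expect_equal(a$mz, b$mz)
  expect_equal(a$mz, c3$mz)
  expect_equal(a$intensity, b$intensity)
  expect_equal(a$intensity, c3$intensity)
})

test_that("malformed peak lists are rejected with a line reference", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1404.61\t100", "oops\t3"), bad)
  expect_error(read_peaks(bad), "line")
  badmgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "xx 1", "END IONS"), badmgf)
  expect_error(read_peaks(badmgf), "line")
})

test_that("variants match to nearest peak within tolerance only", {
  peaks <- peaklist(c(2087.96, 2167.93))
  variants <- tibble::tibble(
    label = c("unmodified", "phospho"),
    mh = c(mh_plus("AAFDDAIAELDTLSEESYK"),
           mh_plus("AAFDDAIAELDTLSEESYK",
                   data.frame(site = 14, mod = "phospho", n = 1)))
  )
  m <- match_variants(peaks, variants, tolerance = 0.1)
  expect_true(all(m$matched))
  expect_equal(diff(m$matched_mz), 79.97, tolerance = 0.01)
  expect_true(all(abs(m$mass_error) <= 0.1))

  # empty peak list: all absent
  m0 <- match_variants(peaklist(numeric(0)), variants)
  expect_false(any(m0$matched))

  # just outside tolerance: absent
  m1 <- match_variants(peaklist(variants$mh[1] + 0.25), variants[1, ],
                       tolerance = 0.1)
  expect_false(m1$matched)
  expect_error(match_variants(peaks, variants[0, ]), "empty variant")
})

test_that("one peak matching several variants is flagged ambiguous", {
  variants <- tibble::tibble(mh = c(1500.00, 1500.05, 1600))
  m <- match_variants(peaklist(c(1500.02, 1600)), variants, tolerance = 0.1)
  expect_identical(m$ambiguous, c(TRUE, TRUE, FALSE))
})

test_that("shrinking the tolerance never adds matches", {
  withr::with_seed(31, {
    for (i in 1:10) {
      peaks <- peaklist(sort(runif(30, 800, 3900)))
      variants <- tibble::tibble(mh = runif(10, 800, 3900))
      tols <- c(0.5, 0.2, 0.1, 0.02)
      matched <- lapply(tols, function(tol) {
        which(match_variants(peaks, variants, tolerance = tol)$matched)
      })
      for (k in seq_along(tols)[-1]) {
        expect_true(all(matched[[k]] %in% matched[[k - 1]]))
      }
    }
  })
})

test_that("phospho pair detection distinguishes pair/exclusive/none", {
  base <- mh_plus("EQIQDVEDQDVS")
  pair <- detect_phospho_pair(peaklist(c(1404.61, 1484.58)), base)
  expect_identical(pair$status, "pair")
  expect_true(pair$base_present && pair$phospho_present)

  # fully phosphorylated site: shifted peak without its unmodified partner
  base2 <- mh_plus("AFDAAITDLDKLTEESYK")
  excl <- detect_phospho_pair(peaklist(2109.96), base2)
  expect_identical(excl$status, "exclusive")
  expect_false(excl$base_present)

  none <- detect_phospho_pair(peaklist(c(1404.61, 1450.00)), base)
  expect_identical(none$status, "base_only")
  expect_false(none$phospho_present)
  expect_identical(detect_phospho_pair(peaklist(numeric(0)), base)$status,
                   "none")
})

test_that("ladder calling walks the 57-Da grid and reports gaps", {
  base <- mh_plus("DNLNLWVTDSAGDDNAEEK")
  full <- peaklist(base + (0:24) * delta_glycyl)
  lc <- call_ladder(full, base)
  expect_identical(lc$k_max, 24L)
  expect_identical(lc$gaps, integer(0))
  expect_identical(lc$rungs$n, 0:24)

  # rungs {0,1,3,4}: gap at 2 tolerated with max_gap = 1
  sparse <- peaklist(base + c(0, 1, 3, 4) * delta_glycyl)
  lc2 <- call_ladder(sparse, base, max_gap = 1, min_rungs = 3)
  expect_identical(lc2$k_max, 4L)
  expect_identical(lc2$gaps, 2L)

  # nothing beyond n = 0: below min_rungs, no call
  expect_null(call_ladder(peaklist(base), base, min_rungs = 3))
})

test_that("a missing anchor rung does not prevent the ladder call", {
  base <- 2000
  lad <- peaklist(base + (1:6) * delta_glycyl)
  lc <- call_ladder(lad, base, max_gap = 1)
  expect_identical(lc$rungs$n, 1:6)
  expect_identical(lc$gaps, 0L)
  expect_identical(lc$k_max, 6L)
})

test_that("ladder calls ignore decoys away from the rung grid", {
  withr::with_seed(33, {
    base <- 2000
    rungs <- base + (0:8) * delta_glycyl
    for (i in 1:20) {
      decoys <- runif(40, 800, 3900)
      # keep decoys > 2 x tolerance away from every rung position
      decoys <- decoys[vapply(decoys, function(m) {
        min(abs(base + (0:30) * delta_glycyl - m)) > 0.2
      }, logical(1))]
      with_decoys <- peaklist(sort(c(rungs, decoys)))
      lc <- call_ladder(with_decoys, base, tolerance = 0.1)
      expect_identical(lc$rungs$n, 0:8)
      expect_identical(lc$k_max, 8L)
    }
  })
})
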