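test_that("residue pairs classify by charge complementarity", {
  expect_identical(classify_pair("R", "E"), "intact")
  expect_identical(classify_pair("E", "K"), "intact")
  expect_identical(classify_pair("D", "E"), "repulsive")
  expect_identical(classify_pair("K", "R"), "repulsive")
  expect_identical(classify_pair("N", "E"), "neutral")
  expect_identical(classify_pair("E", "Q"), "neutral")
  expect_identical(classify_pair("A", "V"), "neutral")
  # histidine is uncharged by default but configurable
  expect_identical(classify_pair("H", "E"), "neutral")
  expect_identical(classify_pair("H", "E", positive = c("K", "R", "H")),
                   "intact")
  expect_error(classify_pair("B", "E"), "invalid residue")
})

test_that("classification is symmetric and collapses without charge sets", {
  withr::with_seed(61, {
    for (i in 1:50) {
      pair <- sample(aa20, 2, replace = TRUE)
      expect_identical(classify_pair(pair[1], pair[2]),
                       classify_pair(pair[2], pair[1]))
    }
  })
  rb <- reference_bridges()
  rep0 <- score_dimer(rb[rb$dimer == "g14-3-3/g14-3-3", ],
                      positive = character(0), negative = character(0))
  expect_identical(unname(rep0$counts["neutral"]), 3L)
  expect_identical(rep0$score, 0L)
})

test_that("packaged bridge tables reproduce the published intact counts", {
  rb <- reference_bridges()
  intact_of <- function(d) {
    unname(score_dimer(rb[rb$dimer == d, ])$counts["intact"])
  }
  expect_identical(intact_of("h14-3-3z/h14-3-3z"), 3L)
  expect_identical(intact_of("LeoII/LeoII"), 3L)
  expect_identical(intact_of("D14-3-3e/D14-3-3e"), 1L)
  expect_identical(intact_of("g14-3-3/g14-3-3"), 3L)
  expect_identical(intact_of("g14-3-3/LeoII"), 3L)

  het <- score_dimer(rb[rb$dimer == "g14-3-3/D14-3-3e", ],
                     ids = c("g14-3-3", "D14-3-3e"))
  expect_identical(unname(het$counts["intact"]), 1L)
  expect_identical(unname(het$counts["repulsive"]), 1L)
  expect_identical(unname(het$counts["neutral"]), 1L)
  expect_identical(het$score, 0L)
})

test_that("an empty bridge list scores zero", {
  rep0 <- score_dimer(tibble::tibble(pos_a = integer(0), res_a = character(0),
                                     pos_b = integer(0), res_b = character(0)))
  expect_identical(rep0$score, 0L)
  expect_identical(sum(rep0$counts), 0L)
})

test_that("bridges resolve through partner sequences with identity maps", {
  bridges <- tibble::tibble(bridge = "2-5", pos_a = 2L, res_a = "K",
                            pos_b = 5L, res_b = "K")
  # annotated residues say repulsive, but the partner sequences say intact:
  # sequence lookup must win when partners are supplied
  rep1 <- score_dimer(bridges, partner_a = "ARCDE", partner_b = "ARCDE")
  expect_identical(unname(rep1$counts["intact"]), 1L)
  rep2 <- score_dimer(bridges)
  expect_identical(unname(rep2$counts["repulsive"]), 1L)
})

test_that("bridges resolve through alignments and report gapped ones", {
  ref <- "ARCDE"
  partner <- "ACDE"                 # R deleted
  al <- global_align(ref, partner)  # reference is row a
  bridges <- tibble::tibble(
    bridge = c("R2-E5", "C3-D4"),
    pos_a = c(2L, 3L), res_a = c("R", "C"),
    pos_b = c(5L, 4L), res_b = c("E", "D")
  )
  expect_warning(
    rep1 <- score_dimer(bridges, partner_a = partner, partner_b = partner,
                        map_a = al, map_b = al),
    "unresolvable"
  )
  # R2 maps to the gap; C3-D4 maps to C2-D3 of the partner and stays intact?
  expect_identical(unname(rep1$counts["unresolved"]), 1L)
  expect_identical(sum(rep1$counts[c("intact", "neutral", "repulsive")]), 1L)
})

test_that("scores are invariant under consistent renumbering", {
  rb <- reference_bridges()
  gg <- rb[rb$dimer == "g14-3-3/g14-3-3", ]
  shifted <- dplyr::mutate(gg, pos_a = pos_a + 100L, pos_b = pos_b + 100L)
  expect_identical(score_dimer(gg)$score, score_dimer(shifted)$score)
  expect_identical(score_dimer(gg)$counts, score_dimer(shifted)$counts)
})

test_that("partner ranking follows score, intact count, then id", {
  rb <- reference_bridges()
  ranked <- rank_partners(rb, "g14-3-3")
  expect_identical(ranked$partner, c("LeoII", "g14-3-3", "D14-3-3e"))
  expect_identical(ranked$score, c(3L, 3L, 0L))
  # the epsilon heterodimer ranks strictly below both zeta-type pairings
  expect_lt(ranked$score[3], ranked$score[2])
  expect_error(rank_partners(rb, "nosuch"), "no dimer entries")
  # deterministic ordering on exact ties (LeoII before g14-3-3 by id)
  expect_identical(rank_partners(rb, "g14-3-3")$partner[1:2],
                   c("LeoII", "g14-3-3"))
})
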