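#' Packaged reference salt-bridge table
#'
#' Interface residue pairs for the N-terminal dimerization helices of five
#' 14-3-3 proteins (human zeta, Drosophila LeoII and D14-3-3-epsilon,
#' Giardia g14-3-3) and the two giardial heterodimer mappings, at the
#' residue-identity level. Positions are 1-based on each protein's published
#' numbering.
#'
#' @return Tibble: `dimer`, `partner_a`, `partner_b`, `bridge`, `pos_a`,
#'   `res_a`, `pos_b`, `res_b`, `note`.
#' @export
reference_bridges <- function() {
  path <- system.file("extdata", "reference_bridges.tsv",
                      package = "ptmladder", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pos_a = readr::col_integer(),
                    pos_b = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}

#' Classify a candidate salt-bridge residue pair
#'
#' `intact` when one residue is basic and the other acidic (a formable salt
#' bridge), `repulsive` when both carry the same charge, `neutral` otherwise.
#' Histidine is excluded from the basic set by default (physiological-pH
#' assumption). Classification is purely residue-identity based; no geometry
#' is modeled.
#'
#' @param res_a,res_b One-letter residue codes (vectorized).
#' @param positive,negative Charge sets (defaults \{K, R\} and \{D, E\}).
#' @return Character vector: `"intact"`, `"neutral"` or `"repulsive"`.
#' @examples
#' classify_pair("R", "E")  # intact
#' classify_pair("D", "E")  # repulsive
#' classify_pair("N", "E")  # neutral
#' @export
classify_pair <- function(res_a, res_b, positive = c("K", "R"),
                          negative = c("D", "E")) {
  valid <- names(aa_residue_masses)
  if (!all(res_a %in% valid) || !all(res_b %in% valid)) {
    stop("invalid residue letter", call. = FALSE)
  }
  charge <- function(r) {
    ifelse(r %in% positive, 1L, ifelse(r %in% negative, -1L, 0L))
  }
  qa <- charge(res_a)
  qb <- charge(res_b)
  dplyr::case_when(
    qa != 0L & qb != 0L & qa != qb ~ "intact",
    qa != 0L & qa == qb ~ "repulsive",
    TRUE ~ "neutral"
  )
}

.resolve_residue <- function(pos, res, partner, map) {
  # no partner sequence: trust the residue annotated in the bridge table
  if (is.null(partner)) {
    return(list(pos = pos, res = res))
  }
  mapped <- if (is.null(map)) {
    pos
  } else if (is.function(map)) {
    map(pos)
  } else {
    map_position(map, pos)
  }
  if (is.na(mapped)) return(list(pos = NA_integer_, res = NA_character_))
  list(pos = mapped, res = residue_at(partner, mapped))
}

#' Score dimer compatibility from salt-bridge conservation
#'
#' Classifies each interface residue pair and aggregates into a
#' compatibility score `intact - repulsive`. By default the residues
#' annotated in `bridges` (`res_a`, `res_b`) are used directly; when partner
#' sequences and position maps are supplied, reference positions are carried
#' onto each partner (via [map_position()] alignments, lookup functions, or
#' identity) and residues are read from the sequences. A bridge whose
#' position maps to a gap is reported unresolvable and excluded from the
#' counts with a warning.
#'
#' @param bridges Tibble with `pos_a`, `res_a`, `pos_b`, `res_b` (and
#'   optionally `bridge` labels), e.g. one dimer's rows of
#'   [reference_bridges()].
#' @param partner_a,partner_b Optional protein records (tibble row or
#'   string); when given, residues are looked up rather than taken from
#'   `bridges`.
#' @param map_a,map_b Optional position maps from reference numbering onto
#'   each partner: a `pairwise_alignment`, a function, or `NULL` (identity).
#' @param positive,negative Charge sets passed to [classify_pair()].
#' @param ids Length-2 character, partner labels for reporting.
#' @return A `dimer_report` object: partner ids, per-bridge classification
#'   tibble, counts and `score`.
#' @export
score_dimer <- function(bridges, partner_a = NULL, partner_b = NULL,
                        map_a = NULL, map_b = NULL,
                        positive = c("K", "R"), negative = c("D", "E"),
                        ids = c("A", "B")) {
  n <- nrow(bridges)
  label <- if ("bridge" %in% names(bridges)) bridges$bridge else
    as.character(seq_len(max(n, 0L)))
  res <- purrr::map_dfr(seq_len(n), function(i) {
    a <- .resolve_residue(bridges$pos_a[i], bridges$res_a[i], partner_a, map_a)
    b <- .resolve_residue(bridges$pos_b[i], bridges$res_b[i], partner_b, map_b)
    tibble::tibble(
      bridge = label[i],
      pos_a = a$pos, res_a = a$res, pos_b = b$pos, res_b = b$res,
      resolved = !is.na(a$res) && !is.na(b$res)
    )
  })
  if (n == 0L) {
    res <- tibble::tibble(bridge = character(0), pos_a = integer(0),
                          res_a = character(0), pos_b = integer(0),
                          res_b = character(0), resolved = logical(0))
  }
  if (any(!res$resolved)) {
    warning(sum(!res$resolved), " bridge(s) unresolvable (mapped to a gap), ",
            "excluded from counts", call. = FALSE)
  }
  res$class <- NA_character_
  ok <- res$resolved
  if (any(ok)) {
    res$class[ok] <- classify_pair(res$res_a[ok], res$res_b[ok],
                                   positive, negative)
  }
  counts <- c(
    intact = sum(res$class == "intact", na.rm = TRUE),
    neutral = sum(res$class == "neutral", na.rm = TRUE),
    repulsive = sum(res$class == "repulsive", na.rm = TRUE),
    unresolved = sum(!res$resolved)
  )
  structure(
    list(
      partner_a = ids[1], partner_b = ids[2],
      bridges = res,
      counts = counts,
      score = unname(counts["intact"] - counts["repulsive"])
    ),
    class = "dimer_report"
  )
}

#' @export
print.dimer_report <- function(x, ...) {
  cat(sprintf("%s / %s: %d intact, %d neutral, %d repulsive%s -> score %d\n",
              x$partner_a, x$partner_b,
              x$counts["intact"], x$counts["neutral"], x$counts["repulsive"],
              if (x$counts["unresolved"] > 0)
                sprintf(" (%d unresolved)", x$counts["unresolved"]) else "",
              x$score))
  invisible(x)
}

#' Rank dimerization partners by salt-bridge compatibility
#'
#' Scores every dimer configuration in a bridge table that involves
#' `subject` and ranks candidates by compatibility score (descending), then
#' intact-bridge count, then partner id.
#'
#' @param bridge_table Tibble in the [reference_bridges()] layout.
#' @param subject Protein label to rank partners for.
#' @param positive,negative Charge sets.
#' @return Tibble: `partner`, `dimer`, `intact`, `neutral`, `repulsive`,
#'   `unresolved`, `score`, ordered best-first.
#' @export
rank_partners <- function(bridge_table, subject,
                          positive = c("K", "R"), negative = c("D", "E")) {
  rows <- bridge_table[bridge_table$partner_a == subject |
                         bridge_table$partner_b == subject, ]
  if (nrow(rows) == 0L) stop("no dimer entries for ", subject, call. = FALSE)
  purrr::map_dfr(unique(rows$dimer), function(d) {
    br <- rows[rows$dimer == d, ]
    partner <- ifelse(br$partner_a[1] == subject,
                      br$partner_b[1], br$partner_a[1])
    rep <- score_dimer(br, positive = positive, negative = negative,
                       ids = c(subject, partner))
    tibble::tibble(
      partner = partner, dimer = d,
      intact = unname(rep$counts["intact"]),
      neutral = unname(rep$counts["neutral"]),
      repulsive = unname(rep$counts["repulsive"]),
      unresolved = unname(rep$counts["unresolved"]),
      score = rep$score
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$intact),
                   .data$partner)
}
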