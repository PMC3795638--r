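#' Monoisotopic residue masses and physical constants
#'
#' Residue (not free amino acid) monoisotopic masses in daltons for the 20
#' standard amino acids, plus the monoisotopic mass of water and of a proton.
#' A peptide's neutral monoisotopic mass is the sum of its residue masses plus
#' one water; the singly protonated MALDI ion (MH+) adds one proton.
#'
#' @format `aa_residue_masses` is a named numeric vector of length 20 keyed by
#'   one-letter amino-acid code. `mass_water` and `mass_proton` are scalars in
#'   daltons. `delta_phospho` and `delta_glycyl` are the mass increments of one
#'   phosphorylation event (HPO3 on S/T/Y) and of one glycine added to a
#'   glutamate side chain.
#' @export
aa_residue_masses <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname aa_residue_masses
#' @export
mass_water <- 18.010565

#' @rdname aa_residue_masses
#' @export
mass_proton <- 1.007276

#' @rdname aa_residue_masses
#' @export
delta_phospho <- 79.96633

#' @rdname aa_residue_masses
#' @export
delta_glycyl <- 57.02146

# residues a modification may sit on
.mod_targets <- list(phospho = c("S", "T", "Y"), glycyl = "E")

.check_sequence <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(aa_residue_masses))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  chars
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water. Values are returned at
#' full precision; round for display only.
#'
#' @param sequence Peptide sequence, one-letter codes, uppercase.
#' @return Mass in daltons (numeric scalar).
#' @examples
#' neutral_mass("G")  # 75.03203
#' @export
neutral_mass <- function(sequence) {
  chars <- .check_sequence(sequence)
  sum(aa_residue_masses[chars]) + mass_water
}

#' Singly protonated monoisotopic mass (MH+) of a possibly modified peptide
#'
#' The MALDI reflector observable for a singly charged peptide ion: neutral
#' monoisotopic mass, plus the mass increment of every applied modification,
#' plus one proton.
#'
#' Modifications are given as a data frame with one row per modification
#' event group: `site` (1-based position within the peptide), `mod`
#' ("phospho" or "glycyl") and `n` (multiplicity; phospho is restricted to
#' one event per site, glycyl may add `n >= 1` glycines to one glutamate).
#' Sites are validated against the permitted target residues (phospho on
#' S/T/Y, glycyl on E).
#'
#' @param sequence Peptide sequence.
#' @param mods Optional modification data frame (`site`, `mod`, `n`); `NULL`
#'   or zero rows means unmodified.
#' @return MH+ in daltons.
#' @examples
#' mh_plus("QAFDDAIAELDTLNEDSYK")               # 2157.98
#' mh_plus("AFDAAITDLDKLTEESYK",
#'         mods = data.frame(site = 13, mod = "phospho", n = 1))  # 2109.96
#' @export
mh_plus <- function(sequence, mods = NULL) {
  chars <- .check_sequence(sequence)
  mass <- sum(aa_residue_masses[chars]) + mass_water
  if (!is.null(mods) && nrow(mods) > 0L) {
    stopifnot(all(c("site", "mod", "n") %in% names(mods)))
    for (i in seq_len(nrow(mods))) {
      site <- mods$site[i]
      mod <- mods$mod[i]
      n <- mods$n[i]
      if (!mod %in% names(.mod_targets)) {
        stop("unknown modification: ", mod, call. = FALSE)
      }
      if (site < 1L || site > length(chars)) {
        stop("modification site ", site, " outside peptide", call. = FALSE)
      }
      if (!chars[site] %in% .mod_targets[[mod]]) {
        stop(sprintf("%s not permitted on residue '%s' at peptide position %d",
                     mod, chars[site], site), call. = FALSE)
      }
      if (mod == "phospho") {
        if (n != 1L) stop("phospho multiplicity must be 1", call. = FALSE)
        mass <- mass + delta_phospho
      } else {
        if (n < 1L) stop("glycyl multiplicity must be >= 1", call. = FALSE)
        mass <- mass + n * delta_glycyl
      }
    }
  }
  mass + mass_proton
}

#' Enumerate modified variants of a peptide
#'
#' Generates every combination of phosphorylation presence/absence on each
#' permitted S/T/Y site and polyglycine chain length on the permitted
#' glutamate(s), as a tibble sorted by MH+. By default polyglycylation is
#' considered on a single glutamate (the C-terminal-most E, matching the
#' biology of C-terminal polyglycylation); set `multi_glycyl_sites = TRUE` to
#' enumerate independent chains on every E.
#'
#' @param sequence Peptide sequence.
#' @param phospho_sites Positions allowed to carry one phospho each; `NULL`
#'   (default) means every S/T/Y in the peptide, `integer(0)` disables
#'   phosphorylation.
#' @param glycyl_range Integer length-2 vector, inclusive range of glycine
#'   counts per glycylation site (0 = unmodified rung). Default `c(0, 30)`.
#' @param glycyl_sites Positions allowed to carry a polyglycine chain; `NULL`
#'   (default) means the last E (or every E when `multi_glycyl_sites`),
#'   `integer(0)` disables glycylation.
#' @param multi_glycyl_sites Allow independent chains on several glutamates.
#' @return Tibble with columns `sequence`, `phospho_sites` (list of integer),
#'   `glycyl` (list of tibbles `site`,`n`), `n_glycines` (total), `n_phospho`,
#'   `neutral_mass`, `mh` — one row per distinct (site set, multiplicity)
#'   combination, sorted by `mh`.
#' @examples
#' enumerate_variants("AEK", glycyl_range = c(0, 2), phospho_sites = integer(0))
#' @export
enumerate_variants <- function(sequence,
                               phospho_sites = NULL,
                               glycyl_range = c(0L, 30L),
                               glycyl_sites = NULL,
                               multi_glycyl_sites = FALSE) {
  chars <- .check_sequence(sequence)
  stopifnot(length(glycyl_range) == 2L)
  if (glycyl_range[1] > glycyl_range[2] || glycyl_range[1] < 0L) {
    stop("glycyl_range must be a non-negative, non-empty range", call. = FALSE)
  }

  if (is.null(phospho_sites)) {
    phospho_sites <- which(chars %in% .mod_targets$phospho)
  } else if (length(phospho_sites) > 0L &&
             !all(chars[phospho_sites] %in% .mod_targets$phospho)) {
    stop("phospho site not on S/T/Y", call. = FALSE)
  }
  all_e <- which(chars == "E")
  if (is.null(glycyl_sites)) {
    glycyl_sites <- if (multi_glycyl_sites) all_e else utils::tail(all_e, 1L)
  } else if (length(glycyl_sites) > 0L && !all(chars[glycyl_sites] == "E")) {
    stop("glycyl site not on E", call. = FALSE)
  }
  if (!multi_glycyl_sites && length(glycyl_sites) > 1L) {
    glycyl_sites <- utils::tail(glycyl_sites, 1L)
  }

  # per-site option grids: phospho 0/1 per site, glycyl count per site
  tag <- function(prefix, sites) {
    if (length(sites) == 0L) character(0) else paste0(prefix, sites)
  }
  opts <- c(
    stats::setNames(rep(list(0:1), length(phospho_sites)),
                    tag("p", phospho_sites)),
    stats::setNames(
      rep(list(seq(glycyl_range[1], glycyl_range[2])), length(glycyl_sites)),
      tag("g", glycyl_sites)
    )
  )
  grid <- if (length(opts) == 0L) {
    data.frame(row.names = 1L)
  } else {
    expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
  }

  base <- sum(aa_residue_masses[chars]) + mass_water
  p_cols <- grep("^p", names(grid), value = TRUE)
  g_cols <- grep("^g", names(grid), value = TRUE)
  n_phos <- if (length(p_cols)) rowSums(grid[, p_cols, drop = FALSE]) else
    rep(0L, nrow(grid))
  n_gly <- if (length(g_cols)) rowSums(grid[, g_cols, drop = FALSE]) else
    rep(0L, nrow(grid))
  nm <- base + n_phos * delta_phospho + n_gly * delta_glycyl

  out <- tibble::tibble(
    sequence = sequence,
    phospho_sites = purrr::map(seq_len(max(nrow(grid), 1L)), function(i) {
      if (!length(p_cols)) return(integer(0))
      row <- unlist(grid[i, p_cols])
      as.integer(sub("^p", "", p_cols[row == 1L]))
    }),
    glycyl = purrr::map(seq_len(max(nrow(grid), 1L)), function(i) {
      if (!length(g_cols)) {
        return(tibble::tibble(site = integer(0), n = integer(0)))
      }
      row <- unlist(grid[i, g_cols])
      keep <- row > 0L
      tibble::tibble(
        site = as.integer(sub("^g", "", g_cols[keep])),
        n = as.integer(row[keep])
      )
    }),
    n_phospho = as.integer(n_phos),
    n_glycines = as.integer(n_gly),
    neutral_mass = nm,
    mh = nm + mass_proton
  )
  dplyr::arrange(dplyr::distinct(out, .data$phospho_sites, .data$glycyl,
                                 .keep_all = TRUE), .data$mh)
}
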