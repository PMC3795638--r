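#' Read protein sequences from a FASTA file
#'
#' Returns one row per record. Sequences are uppercased, intra-sequence line
#' breaks joined, and a terminal '*' stop character stripped with a warning.
#' Residue numbering throughout the package is 1-based and inclusive, so that
#' e.g. a threonine written Thr-214 in a publication is
#' `residue_at(rec, 214)`.
#'
#' The 20 standard one-letter codes are accepted; ambiguity and non-standard
#' codes (B, Z, J, U, O, X) are rejected by default with the record and
#' position named in the error. Set `strict_alphabet = FALSE` to pass them
#' through unvalidated.
#'
#' @param path Path to a FASTA text file.
#' @param strict_alphabet Reject non-standard residue letters (default TRUE).
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header), `description` (remainder of the header, possibly ""), and
#'   `sequence`.
#' @export
read_fasta <- function(path, strict_alphabet = TRUE) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  starred <- grepl("\\*$", seqs)
  if (any(starred)) {
    warning("stripping terminal '*' from record(s): ",
            paste(ids[starred], collapse = ", "), call. = FALSE)
    seqs <- sub("\\*$", "", seqs)
  }
  if (strict_alphabet) {
    for (i in seq_along(seqs)) {
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      bad <- which(!chars %in% names(aa_residue_masses))
      if (length(bad) > 0L) {
        stop(sprintf("record '%s': invalid residue '%s' at position %d",
                     ids[i], chars[bad[1]], bad[1]), call. = FALSE)
      }
    }
  }
  tibble::tibble(id = ids, description = desc, sequence = unname(seqs))
}

#' Write protein records to FASTA
#'
#' @param records Data frame with `id`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else
      records$id[i]
    writeLines(paste0(">", header), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a precomputed multiple alignment
#'
#' Reads aligned-FASTA or Clustal format into a tibble of gapped rows of equal
#' length, gap character `-`. Clustal conservation lines (asterisks, colons,
#' dots) are ignored. Column numbering over the alignment is 1-based. This
#' package reads alignments; it does not build them.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return Tibble with columns `id` and `aligned` (gapped sequence); all
#'   `aligned` strings have equal length.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "aligned-fasta") {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("no records in ", path, call. = FALSE)
    ends <- c(hdr[-1] - 1L, length(lines))
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    rows <- vapply(seq_along(hdr), function(i) {
      toupper(paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = ""))
    }, character(1))
  } else {
    lines <- readLines(path)
    # drop header line, blank lines and conservation tracks
    body <- lines[-1][nzchar(trimws(lines[-1]))]
    body <- body[grepl("^\\S+\\s+[A-Za-z-]+", body)]
    ids_all <- sub("\\s.*$", "", body)
    segs <- sub("\\s+\\d*\\s*$", "", sub("^\\S+\\s+", "", body))
    ids <- unique(ids_all)
    rows <- vapply(ids, function(id) {
      toupper(paste(segs[ids_all == id], collapse = ""))
    }, character(1))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows differ in length: ",
         paste(widths, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = unname(ids), aligned = unname(rows))
}

#' Remove gaps from aligned rows
#'
#' @param block Alignment tibble from [read_alignment()].
#' @return Tibble with `id` and ungapped `sequence`.
#' @export
degap <- function(block) {
  tibble::tibble(
    id = block$id,
    sequence = gsub("-", "", block$aligned, fixed = TRUE)
  )
}

#' Residue at a 1-based position
#'
#' @param record A single-row protein tibble (or any object with a `sequence`
#'   field), or a plain sequence string.
#' @param n 1-based position.
#' @return One-letter residue code.
#' @examples
#' residue_at("MARG", 1)  # "M"
#' @export
residue_at <- function(record, n) {
  seq <- if (is.character(record)) record[[1]] else record$sequence[[1]]
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 1L || n > nchar(seq)) {
    stop(sprintf("position %d out of range 1..%d", n, nchar(seq)),
         call. = FALSE)
  }
  substr(seq, n, n)
}
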