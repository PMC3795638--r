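#' Default pipeline run configuration
#'
#' Collects the tunable parameters shared across the pipeline into one plain
#' list, serializable to and from YAML so a run's effective configuration can
#' be echoed next to its outputs. Defaults mirror the per-function defaults:
#' matching tolerance 0.1 Da, up to 2 missed cleavages, glycine multiplicity
#' 0-30, a minimum of 3 ladder rungs, BLOSUM62 with gap open 10 / extend 0.5,
#' and physiological charge sets.
#'
#' @param ... Named overrides of default entries.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    tolerance = 0.1,
    max_missed = 2L,
    glycyl_range = c(0L, 30L),
    min_rungs = 3L,
    max_gap = 1L,
    n_max = 30L,
    x_alphabet = c("S", "T", "N", "Q", "C", "Y", "D", "E"),
    strictness = "strict",
    max_violations = 1L,
    matrix = "blosum62",
    gap_open = 10,
    gap_extend = 0.5,
    positive = c("K", "R"),
    negative = c("D", "E"),
    window = c(750, 4000),
    jitter_sd = 0.02,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config` list; for
#'   `write_run_config`, `path` invisibly.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
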