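# Run configuration: every benchmark constant in one place, defaulting to
# the values used throughout the benchmark definitions.

#' Default run configuration
#'
#' Collects the constants of the docking pipeline and benchmark suites:
#' box padding 12.5 A and minimum side 30 A; DBSCAN eps 0.25; evaluation
#' budget 5000; screening top-k 5000 and base active rate 1e-3; QED penalty
#' weight 10; LCK anchor -8.1; per-target screening thresholds (KIT -10.7,
#' PARP1 -12.1, PGR -10.1); regression target panel PARP1, F2, KIT, ESR2,
#' PGR and screening panel PARP1, KIT, PGR.
#'
#' @param ... Named overrides of individual fields.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 0L,
    backend = "mock",
    pH = 7.4,
    box_padding = 12.5,
    box_min_side = 30,
    dbscan_eps = 0.25,
    dbscan_min_core_neighbors = 5L,
    budget = 5000L,
    top_k = 5000L,
    base_rate = 0.001,
    qed_penalty_weight = 10,
    lck_anchor = -8.1,
    thresholds = c(KIT = -10.7, PARP1 = -12.1, PGR = -10.1),
    regression_targets = c("PARP1", "F2", "KIT", "ESR2", "PGR"),
    screening_targets = c("PARP1", "KIT", "PGR"),
    exhaustiveness = 8L,
    num_modes = 9L,
    energy_range = 3
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config field: %s", nm))
    cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration as flat key-value text
#'
#' @param cfg A [run_config()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  flat <- unlist(cfg)
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' @param path File written by [write_run_config()].
#' @return A named character vector of the stored fields.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, " = ", fixed = TRUE)
  stats::setNames(vapply(kv, `[[`, character(1), 2L),
                  vapply(kv, `[[`, character(1), 1L))
}
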