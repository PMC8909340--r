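## Report writers: CSV/JSON outputs with provenance.

provenance <- function(p, seed = NULL) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  save_params(p, tf)
  list(package = "pmcohort",
       version = as.character(utils::packageVersion("pmcohort")),
       config_hash = unname(tools::md5sum(tf)),
       seed = seed)
}

#' Write base-case reports
#'
#' Writes, under `dir`: `outcomes.json` (per-scenario outcomes, incremental
#' comparison, calibration constants, provenance), per-scenario trace CSVs
#' (`trace_<scenario>.csv`, one row per cycle: occupancies then entries) and
#' `cumulative.csv` (discounted cumulative cost and QALY series for both
#' scenarios).
#'
#' @param model a `pm_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(model$traces))
    utils::write.csv(as.data.frame(model$traces[[nm]]),
                     file.path(dir, paste0("trace_", nm, ".csv")),
                     row.names = FALSE)
  pc_s <- model$outcomes$standard$per_cycle
  pc_i <- model$outcomes$increased$per_cycle
  utils::write.csv(
    data.frame(cycle = pc_s$cycle,
               cum_cost_std = pc_s$cum_cost, cum_cost_inc = pc_i$cum_cost,
               cum_qaly_std = pc_s$cum_qaly, cum_qaly_inc = pc_i$cum_qaly),
    file.path(dir, "cumulative.csv"), row.names = FALSE)
  strip <- function(o) o[c("cost", "qaly", "life_years",
                           "cost_discount", "qaly_discount", "horizon")]
  jsonlite::write_json(
    list(outcomes = lapply(model$outcomes, strip),
         incremental = unclass(model$incremental),
         calibration = model$calibration,
         provenance = provenance(model$params)),
    file.path(dir, "outcomes.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write one-way sensitivity analysis results
#'
#' @param rows output of [run_owsa()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_owsa_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write PSA outputs
#'
#' Writes `psa_draws.csv` (draw, scenario, cost, qaly, life_years -- the
#' scatterplot source) and `psa_summary.json` (distributional summary plus
#' provenance) under `dir`.
#'
#' @param psa a `pm_psa`.
#' @param p the parameter set the PSA was run from.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_psa <- function(psa, p, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(psa$draws, file.path(dir, "psa_draws.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = psa$summary, n_draws = psa$n_draws,
         n_rejected = psa$n_rejected,
         provenance = provenance(p, seed = psa$seed)),
    file.path(dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
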