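## One-way (univariate) sensitivity analysis and tornado summary.

#' Default one-way sensitivity plan
#'
#' The published univariate analysis: discount rate at 0%, 3%, 5% and 7%
#' (applied to both cost and QALY streams), time horizon at 5, 10, 20 and 40
#' years, and each of the eight relative risks at its lower and upper 95%
#' confidence bound.
#'
#' @param p a `pm_params` object.
#' @return A `data.frame` with columns `parameter`, `label`, `value`.
#' @export
owsa_plan <- function(p) {
  rows <- list(
    data.frame(parameter = "discount", label = c("0%", "3%", "5%", "7%"),
               value = c(0, 0.03, 0.05, 0.07)),
    data.frame(parameter = "horizon", label = c("5y", "10y", "20y", "40y"),
               value = c(5, 10, 20, 40)))
  for (d in names(p$diseases)) for (kind in c("incidence", "mortality")) {
    rr <- p$diseases[[d]][[paste0("rr_", kind)]]
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = paste0("rr_", d, "_", kind),
                 label = c("lower95", "upper95"),
                 value = c(rr$ci_low, rr$ci_high))
  }
  do.call(rbind, rows)
}

owsa_valid_ids <- function(p) {
  c("discount", "horizon",
    as.vector(outer(paste0("rr_", names(p$diseases), "_"),
                    c("incidence", "mortality"), paste0)))
}

#' Run a one-way sensitivity analysis
#'
#' Each variation substitutes a single parameter value, holds everything else
#' (including the calibration constants) at base case, and re-runs the full
#' model under both scenarios. Discount variations apply the varied rate to
#' both the cost and the QALY stream; horizon variations truncate accrual
#' without recalibrating; relative-risk variations replace the RR point value
#' (so the standard scenario, whose RR multiplier is 1, is unchanged).
#'
#' @param p a calibrated `pm_params` (or a `pm_model`, whose calibrated
#'   parameters are used).
#' @param plan a variation plan as from [owsa_plan()].
#' @return A `data.frame` with one row per variation and scenario: `parameter`,
#'   `label`, `scenario`, `cost`, `qaly`, `incr_cost`, `pct_cost`, `incr_qaly`,
#'   `pct_qaly` (incrementals on increased-scenario rows only).
#' @export
#' @examples
#' \donttest{
#' m <- pm_model()
#' sa <- run_owsa(m)
#' subset(sa, parameter == "discount")
#' }
run_owsa <- function(p, plan = NULL) {
  if (inherits(p, "pm_model")) p <- p$params
  if (is.null(plan)) plan <- owsa_plan(p)
  valid <- owsa_valid_ids(p)
  bad <- setdiff(unique(plan$parameter), valid)
  if (length(bad))
    stop("unknown parameter id(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(valid, collapse = ", "))

  base_traces <- list(standard = run_cohort(p, "standard"),
                      increased = run_cohort(p, "increased"))
  out <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    par_id <- plan$parameter[r]; val <- plan$value[r]
    if (par_id == "discount") {
      oo <- lapply(base_traces, accrue_outcomes, p = p,
                   cost_discount = val, qaly_discount = val)
    } else if (par_id == "horizon") {
      oo <- lapply(base_traces, accrue_outcomes, p = p, horizon = val)
    } else {
      d <- sub("^rr_(.*)_(incidence|mortality)$", "\\1", par_id)
      kind <- sub("^rr_.*_(incidence|mortality)$", "\\1", par_id)
      p2 <- p
      p2$diseases[[d]][[paste0("rr_", kind)]]$point <- val
      oo <- list(standard = accrue_outcomes(run_cohort(p2, "standard"), p2),
                 increased = accrue_outcomes(run_cohort(p2, "increased"), p2))
    }
    inc <- compare_scenarios(oo$standard, oo$increased)
    out[[r]] <- data.frame(
      parameter = par_id, label = plan$label[r],
      scenario = c("standard", "increased"),
      cost = c(oo$standard$cost, oo$increased$cost),
      qaly = c(oo$standard$qaly, oo$increased$qaly),
      incr_cost = c(NA, inc$delta_cost), pct_cost = c(NA, inc$pct_cost),
      incr_qaly = c(NA, inc$delta_qaly), pct_qaly = c(NA, inc$pct_qaly))
  }
  do.call(rbind, out)
}

#' Tornado summary of a one-way sensitivity analysis
#'
#' For every parameter varied to paired lower/upper bounds, the minimum and
#' maximum incremental outcome and their spread, sorted by spread descending.
#'
#' @param rows output of [run_owsa()] (must contain a `lower95` and an
#'   `upper95` row pair per relative-risk parameter).
#' @param outcome `"cost"` or `"qaly"`.
#' @return A `data.frame` with `parameter`, `low`, `high`, `spread`.
#' @export
tornado_table <- function(rows, outcome = c("cost", "qaly")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "cost") "incr_cost" else "incr_qaly"
  rr <- rows[rows$label %in% c("lower95", "upper95") &
               rows$scenario == "increased", ]
  if (nrow(rr) == 0) stop("no bound variations present")
  out <- do.call(rbind, lapply(split(rr, rr$parameter), function(g) {
    if (!setequal(g$label, c("lower95", "upper95")))
      stop("unpaired bounds for parameter '", g$parameter[1], "'")
    v <- g[[col]]
    data.frame(parameter = g$parameter[1], low = min(v), high = max(v),
               spread = max(v) - min(v))
  }))
  out[order(-out$spread), , drop = FALSE]
}
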