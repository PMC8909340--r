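## Front-end model object: calibrate once, run both scenarios, compare.

#' Fit the lifetime PM2.5 cohort model
#'
#' Calibrates the unprinted ancillary inputs to their anchors (see
#' [calibrate_model()]), propagates the cohort under both exposure scenarios,
#' accrues costs, QALYs and life years, and returns everything as a single
#' model object with the usual methods (`print`, `summary`, `coef`, `plot`,
#' `predict`, `simulate`).
#'
#' @param params a `pm_params` object; defaults to the packaged inputs.
#' @param calibrate logical; set `FALSE` to run with the background and
#'   utility scales already present in `params`.
#' @return An object of class `pm_model`: list with the calibrated `params`,
#'   per-scenario `traces` and `outcomes`, the `incremental` comparison and
#'   the `calibration` constants.
#' @export
#' @examples
#' \donttest{
#' m <- pm_model()
#' m
#' coef(m)
#' }
pm_model <- function(params = pm_params(), calibrate = TRUE) {
  bad <- validate_params(params)
  if (length(bad))
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "))
  if (calibrate) params <- calibrate_model(params) else
    params <- ensure_gompertz_a(params)
  traces <- list(standard = run_cohort(params, "standard"),
                 increased = run_cohort(params, "increased"))
  outcomes <- lapply(traces, accrue_outcomes, p = params)
  structure(list(params = params,
                 traces = traces,
                 outcomes = outcomes,
                 incremental = compare_scenarios(outcomes$standard,
                                                 outcomes$increased),
                 calibration = attr(params, "calibration")),
            class = "pm_model")
}

#' @export
print.pm_model <- function(x, ...) {
  s <- x$params$settings
  cat("Lifetime PM2.5 Markov cohort model\n")
  cat(sprintf("  cohort of %d women aged %d, %d annual cycles; cost discount %.0f%%, QALY discount %.0f%%\n",
              s$cohort_size, s$start_age, s$horizon,
              100 * s$cost_discount, 100 * s$qaly_discount))
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated to %s scenario: life years %.2f, QALYs %.2f (k=%.4f, u=%.4f)\n",
                x$calibration$scenario, x$calibration$target_ly,
                x$calibration$target_qaly, x$calibration$hazard_scale,
                x$calibration$utility_scale))
  for (nm in names(x$outcomes)) {
    o <- x$outcomes[[nm]]
    cat(sprintf("  %-9s (%2g ug/m3): cost %8.0f USD, QALYs %6.2f, life years %6.2f\n",
                nm, x$params$scenarios[[nm]]$concentration, o$cost, o$qaly,
                o$life_years))
  }
  print(x$incremental)
  invisible(x)
}

#' @export
coef.pm_model <- function(object, ...) {
  cal <- object$calibration
  if (is.null(cal))
    cal <- list(gompertz_a = object$params$background$gompertz_a,
                hazard_scale = object$params$background$calibration_scale,
                utility_scale = object$params$background$utility_scale)
  c(gompertz_a = cal$gompertz_a, hazard_scale = cal$hazard_scale,
    utility_scale = cal$utility_scale)
}

#' @export
summary.pm_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$outcomes), function(nm) {
    o <- object$outcomes[[nm]]
    data.frame(scenario = nm,
               concentration = object$params$scenarios[[nm]]$concentration,
               cost = o$cost, qaly = o$qaly, life_years = o$life_years)
  }))
  structure(list(table = tab, incremental = object$incremental,
                 calibration = object$calibration,
                 settings = object$params$settings),
            class = "summary.pm_model")
}

#' @export
print.summary.pm_model <- function(x, ...) {
  cat("Scenario outcomes (per person):\n")
  print(x$table, row.names = FALSE, digits = 6)
  print(x$incremental)
  if (!is.null(x$calibration))
    cat(sprintf("calibration: a=%.6g, k=%.6g, u=%.6g (anchors: %.2f life years, %.2f QALYs, lifetable LE %.1f)\n",
                x$calibration$gompertz_a, x$calibration$hazard_scale,
                x$calibration$utility_scale, x$calibration$target_ly,
                x$calibration$target_qaly, x$calibration$lifetable_le))
  invisible(x)
}

#' Re-evaluate a fitted model under altered run conditions
#'
#' Re-runs or re-accrues the calibrated model for a single scenario with an
#' optionally truncated horizon and altered discount rates; the calibration is
#' frozen at its base-case values.
#'
#' @param object a `pm_model`.
#' @param scenario scenario name.
#' @param horizon accrual horizon in cycles (defaults to the full run).
#' @param cost_discount,qaly_discount annual discount rates (default run
#'   settings).
#' @param ... unused.
#' @return A `pm_outcomes` object.
#' @export
predict.pm_model <- function(object, scenario = "increased", horizon = NULL,
                             cost_discount = NULL, qaly_discount = NULL, ...) {
  accrue_outcomes(object$traces[[scenario]] %||% run_cohort(object$params, scenario),
                  object$params, cost_discount = cost_discount,
                  qaly_discount = qaly_discount, horizon = horizon)
}

#' Simulate parameter uncertainty (probabilistic sensitivity analysis)
#'
#' `simulate()` on a fitted model runs the second-order Monte Carlo PSA: see
#' [run_psa()].
#'
#' @param object a `pm_model`.
#' @param nsim number of parameter draws.
#' @param seed integer seed (required for reproducibility).
#' @param ... passed to [run_psa()].
#' @return A `pm_psa` object.
#' @export
simulate.pm_model <- function(object, nsim = 1000, seed = 1L, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed, ...)
}

#' Plot cumulative cost and QALY curves
#'
#' Two panels mirroring the cumulative lifetime trajectories: discounted
#' cumulative healthcare cost and cumulative QALYs per person, by cycle, one
#' line per exposure scenario.
#'
#' @param x a `pm_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pm_model <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pc_s <- x$outcomes$standard$per_cycle
  pc_i <- x$outcomes$increased$per_cycle
  graphics::matplot(pc_s$cycle, cbind(pc_s$cum_cost, pc_i$cum_cost),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "cycle (years)", ylab = "cumulative cost (USD)",
                    main = "Healthcare cost", ...)
  graphics::legend("topleft", c("standard", "increased"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(pc_s$cycle, cbind(pc_s$cum_qaly, pc_i$cum_qaly),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "cycle (years)", ylab = "cumulative QALYs",
                    main = "Quality-adjusted life years", ...)
  invisible(x)
}
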