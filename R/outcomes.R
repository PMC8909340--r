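## Reward accrual: discounted costs, QALYs, life years; scenario comparison.

#' Discount factor for a cycle
#'
#' Rewards accrued during cycle `t` (`t = 1..horizon`) are multiplied by
#' `(1 + rate)^(-t)`. Cycle 0 accrues nothing (the cohort starts event-free
#' and accrual begins with the first transition), so `cycle = 0` is an error.
#'
#' @param rate annual discount rate, `>= 0`.
#' @param cycle integer cycle index, `>= 1`; vectorised.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(0.05, 1)  # 1/1.05
discount_factor <- function(rate, cycle) {
  if (rate < 0) stop("rate must be >= 0")
  if (any(cycle < 1)) stop("cycle must be >= 1; cycle-0 occupancy accrues nothing")
  (1 + rate)^(-cycle)
}

## per-age utility weights for the 8 alive states (baseline template scaled by
## u and clipped to [0,1]; disease utilities capped at the scaled baseline)
alive_utilities <- function(p, ages) {
  u <- p$background$utility_scale
  bu <- pmin(1, u * schedule_value(p$rewards$baseline_utility, ages))
  su <- p$rewards$state_utilities[setdiff(PM_ALIVE, "event_free")]
  m <- cbind(event_free = bu,
             outer(bu, unlist(su), pmin))
  colnames(m) <- PM_ALIVE
  m
}

#' Accrue outcomes over a cohort trace
#'
#' Per cycle `t`, costs are the occupancy-weighted annual state costs plus the
#' one-time death costs charged on entry into the cause-specific dead states,
#' discounted at the cost rate; QALYs are the occupancy-weighted utilities
#' (event-free occupancy uses the age-specific scaled baseline utility;
#' disease-state utilities are capped at that baseline), discounted at the
#' QALY rate; life years are the undiscounted alive mass.
#'
#' @param trace a `pm_trace` from [run_cohort()].
#' @param p the `pm_params` the trace was produced from.
#' @param cost_discount,qaly_discount annual rates; default to the run
#'   settings.
#' @param horizon accrue only the first `horizon` cycles of the trace
#'   (defaults to the full trace).
#' @return An object of class `pm_outcomes`: list with `cost`, `qaly`,
#'   `life_years`, the `scenario` label and a `per_cycle` data frame (cycle,
#'   age, discounted per-cycle and cumulative cost and QALYs, alive fraction).
#' @export
accrue_outcomes <- function(trace, p, cost_discount = NULL,
                            qaly_discount = NULL, horizon = NULL) {
  s <- p$settings
  h_tr <- nrow(trace$entries)
  h <- if (is.null(horizon)) h_tr else horizon
  if (h > h_tr) stop("horizon exceeds the trace length (", h_tr, ")")
  cd <- cost_discount %||% s$cost_discount
  qd <- qaly_discount %||% s$qaly_discount

  cyc <- seq_len(h)
  ages <- trace$start_age + cyc
  occ <- trace$occupancy[1 + cyc, , drop = FALSE]
  ent <- trace$entries[cyc, , drop = FALSE]

  sc <- numeric(13); names(sc) <- PM_STATES
  sc[names(p$rewards$state_costs)] <- p$rewards$state_costs
  dc <- numeric(13); names(dc) <- PM_STATES
  dc[names(p$rewards$death_costs)] <- p$rewards$death_costs

  cost_t <- drop(occ %*% sc) + drop(ent %*% dc)
  um <- alive_utilities(p, ages)
  qaly_t <- rowSums(occ[, 1:8, drop = FALSE] * um)
  alive_t <- rowSums(occ[, 1:8, drop = FALSE])

  df_c <- discount_factor(cd, cyc)
  df_q <- discount_factor(qd, cyc)
  per_cycle <- data.frame(cycle = cyc, age = ages,
                          cost = cost_t * df_c, qaly = qaly_t * df_q,
                          cum_cost = cumsum(cost_t * df_c),
                          cum_qaly = cumsum(qaly_t * df_q),
                          alive = alive_t)
  structure(list(cost = sum(cost_t * df_c), qaly = sum(qaly_t * df_q),
                 life_years = sum(alive_t),
                 cost_discount = cd, qaly_discount = qd,
                 scenario = trace$scenario, horizon = h,
                 per_cycle = per_cycle),
            class = "pm_outcomes")
}

#' @export
print.pm_outcomes <- function(x, ...) {
  cat(sprintf("outcomes (%s, %d cycles): cost %.0f USD (%.0f%% disc.), QALYs %.2f (%.0f%% disc.), life years %.2f\n",
              x$scenario, x$horizon, x$cost, 100 * x$cost_discount,
              x$qaly, 100 * x$qaly_discount, x$life_years))
  invisible(x)
}

#' Incremental comparison of two scenarios
#'
#' Differences are increased minus standard; percentages are relative to the
#' standard scenario.
#'
#' @param std,inc `pm_outcomes` for the standard and increased scenarios,
#'   accrued under the same settings.
#' @return An object of class `pm_incremental` with `delta_cost`, `pct_cost`,
#'   `delta_qaly`, `pct_qaly`, `delta_life_years`.
#' @export
compare_scenarios <- function(std, inc) {
  if (std$horizon != inc$horizon ||
      std$cost_discount != inc$cost_discount ||
      std$qaly_discount != inc$qaly_discount)
    stop("outcomes were accrued under different settings")
  if (std$cost == 0) stop("standard-scenario cost is zero; percentage undefined")
  if (std$qaly == 0) stop("standard-scenario QALYs are zero; percentage undefined")
  structure(list(delta_cost = inc$cost - std$cost,
                 pct_cost = 100 * (inc$cost - std$cost) / std$cost,
                 delta_qaly = inc$qaly - std$qaly,
                 pct_qaly = 100 * (inc$qaly - std$qaly) / std$qaly,
                 delta_life_years = inc$life_years - std$life_years),
            class = "pm_incremental")
}

#' @export
print.pm_incremental <- function(x, ...) {
  cat(sprintf("incremental (increased - standard): cost %+.0f USD (%+.1f%%), QALYs %+.2f (%+.1f%%), life years %+.2f\n",
              x$delta_cost, x$pct_cost, x$delta_qaly, x$pct_qaly,
              x$delta_life_years))
  invisible(x)
}
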