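## Transition matrices and cohort propagation.

## per-cycle inputs for a run: incidence/mortality probabilities after RR
## scaling (cycles x 4) and background probabilities (cycles)
cycle_inputs <- function(p, scenario, horizon) {
  ages <- p$settings$start_age + seq_len(horizon) - 1
  mult <- scenario_multipliers(p, scenario)
  iv <- vapply(PM_DISEASES, function(d)
    disease_prob(p, d, "incidence", ages) * mult$incidence[[d]],
    numeric(length(ages)))
  mv <- vapply(PM_DISEASES, function(d)
    disease_prob(p, d, "mortality", ages) * mult$mortality[[d]],
    numeric(length(ages)))
  q0 <- background_prob(p$background, ages)
  list(ages = ages, iv = iv, mv = mv, q0 = q0)
}

stop_infeasible <- function(state, age, scenario, total) {
  stop(structure(class = c("pmcohort_infeasible", "error", "condition"),
                 list(message = paste0("infeasible parameters: exit probability ",
                                       signif(total, 6), " > 1 from state '",
                                       state, "' at age ", age, " (scenario ",
                                       scenario, ")"),
                      call = NULL)))
}

check_feasible <- function(ci, scenario_label) {
  ef_exit <- rowSums(ci$iv) + ci$q0
  if (any(ef_exit > 1 + 1e-12)) {
    j <- which.max(ef_exit)
    stop_infeasible("event_free", ci$ages[j], scenario_label, ef_exit[j])
  }
  for (i in seq_along(PM_DISEASES)) {
    ex <- ci$mv[, i] + ci$q0
    if (any(ex > 1 + 1e-12)) {
      j <- which.max(ex)
      stop_infeasible(PM_ENTRY_STATE[[PM_DISEASES[i]]], ci$ages[j],
                      scenario_label, ex[j])
    }
  }
}

#' One-cycle transition matrix
#'
#' Builds the 13 x 13 transition matrix at a given age under a scenario. From
#' the event-free state the cohort moves to each disease entry state with the
#' RR-scaled incidence probability and to other-cause death with the
#' background probability; the remainder stays. Disease states exit to their
#' cause-specific death state with the RR-scaled mortality probability and to
#' other-cause death with the background probability; first-year states pass
#' their survivors to the chronic state, chronic states retain them. Death
#' states are absorbing. There are no cross-disease transitions.
#'
#' @param p a `pm_params` object with resolved background (see
#'   [calibrate_model()]).
#' @param age age in years at the start of the cycle.
#' @param scenario scenario name (`"standard"` or `"increased"`).
#' @return A 13 x 13 row-stochastic matrix with state dimnames.
#' @export
transition_matrix <- function(p, age, scenario = "standard") {
  s <- p$settings
  if (age < s$start_age || age >= s$start_age + s$horizon)
    stop("age ", age, " outside the model horizon [", s$start_age, ", ",
         s$start_age + s$horizon, ")")
  sc <- resolve_scenario(p, scenario)
  mult <- scenario_multipliers(p, sc)
  iv <- vapply(PM_DISEASES, function(d)
    disease_prob(p, d, "incidence", age) * mult$incidence[[d]], numeric(1))
  mv <- vapply(PM_DISEASES, function(d)
    disease_prob(p, d, "mortality", age) * mult$mortality[[d]], numeric(1))
  q0 <- background_prob(p$background, age)

  if (sum(iv) + q0 > 1 + 1e-12)
    stop_infeasible("event_free", age, sc$label, sum(iv) + q0)

  P <- matrix(0, 13, 13, dimnames = list(PM_STATES, PM_STATES))
  P["event_free", PM_ENTRY_STATE] <- iv
  P["event_free", "dead_other"] <- q0
  P["event_free", "event_free"] <- 1 - sum(iv) - q0
  for (i in seq_along(PM_DISEASES)) {
    d <- PM_DISEASES[i]
    if (mv[i] + q0 > 1 + 1e-12)
      stop_infeasible(PM_ENTRY_STATE[[d]], age, sc$label, mv[i] + q0)
    for (st in unique(c(PM_ENTRY_STATE[[d]], PM_CHRONIC_STATE[[d]]))) {
      P[st, PM_DEAD_STATE[[d]]] <- mv[i]
      P[st, "dead_other"] <- q0
      P[st, PM_CHRONIC_STATE[[d]]] <- P[st, PM_CHRONIC_STATE[[d]]] + 1 - mv[i] - q0
    }
  }
  for (st in PM_DEAD) P[st, st] <- 1
  P
}

#' Propagate the cohort over the horizon
#'
#' Starts the whole cohort event-free and applies the age-specific transition
#' matrix once per annual cycle. Returns the occupancy trace (fractions of the
#' cohort per state at cycles `0..horizon`) and the per-cycle entry matrix
#' (mass newly entering each state that cycle), which drives one-time death
#' costs and the epidemiological validation rates.
#'
#' @param p a `pm_params` object; background must be resolved (calibrated or
#'   with `gompertz_a` set).
#' @param scenario scenario name.
#' @param horizon number of cycles; defaults to the run settings.
#' @return An object of class `pm_trace`: list with `occupancy`
#'   (`(horizon+1) x 13`), `entries` (`horizon x 13`), `ages`, `scenario`.
#' @export
#' @examples
#' \donttest{
#' p <- calibrate_model(pm_params())
#' tr <- run_cohort(p, "standard")
#' rowSums(tr$occupancy)[1:5]  # mass conservation
#' }
run_cohort <- function(p, scenario = "standard", horizon = NULL) {
  s <- p$settings
  h <- if (is.null(horizon)) s$horizon else horizon
  sc <- resolve_scenario(p, scenario)
  ci <- cycle_inputs(p, sc, h)
  check_feasible(ci, sc$label)

  occ <- matrix(0, h + 1, 13, dimnames = list(0:h, PM_STATES))
  ent <- matrix(0, h, 13, dimnames = list(1:h, PM_STATES))
  v <- c(1, numeric(12))
  occ[1, ] <- v
  for (t in seq_len(h)) {
    i <- ci$iv[t, ]; m <- ci$mv[t, ]; q <- ci$q0[t]
    ef <- v[1]
    lc_surv <- 1 - m[1] - q; mi_surv <- 1 - m[2] - q
    st_surv <- 1 - m[3] - q; cp_surv <- 1 - m[4] - q
    lc1_in <- ef * i[1]; mi1_in <- ef * i[2]; st1_in <- ef * i[3]
    cp_in <- ef * i[4]
    lcL_in <- v[2] * lc_surv; miP_in <- v[4] * mi_surv; stP_in <- v[6] * st_surv
    d_lc <- (v[2] + v[3]) * m[1]; d_chd <- (v[4] + v[5]) * m[2]
    d_cvd <- (v[6] + v[7]) * m[3]; d_cp <- v[8] * m[4]
    d_oth <- sum(v[1:8]) * q
    v <- c(ef * (1 - sum(i) - q),
           lc1_in, lcL_in + v[3] * lc_surv,
           mi1_in, miP_in + v[5] * mi_surv,
           st1_in, stP_in + v[7] * st_surv,
           cp_in + v[8] * cp_surv,
           v[9] + d_lc, v[10] + d_chd, v[11] + d_cvd, v[12] + d_cp,
           v[13] + d_oth)
    occ[t + 1, ] <- v
    ent[t, ] <- c(0, lc1_in, lcL_in, mi1_in, miP_in, st1_in, stP_in, cp_in,
                  d_lc, d_chd, d_cvd, d_cp, d_oth)
  }
  structure(list(occupancy = occ, entries = ent,
                 ages = s$start_age + 0:h, scenario = sc$label,
                 start_age = s$start_age),
            class = "pm_trace")
}

## undiscounted person-years: alive mass summed over cycles 1..horizon
trace_life_years <- function(trace, horizon = NULL) {
  h <- if (is.null(horizon)) nrow(trace$entries) else horizon
  sum(trace$occupancy[1 + seq_len(h), 1:8])
}

#' @export
print.pm_trace <- function(x, ...) {
  h <- nrow(x$entries)
  dead <- sum(x$occupancy[h + 1, 9:13])
  cat(sprintf("cohort trace: scenario '%s', %d cycles from age %d\n",
              x$scenario, h, x$start_age))
  cat(sprintf("  life years %.2f, dead fraction at end %.3f\n",
              trace_life_years(x), dead))
  invisible(x)
}

#' Cohort trace as a data frame
#'
#' One row per cycle: cycle index, age, the 13 state occupancies, then the 13
#' per-cycle entry columns (prefixed `entry_`; zero at cycle 0).
#'
#' @param x a `pm_trace`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return A `data.frame` with `horizon + 1` rows.
#' @export
as.data.frame.pm_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  h <- nrow(x$entries)
  ent <- rbind(matrix(0, 1, 13), x$entries)
  colnames(ent) <- paste0("entry_", PM_STATES)
  data.frame(cycle = 0:h, age = x$ages, x$occupancy, ent,
             check.names = FALSE, row.names = row.names)
}
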