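## Synthetic parameter generation and a microsimulation cross-check.
##
## The generator emulates the structure of the published inputs -- incidence
## and mortality schedules that rise with age, relative risks above 1 with
## log-symmetric confidence intervals, nonnegative costs, utilities in
## [0, 1] -- so every stage of the pipeline is testable on fresh random but
## valid parameter sets. It draws from a private RNG stream, so generating
## fixtures never perturbs the reproducibility of a PSA run.

rand_schedule <- function(bands, scale, constant = FALSE) {
  v <- if (constant) rep(stats::runif(1, 0.3, 1) * scale, length(bands)) else
    cumsum(stats::runif(length(bands), 0.2, 1)) * scale
  age_schedule(bands, pmin(v, 0.95))
}

rand_rr <- function(per_increment = 10) {
  point <- stats::runif(1, 1.0, 2.0)
  s <- stats::runif(1, 0.02, 0.25)
  z <- stats::qnorm(0.975)
  structure(list(point = point, ci_low = point * exp(-z * s),
                 ci_high = point * exp(z * s), per_increment = per_increment),
            class = "pm_rr")
}

#' Generate a random, valid parameter set
#'
#' Deterministic given `seed`. `severity` controls the magnitude of the
#' disease schedules: `"mild"` keeps all probabilities small, `"paper_like"`
#' matches the order of magnitude of the published tables, and `"extreme"`
#' pushes rates high enough to stress exit-probability feasibility, then
#' rescales every schedule so the largest total exit probability over all
#' ages and both scenarios is at most 0.99.
#'
#' @param seed integer seed.
#' @param severity one of `"mild"`, `"paper_like"`, `"extreme"`.
#' @return A validated `pm_params` object.
#' @export
#' @examples
#' p <- random_param_set(1)
#' validate_params(p)  # character(0)
random_param_set <- function(seed,
                             severity = c("paper_like", "mild", "extreme")) {
  severity <- match.arg(severity)
  with_local_seed(seed, {
    inc_scale <- switch(severity, mild = 2e-4, paper_like = 5e-3, extreme = 0.15)
    mor_scale <- switch(severity, mild = 2e-3, paper_like = 3e-2, extreme = 0.4)
    bands <- c(40, 50, 60, 70, 80)
    diseases <- list()
    for (d in PM_DISEASES) {
      diseases[[d]] <- list(
        incidence = rand_schedule(bands, inc_scale),
        mortality = rand_schedule(bands, mor_scale,
                                  constant = stats::runif(1) < 0.25),
        rr_incidence = rand_rr(sample(c(5, 10), 1)),
        rr_mortality = rand_rr(sample(c(5, 10), 1)))
    }
    su <- round(stats::runif(7, 0.3, 0.9), 3)
    names(su) <- setdiff(PM_ALIVE, "event_free")
    scost <- c(event_free = 0,
               round(stats::rgamma(7, shape = 2, scale = 3000)))
    names(scost) <- PM_ALIVE
    dcost <- c(round(stats::rgamma(4, shape = 2, scale = 2000)), 0)
    names(dcost) <- PM_DEAD
    x <- list(
      settings = list(start_age = 40, horizon = 60, cycle_length = 1,
                      cost_discount = 0.05, qaly_discount = 0,
                      cohort_size = 10000),
      scenarios = list(
        standard = list(label = "standard", concentration = 15,
                        reference_concentration = 15),
        increased = list(label = "increased", concentration = 25,
                         reference_concentration = 15)),
      diseases = diseases,
      rewards = list(
        state_costs = as.list(scost),
        death_costs = as.list(dcost),
        state_utilities = as.list(su),
        baseline_utility = list(
          age_lower = bands,
          value = sort(round(stats::runif(5, 0.7, 1), 3), decreasing = TRUE))),
      background = list(mode = "gompertz_makeham",
                        makeham_c = stats::runif(1, 1e-4, 1e-3),
                        gompertz_a = stats::runif(1, 2e-4, 1e-3),
                        gompertz_b = stats::runif(1, 0.05, 0.12),
                        calibration_scale = 1, utility_scale = 1),
      calibration = list(scenario = "standard", target_ly = 41.34,
                         target_qaly = 32.08, lifetable_le = 47.3))

    ## rescale the disease schedules so the worst-case total exit probability
    ## stays below 0.99; the background term is not scaled, so headroom is
    ## computed net of the largest background probability
    p0 <- as_pm_params_unchecked(x)
    worst <- max_exit_probability(p0)
    if (worst > 0.99) {
      ages <- 40 + 0:59
      qmax <- max(background_prob(p0$background, ages))
      f <- (0.99 - qmax) / (worst - qmax)
      for (d in PM_DISEASES) {
        x$diseases[[d]]$incidence$value <- x$diseases[[d]]$incidence$value * f
        x$diseases[[d]]$mortality$value <- x$diseases[[d]]$mortality$value * f
      }
    }
    as_pm_params(x)
  })
}

## structural assembly without invariant checking (generator internals)
as_pm_params_unchecked <- function(x) {
  p <- x
  class(p) <- "pm_params"
  p
}

## largest total exit probability from any alive state over all ages of the
## horizon, under both scenarios
max_exit_probability <- function(p) {
  s <- p$settings
  ages <- s$start_age + seq_len(s$horizon) - 1
  q0 <- background_prob(p$background, ages)
  worst <- 0
  for (nm in c("standard", "increased")) {
    mult <- scenario_multipliers(p, nm)
    iv <- vapply(PM_DISEASES, function(d)
      schedule_value(p$diseases[[d]]$incidence, ages) * mult$incidence[[d]],
      numeric(length(ages)))
    mv <- vapply(PM_DISEASES, function(d)
      schedule_value(p$diseases[[d]]$mortality, ages) * mult$mortality[[d]],
      numeric(length(ages)))
    worst <- max(worst, rowSums(iv) + q0, mv + q0)
  }
  worst
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` independent individuals by per-cycle categorical
#' draws from the rows of [transition_matrix()] (individuals are exchangeable,
#' so the per-state counts are propagated with multinomial draws, which is an
#' exact simulation). The deterministic cohort trace is the expectation of
#' this process; occupancy discrepancies should stay within a few binomial
#' standard errors.
#'
#' @param p a `pm_params` with resolved background.
#' @param scenario scenario name.
#' @param n_individuals number of simulated individuals.
#' @param cycles number of cycles (small horizons recommended).
#' @param seed integer seed (private stream).
#' @return List with `occupancy` (`(cycles+1) x 13` fractions), `se`
#'   (binomial standard errors of each fraction), and `n`.
#' @export
microsim_oracle <- function(p, scenario = "standard", n_individuals = 1e5,
                            cycles = 10, seed = 1L) {
  s <- p$settings
  counts <- c(n_individuals, numeric(12))
  occ <- matrix(0, cycles + 1, 13, dimnames = list(0:cycles, PM_STATES))
  occ[1, ] <- counts / n_individuals
  with_local_seed(seed, {
    for (t in seq_len(cycles)) {
      P <- transition_matrix(p, s$start_age + t - 1, scenario)
      newc <- numeric(13)
      for (st in which(counts > 0)) {
        if (P[st, st] == 1) { newc[st] <- newc[st] + counts[st]; next }
        newc <- newc + drop(stats::rmultinom(1, counts[st], P[st, ]))
      }
      counts <- newc
      occ[t + 1, ] <- counts / n_individuals
    }
  })
  list(occupancy = occ,
       se = sqrt(occ * (1 - occ) / n_individuals),
       n = n_individuals)
}
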