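## Fixtures built in code: toy parameter sets with analytically tractable
## dynamics, used throughout the suite.

## A structurally complete parameter list; every rate constant and small, so
## closed forms are easy. Background is a constant-probability table so no
## Gompertz resolution is involved unless asked for.
toy_params_list <- function(incidence = 0, disease_mortality = 0,
                            background_q = 0,
                            event_free_cost = 0, state_cost = 0,
                            death_cost = 0,
                            state_utility = 1, baseline_utility = 1,
                            horizon = 60, cost_discount = 0.05,
                            qaly_discount = 0) {
  dis <- function() list(
    incidence = list(age_lower = 40, value = incidence),
    mortality = list(age_lower = 40, value = disease_mortality),
    rr_incidence = list(point = 1.5, ci_low = 1.2, ci_high = 1.875,
                        per_increment = 10),
    rr_mortality = list(point = 1.0, ci_low = 0.9, ci_high = 1.15,
                        per_increment = 10))
  su <- rep(state_utility, 7)
  names(su) <- setdiff(state_space("alive"), "event_free")
  sc <- c(event_free = event_free_cost, rep(state_cost, 7))
  names(sc) <- state_space("alive")
  dc <- c(rep(death_cost, 4), 0)
  names(dc) <- state_space("dead")
  list(
    settings = list(start_age = 40, horizon = horizon, cycle_length = 1,
                    cost_discount = cost_discount,
                    qaly_discount = qaly_discount, cohort_size = 10000),
    scenarios = list(
      standard = list(label = "standard", concentration = 15,
                      reference_concentration = 15),
      increased = list(label = "increased", concentration = 25,
                       reference_concentration = 15)),
    diseases = list(lung_cancer = dis(), mi = dis(), stroke = dis(),
                    copd = dis()),
    rewards = list(state_costs = as.list(sc), death_costs = as.list(dc),
                   state_utilities = as.list(su),
                   baseline_utility = list(age_lower = 40,
                                           value = baseline_utility)),
    background = list(mode = "table", makeham_c = 5e-4, gompertz_a = 1e-3,
                      gompertz_b = 0.09, calibration_scale = 1,
                      utility_scale = 1,
                      table = list(age_lower = 40, value = background_q)),
    calibration = list(scenario = "standard", target_ly = 41.34,
                       target_qaly = 32.08, lifetable_le = 47.3))
}

toy_params <- function(...) as_pm_params(toy_params_list(...))

## the packaged inputs, calibrated once per test session
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_model(pm_params())
    cache
  }
})

fitted_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pm_model(pm_params())
    cache
  }
})

## assemble without the validity gate (for tests that probe validate_params)
as_pm_params_quiet <- function(x) pmcohort:::as_pm_params_struct(x)
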