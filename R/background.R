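## Other-cause mortality and baseline-utility calibration.
##
## The published model relies on two inputs that are not printed: the Korean
## female other-cause mortality schedule and the age-specific baseline EQ-5D
## utilities of the event-free population. Both are supplied here in
## parametric form and pinned to printed anchors: a Gompertz-Makeham hazard
## whose unscaled level reproduces the lifetable life expectancy at the start
## age, a multiplicative scale k set so the standard scenario reproduces its
## published undiscounted life years, and a utility scale u applied to a
## declining by-decade template so the standard scenario reproduces its
## published undiscounted QALYs.

#' Annual other-cause death probability
#'
#' In `gompertz_makeham` mode the annual hazard at age `x` is
#' `k * (c + a * exp(b * (x - start)))` with `start = 40`, converted to a
#' probability as `1 - exp(-hazard)`. In `table` mode the probability is read
#' from the supplied age schedule.
#'
#' @param bm the `background` component of a `pm_params` object.
#' @param age numeric vector of ages, each `>= 40`.
#' @return Annual probability of death from other causes at each age.
#' @export
background_prob <- function(bm, age) {
  if (any(age < 40)) stop("age below the cohort start age (40)")
  if (identical(bm$mode, "table")) {
    if (is.null(bm$table)) stop("background mode 'table' has no table")
    return(bm$calibration_scale * schedule_value(bm$table, age))
  }
  if (is.na(bm$gompertz_a))
    stop("background Gompertz scale 'a' is unresolved; calibrate first ",
         "(see calibrate_model)")
  h <- bm$calibration_scale *
    (bm$makeham_c + bm$gompertz_a * exp(bm$gompertz_b * (age - 40)))
  1 - exp(-h)
}

## remaining life expectancy at the start age under background mortality only,
## truncated at the model horizon
background_le <- function(bm, start_age = 40, horizon = 60) {
  q <- background_prob(bm, start_age + seq_len(horizon) - 1)
  sum(cumprod(1 - q))
}

## Resolve the Gompertz hazard scale `a` so that the unscaled (k = 1)
## background-only remaining life expectancy at the start age matches the
## lifetable anchor. No-op when `a` is already set.
ensure_gompertz_a <- function(p) {
  bm <- p$background
  if (bm$mode != "gompertz_makeham" || !is.na(bm$gompertz_a)) return(p)
  target <- p$calibration$lifetable_le
  s <- p$settings
  f <- function(a) {
    bm2 <- bm; bm2$gompertz_a <- a; bm2$calibration_scale <- 1
    background_le(bm2, s$start_age, s$horizon) - target
  }
  if (f(0) < 0)
    stop("lifetable anchor ", target,
         " years is unattainable even with zero age-dependent hazard")
  p$background$gompertz_a <-
    stats::uniroot(f, c(1e-8, 1), tol = 1e-13, extendInt = "downX")$root
  p
}

#' Calibrate the background-mortality scale
#'
#' Finds the multiplicative hazard scale `k` such that the undiscounted life
#' years of the cohort under `scenario` equal `target_ly`. Life years are
#' monotone decreasing in `k`, so the root is found by bracketed bisection
#' ([stats::uniroot()]).
#'
#' @param p a `pm_params` object.
#' @param target_ly target undiscounted life years, in `(0, horizon]`.
#' @param scenario scenario name, by default the one named in
#'   `p$calibration$scenario`.
#' @param tol absolute tolerance on life years.
#' @return The scale `k` (a single number).
#' @export
calibrate_background <- function(p, target_ly = p$calibration$target_ly,
                                 scenario = p$calibration$scenario,
                                 tol = 1e-6) {
  s <- p$settings
  if (target_ly <= 0 || target_ly > s$horizon)
    stop("target_ly must lie in (0, horizon]")
  p <- ensure_gompertz_a(p)
  ly_at <- function(k) {
    p$background$calibration_scale <- k
    trace_life_years(run_cohort(p, scenario))
  }
  ly0 <- ly_at(0)
  if (ly0 < target_ly)
    stop("calibration error: target life years ", target_ly,
         " unattainable; achievable range is (0, ", signif(ly0, 6),
         "] under scenario '", scenario, "'")
  k_hi <- 1
  while (ly_at(k_hi) > target_ly) {
    k_hi <- k_hi * 2
    if (k_hi > 1024) stop("calibration error: no bracket for k below 1024")
  }
  stats::uniroot(function(k) ly_at(k) - target_ly, c(0, k_hi),
                 tol = tol * 1e-3)$root
}

#' Calibrate the baseline-utility scale
#'
#' Finds the multiplier `u` applied to the baseline (event-free) utility
#' template -- with all per-age utilities clipped to `[0, 1]` and disease-state
#' utilities capped at the scaled baseline -- such that undiscounted QALYs
#' under `scenario` equal `target_qaly`. Uses the background scale already set
#' in `p` (run [calibrate_background()] first).
#'
#' @param p a `pm_params` object with calibrated background.
#' @param target_qaly target undiscounted QALYs; must not exceed the life
#'   years of the same run.
#' @param scenario scenario name.
#' @return The utility scale `u` (a single number).
#' @export
calibrate_baseline_utility <- function(p, target_qaly = p$calibration$target_qaly,
                                       scenario = p$calibration$scenario) {
  p <- ensure_gompertz_a(p)
  tr <- run_cohort(p, scenario)
  q_at <- function(u) {
    p$background$utility_scale <- u
    accrue_outcomes(tr, p, qaly_discount = 0)$qaly
  }
  ly <- trace_life_years(tr)
  if (target_qaly > ly + 1e-9)
    stop("calibration error: target QALYs ", target_qaly,
         " exceed the life years of the run (", signif(ly, 6), ")")
  ## utilities are clipped at 1, so QALYs plateau; find the feasible ceiling
  u_hi <- 1 / min(p$rewards$baseline_utility$value)
  q_max <- q_at(u_hi)
  if (q_max < target_qaly)
    stop("calibration error: target QALYs ", target_qaly,
         " unattainable; maximum is ", signif(q_max, 6),
         " under scenario '", scenario, "'")
  stats::uniroot(function(u) q_at(u) - target_qaly, c(0, u_hi),
                 tol = 1e-10)$root
}

#' Calibrate a parameter set to its printed anchors
#'
#' Performs the three-step calibration of the unprinted ancillary inputs, in
#' order: (1) the Gompertz hazard scale `a` from the lifetable life-expectancy
#' anchor (background mortality alone); (2) the hazard scale `k` from the
#' calibration scenario's undiscounted life years; (3) the baseline-utility
#' scale `u` from the same scenario's undiscounted QALYs. Steps 2 and 3 do not
#' interact: the utility scale does not perturb survival, so both anchors hold
#' simultaneously afterwards.
#'
#' @param p a `pm_params` object.
#' @return `p` with `background$gompertz_a`, `background$calibration_scale`
#'   and `background$utility_scale` set, and a `"calibration"` attribute
#'   recording the constants and targets.
#' @export
#' @examples
#' \donttest{
#' p <- calibrate_model(pm_params())
#' attr(p, "calibration")
#' }
calibrate_model <- function(p) {
  p <- ensure_gompertz_a(p)
  k <- calibrate_background(p)
  p$background$calibration_scale <- k
  u <- calibrate_baseline_utility(p)
  p$background$utility_scale <- u
  attr(p, "calibration") <- list(
    gompertz_a = p$background$gompertz_a,
    hazard_scale = k,
    utility_scale = u,
    scenario = p$calibration$scenario,
    target_ly = p$calibration$target_ly,
    target_qaly = p$calibration$target_qaly,
    lifetable_le = p$calibration$lifetable_le)
  p
}
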