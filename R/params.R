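## Parameter containers, I/O and elementary transforms.

#' Construct an age schedule
#'
#' An age schedule maps age bands to an annual probability. Bands are closed
#' below and open above; the last band is open-ended. The first band must
#' cover the cohort start age.
#'
#' @param age_lower numeric vector of band lower bounds (years), strictly
#'   increasing.
#' @param value annual probabilities, one per band, each in `[0, 1]`.
#' @return A `data.frame` with columns `age_lower` and `value`.
#' @export
#' @examples
#' age_schedule(c(40, 50, 60, 70), c(1e-4, 3e-4, 7e-4, 14e-4))
age_schedule <- function(age_lower, value) {
  if (length(age_lower) != length(value) || length(value) == 0L)
    stop("age_lower and value must be non-empty and of equal length")
  if (any(diff(age_lower) <= 0))
    stop("age_lower must be strictly increasing")
  data.frame(age_lower = as.numeric(age_lower), value = as.numeric(value))
}

#' Look up an age schedule
#'
#' @param sched an [age_schedule()].
#' @param age numeric vector of ages; each must be at or above the first band.
#' @return Annual probability at each age.
#' @export
schedule_value <- function(sched, age) {
  i <- findInterval(age, sched$age_lower)
  if (any(i == 0L))
    stop("age below the first band of the schedule (", sched$age_lower[1], ")")
  sched$value[i]
}

#' Relative risk per exposure increment
#'
#' @param point point estimate (dimensionless relative risk).
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= point <= ci_high`.
#' @param per_increment exposure increment (ug/m3) the risk is expressed per.
#' @return A list of class `pm_rr`.
#' @export
relative_risk <- function(point, ci_low = point, ci_high = point,
                          per_increment = 10) {
  rr <- list(point = point, ci_low = ci_low, ci_high = ci_high,
             per_increment = per_increment)
  bad <- rr_violations(rr, "relative_risk")
  if (length(bad)) stop(paste(bad, collapse = "; "))
  class(rr) <- "pm_rr"
  rr
}

rr_violations <- function(rr, label) {
  out <- character()
  if (!is.numeric(rr$point) || !is.numeric(rr$ci_low) || !is.numeric(rr$ci_high))
    return(paste0(label, ": non-numeric relative risk"))
  if (rr$ci_low <= 0)
    out <- c(out, paste0(label, ": ci_low must be > 0"))
  if (rr$ci_low > rr$point || rr$point > rr$ci_high)
    out <- c(out, paste0(label, ": requires ci_low <= point <= ci_high"))
  if (is.null(rr$per_increment) || rr$per_increment <= 0)
    out <- c(out, paste0(label, ": per_increment must be > 0"))
  out
}

#' Scale a relative risk to a concentration difference
#'
#' Log-linear concentration-response extrapolation: the multiplier applied to
#' an annual probability is `point ^ (delta / per_increment)`, so a zero
#' difference gives 1 and increments compose multiplicatively.
#'
#' @param rr a [relative_risk()] (or plain list with the same fields).
#' @param delta_concentration concentration difference in ug/m3, `>= 0`.
#' @return Dimensionless multiplier.
#' @export
#' @examples
#' scale_rr(relative_risk(1.42, 1.02, 1.98, per_increment = 10), 10) # 1.42
#' scale_rr(relative_risk(1.2, per_increment = 5), 10)               # 1.44
scale_rr <- function(rr, delta_concentration) {
  if (delta_concentration < 0) stop("delta_concentration must be >= 0")
  rr$point^(delta_concentration / rr$per_increment)
}

#' Consumer-price-index cost adjustment
#'
#' Re-expresses a cost observed under a base index in current-index terms:
#' `cost_base * cpi_current / cpi_base`.
#'
#' @param cost_base cost in base-year currency, `> 0`.
#' @param cpi_base,cpi_current index values, `> 0`.
#' @return Adjusted cost.
#' @export
cpi_adjust <- function(cost_base, cpi_base, cpi_current) {
  if (any(c(cost_base, cpi_base, cpi_current) <= 0))
    stop("cpi_adjust requires positive cost and index values")
  cost_base * cpi_current / cpi_base
}

#' Convert an annual event rate to a one-cycle probability
#'
#' Standard actuarial conversion `1 - exp(-rate * t)`. The packaged inputs are
#' interpreted directly as annual probabilities by default; set the
#' `convert_rates` flag in the run settings to apply this conversion to the
#' incidence and mortality schedules.
#'
#' @param rate annual event rate, `>= 0`.
#' @param t exposure time in years, `> 0`.
#' @return Probability in `[0, 1)`.
#' @export
rate_to_prob <- function(rate, t = 1) {
  if (any(rate < 0)) stop("rate must be >= 0")
  if (t <= 0) stop("t must be > 0")
  1 - exp(-rate * t)
}

as_schedule <- function(x, key) {
  if (is.data.frame(x)) return(age_schedule(x$age_lower, x$value))
  if (is.null(x$age_lower) || is.null(x$value))
    stop("schema error: '", key, "' must have age_lower and value")
  age_schedule(unlist(x$age_lower), unlist(x$value))
}

null_or_na <- function(x) is.null(x) || (length(x) == 1L && is.na(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a validated parameter set
#'
#' Converts a plain nested list (as read from a YAML/JSON parameter file) into
#' a `pm_params` object, filling documented defaults and checking every
#' structural invariant. See [pm_params()] for the packaged inputs and the
#' packaged file `extdata/paper_2022.yaml` for the schema.
#'
#' @param x nested list with elements `settings`, `scenarios`, `diseases`,
#'   `rewards`, `background` and optionally `calibration`, `psa`.
#' @return A validated object of class `pm_params`.
#' @export
as_pm_params <- function(x) {
  p <- as_pm_params_struct(x)
  bad <- validate_params(p)
  if (length(bad))
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "))
  p
}

## structural coercion and defaults only; no invariant checking
as_pm_params_struct <- function(x) {
  for (key in c("settings", "scenarios", "diseases", "rewards", "background"))
    if (is.null(x[[key]])) stop("schema error: missing required key '", key, "'")

  s <- x$settings
  settings <- list(
    start_age = s$start_age %||% 40,
    horizon = s$horizon %||% 60,
    cycle_length = s$cycle_length %||% 1,
    cost_discount = s$cost_discount %||% 0.05,
    qaly_discount = s$qaly_discount %||% 0,
    half_cycle_correction = isTRUE(s$half_cycle_correction),
    cohort_size = s$cohort_size %||% 10000,
    convert_rates = isTRUE(s$convert_rates))

  scenarios <- lapply(x$scenarios, function(sc) {
    list(label = sc$label, concentration = sc$concentration,
         reference_concentration = sc$reference_concentration %||% 15)
  })

  diseases <- list()
  for (d in names(x$diseases)) {
    dd <- x$diseases[[d]]
    for (f in c("incidence", "mortality", "rr_incidence", "rr_mortality"))
      if (is.null(dd[[f]]))
        stop("schema error: disease '", d, "' missing '", f, "'")
    mk_rr <- function(r, key) {
      for (f in c("point", "ci_low", "ci_high"))
        if (is.null(r[[f]]) || !is.numeric(r[[f]]))
          stop("schema error: '", key, "' needs numeric '", f, "'")
      structure(list(point = r$point, ci_low = r$ci_low, ci_high = r$ci_high,
                     per_increment = r$per_increment %||% 10), class = "pm_rr")
    }
    diseases[[d]] <- list(
      name = d,
      incidence = as_schedule(dd$incidence, paste0(d, "$incidence")),
      mortality = as_schedule(dd$mortality, paste0(d, "$mortality")),
      rr_incidence = mk_rr(dd$rr_incidence, paste0(d, "$rr_incidence")),
      rr_mortality = mk_rr(dd$rr_mortality, paste0(d, "$rr_mortality")))
  }

  r <- x$rewards
  num_map <- function(m, key) {
    if (is.null(m)) stop("schema error: missing 'rewards$", key, "'")
    v <- unlist(m)
    if (!is.numeric(v)) stop("schema error: non-numeric value in rewards$", key)
    v
  }
  rewards <- list(
    state_costs = num_map(r$state_costs, "state_costs"),
    death_costs = num_map(r$death_costs, "death_costs"),
    state_utilities = num_map(r$state_utilities, "state_utilities"),
    baseline_utility = as_schedule(r$baseline_utility, "rewards$baseline_utility"))

  b <- x$background
  background <- list(
    mode = b$mode %||% "gompertz_makeham",
    makeham_c = b$makeham_c %||% 5e-4,
    gompertz_a = if (null_or_na(b$gompertz_a)) NA_real_ else b$gompertz_a,
    gompertz_b = b$gompertz_b %||% 0.09,
    calibration_scale = b$calibration_scale %||% 1,
    utility_scale = b$utility_scale %||% 1,
    includes_modelled_causes = isTRUE(b$includes_modelled_causes %||% TRUE),
    table = if (null_or_na(b$table)) NULL else as_schedule(b$table, "background$table"))

  cal <- x$calibration %||% list()
  calibration <- list(
    scenario = cal$scenario %||% "standard",
    target_ly = cal$target_ly %||% 41.34,
    target_qaly = cal$target_qaly %||% 32.08,
    lifetable_le = cal$lifetable_le %||% 47.3)

  psa <- x$psa %||% list()
  psa <- list(utility_cv = psa$utility_cv %||% 0.1,
              cost_cv = psa$cost_cv %||% 0.2)

  structure(list(settings = settings, scenarios = scenarios,
                 diseases = diseases, rewards = rewards,
                 background = background, calibration = calibration,
                 psa = psa),
            class = "pm_params")
}

#' Packaged model inputs
#'
#' The published input tables as a ready-to-use parameter set: age-banded
#' annual incidence and mortality schedules with exposure relative risks for
#' lung cancer, myocardial infarction, stroke and COPD; annual state costs,
#' one-time death costs and state utilities (2020 USD); the two exposure
#' scenarios (15 and 25 ug/m3); run settings (start age 40, 60 annual cycles,
#' 5% cost discounting); and the calibration anchors for the unprinted
#' background-mortality and baseline-utility inputs.
#'
#' @return A validated `pm_params` object.
#' @seealso [load_params()], [calibrate_model()], [pm_model()]
#' @export
#' @examples
#' p <- pm_params()
#' p$diseases$lung_cancer$rr_incidence$point
pm_params <- function() {
  load_params(system.file("extdata", "paper_2022.yaml", package = "pmcohort",
                          mustWork = TRUE))
}

#' Load a parameter file
#'
#' Reads a YAML (or JSON) parameter file with top-level keys `settings`,
#' `scenarios`, `diseases`, `rewards`, `background` and optional
#' `calibration`/`psa`, applies documented defaults, and validates.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pm_params` object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_pm_params(x)
}

#' Save a parameter set
#'
#' Writes YAML (or JSON, by file extension) that [load_params()] reads back to
#' an identical parameter set.
#'
#' @param p a `pm_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path) {
  x <- unclass(p)
  x$diseases <- lapply(x$diseases, function(d) {
    d$incidence <- list(age_lower = d$incidence$age_lower, value = d$incidence$value)
    d$mortality <- list(age_lower = d$mortality$age_lower, value = d$mortality$value)
    d$rr_incidence <- unclass(d$rr_incidence)
    d$rr_mortality <- unclass(d$rr_mortality)
    d
  })
  x$rewards$state_costs <- as.list(x$rewards$state_costs)
  x$rewards$death_costs <- as.list(x$rewards$death_costs)
  x$rewards$state_utilities <- as.list(x$rewards$state_utilities)
  bu <- x$rewards$baseline_utility
  x$rewards$baseline_utility <- list(age_lower = bu$age_lower, value = bu$value)
  if (!is.null(x$background$table)) {
    tb <- x$background$table
    x$background$table <- list(age_lower = tb$age_lower, value = tb$value)
  }
  if (is.na(x$background$gompertz_a)) x$background$gompertz_a <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

sched_violations <- function(sched, start_age, label) {
  out <- character()
  if (any(diff(sched$age_lower) <= 0))
    out <- c(out, paste0(label, ": age bands not strictly increasing"))
  if (sched$age_lower[1] > start_age)
    out <- c(out, paste0(label, ": first band must cover the start age (",
                         start_age, ")"))
  if (any(sched$value < 0 | sched$value > 1))
    out <- c(out, paste0(label, ": values must lie in [0, 1]"))
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant (schedule ordering and bounds, relative
#' risk ordering, reward signs and utility bounds, scenario ordering, run
#' settings) and, in addition, that the total exit probability from each alive
#' state stays at or below 1 at every age of the horizon under both scenarios.
#'
#' @param p a `pm_params` object (structurally complete).
#' @return Character vector of violations; empty when the set is valid.
#' @export
validate_params <- function(p) {
  out <- character()
  s <- p$settings
  if (s$horizon < 1) out <- c(out, "settings$horizon must be >= 1")
  if (s$cycle_length != 1) out <- c(out, "settings$cycle_length: only 1 is supported")
  if (s$cost_discount < 0 || s$qaly_discount < 0)
    out <- c(out, "settings: discount rates must be >= 0")
  if (s$cohort_size <= 0) out <- c(out, "settings$cohort_size must be > 0")

  if (!setequal(names(p$diseases), PM_DISEASES))
    out <- c(out, paste0("diseases: expected exactly {",
                         paste(PM_DISEASES, collapse = ", "), "}"))
  for (d in names(p$diseases)) {
    dd <- p$diseases[[d]]
    out <- c(out,
             sched_violations(dd$incidence, s$start_age, paste0(d, "$incidence")),
             sched_violations(dd$mortality, s$start_age, paste0(d, "$mortality")),
             rr_violations(dd$rr_incidence, paste0(d, "$rr_incidence")),
             rr_violations(dd$rr_mortality, paste0(d, "$rr_mortality")))
  }

  rw <- p$rewards
  need_costs <- setdiff(PM_ALIVE, "event_free")
  if (!all(need_costs %in% names(rw$state_costs)))
    out <- c(out, "rewards$state_costs: missing states")
  if (any(rw$state_costs < 0)) out <- c(out, "rewards$state_costs must be >= 0")
  if (any(rw$death_costs < 0)) out <- c(out, "rewards$death_costs must be >= 0")
  extra <- intersect(names(rw$state_costs), PM_DEAD)
  if (any(rw$state_costs[extra] != 0))
    out <- c(out, "rewards$state_costs: dead states must have zero annual cost")
  for (st in names(rw$state_utilities)) {
    u <- rw$state_utilities[[st]]
    if (u < 0 || u > 1)
      out <- c(out, paste0("rewards$state_utilities$", st,
                           " = ", u, " outside [0, 1]"))
  }
  out <- c(out, sched_violations(rw$baseline_utility, s$start_age,
                                 "rewards$baseline_utility"))

  for (nm in names(p$scenarios)) {
    sc <- p$scenarios[[nm]]
    if (sc$concentration < sc$reference_concentration)
      out <- c(out, paste0("scenarios$", nm,
                           ": concentration below reference_concentration"))
  }
  if (!all(c("standard", "increased") %in% names(p$scenarios)))
    out <- c(out, "scenarios: need both 'standard' and 'increased'")

  bg <- p$background
  if (!bg$mode %in% c("gompertz_makeham", "table"))
    out <- c(out, "background$mode must be 'gompertz_makeham' or 'table'")
  if (bg$mode == "table" && is.null(bg$table))
    out <- c(out, "background: mode 'table' requires a table")
  if (bg$calibration_scale < 0) out <- c(out, "background$calibration_scale must be >= 0")

  if (length(out)) return(out)

  ## feasibility: total exit probability from each alive state <= 1 at every
  ## age, under both scenarios (uses the current background; the Gompertz
  ## scale is resolved from the lifetable anchor if not yet set)
  pf <- tryCatch(ensure_gompertz_a(p), error = function(e) NULL)
  if (is.null(pf)) return("background: Gompertz scale could not be resolved")
  ages <- s$start_age + seq_len(s$horizon) - 1
  q0 <- background_prob(pf$background, ages)
  for (nm in c("standard", "increased")) {
    mult <- scenario_multipliers(pf, nm)
    iv <- vapply(PM_DISEASES, function(d)
      disease_prob(pf, d, "incidence", ages) * mult$incidence[[d]], numeric(length(ages)))
    mv <- vapply(PM_DISEASES, function(d)
      disease_prob(pf, d, "mortality", ages) * mult$mortality[[d]], numeric(length(ages)))
    ef_exit <- rowSums(iv) + q0
    if (any(ef_exit > 1 + 1e-12)) {
      j <- which.max(ef_exit)
      out <- c(out, paste0("exit probability > 1 from event_free at age ",
                           ages[j], " under ", nm, " scenario (",
                           signif(ef_exit[j], 5), ")"))
    }
    for (i in seq_along(PM_DISEASES)) {
      ex <- mv[, i] + q0
      if (any(ex > 1 + 1e-12)) {
        j <- which.max(ex)
        out <- c(out, paste0("exit probability > 1 from ",
                             PM_ENTRY_STATE[[PM_DISEASES[i]]], " at age ",
                             ages[j], " under ", nm, " scenario (",
                             signif(ex[j], 5), ")"))
      }
    }
  }
  out
}

## annual probability for one disease/kind at given ages, before RR scaling
disease_prob <- function(p, disease, kind = c("incidence", "mortality"), ages) {
  kind <- match.arg(kind)
  v <- schedule_value(p$diseases[[disease]][[kind]], ages)
  if (isTRUE(p$settings$convert_rates)) v <- rate_to_prob(v)
  v
}

resolve_scenario <- function(p, scenario) {
  if (is.list(scenario)) return(scenario)
  sc <- p$scenarios[[scenario]]
  if (is.null(sc)) stop("unknown scenario '", scenario, "'; available: ",
                        paste(names(p$scenarios), collapse = ", "))
  sc
}

## RR multipliers for both transition kinds under a scenario
scenario_multipliers <- function(p, scenario) {
  sc <- resolve_scenario(p, scenario)
  delta <- sc$concentration - sc$reference_concentration
  list(incidence = vapply(p$diseases, function(d) scale_rr(d$rr_incidence, delta),
                          numeric(1)),
       mortality = vapply(p$diseases, function(d) scale_rr(d$rr_mortality, delta),
                          numeric(1)))
}

#' @export
print.pm_params <- function(x, ...) {
  s <- x$settings
  cat("PM2.5 cohort model parameter set\n")
  cat(sprintf("  cohort: %d women aged %d, %d annual cycles\n",
              s$cohort_size, s$start_age, s$horizon))
  cat(sprintf("  discounting: costs %.0f%%, QALYs %.0f%%\n",
              100 * s$cost_discount, 100 * s$qaly_discount))
  for (nm in names(x$scenarios))
    cat(sprintf("  scenario %-9s: %g ug/m3 (reference %g)\n", nm,
                x$scenarios[[nm]]$concentration,
                x$scenarios[[nm]]$reference_concentration))
  cat("  diseases:", paste(names(x$diseases), collapse = ", "), "\n")
  cat(sprintf("  background: %s (a=%s, b=%g, c=%g, scale k=%g, utility scale u=%g)\n",
              x$background$mode,
              if (is.na(x$background$gompertz_a)) "uncalibrated"
              else signif(x$background$gompertz_a, 4),
              x$background$gompertz_b, x$background$makeham_c,
              signif(x$background$calibration_scale, 4),
              signif(x$background$utility_scale, 4)))
  invisible(x)
}
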