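## Epidemiological rate projections for external validation.

#' Cause-specific mortality rate projected by the model
#'
#' Cumulative entries into one cause-specific dead state over the first
#' `cycles` cycles, divided by person-years alive. Person-years use the
#' alive-at-cycle-start convention (the alive fraction at the start of each
#' cycle, summed), consistent with the engine's lack of half-cycle
#' correction; set `midcycle = TRUE` to average cycle-start and cycle-end
#' occupancy instead.
#'
#' @param trace a `pm_trace`.
#' @param cause one of the dead states, e.g. `"dead_lc"`.
#' @param cycles number of cycles to accumulate (defaults to the full trace).
#' @param midcycle use mid-cycle person-years.
#' @return Deaths per person-year at risk.
#' @export
#' @examples
#' \donttest{
#' p <- calibrate_model(pm_params())
#' tr <- run_cohort(p, "increased", horizon = 15)
#' 1e5 * cause_mortality_rate(tr, "dead_lc")  # per 100,000 person-years
#' }
cause_mortality_rate <- function(trace, cause, cycles = NULL,
                                 midcycle = FALSE) {
  if (!cause %in% PM_DEAD)
    stop("unknown cause '", cause, "'; one of: ", paste(PM_DEAD, collapse = ", "))
  h <- nrow(trace$entries)
  cyc <- if (is.null(cycles)) h else cycles
  if (cyc > h) stop("cycles exceeds the trace horizon (", h, ")")
  deaths <- sum(trace$entries[seq_len(cyc), cause])
  py <- person_years(trace$occupancy[, 1:8, drop = FALSE], cyc, midcycle)
  deaths / py
}

#' Disease incidence rate projected by the model
#'
#' Cumulative entries into the disease's entry state divided by person-years
#' spent event-free (the population at risk of a first event).
#'
#' @param trace a `pm_trace`.
#' @param disease one of `"lung_cancer"`, `"mi"`, `"stroke"`, `"copd"`.
#' @param cycles number of cycles to accumulate (defaults to the full trace).
#' @param midcycle use mid-cycle person-years.
#' @return Cases per event-free person-year.
#' @export
disease_incidence_rate <- function(trace, disease, cycles = NULL,
                                   midcycle = FALSE) {
  if (!disease %in% PM_DISEASES)
    stop("unknown disease '", disease, "'; one of: ",
         paste(PM_DISEASES, collapse = ", "))
  h <- nrow(trace$entries)
  cyc <- if (is.null(cycles)) h else cycles
  if (cyc > h) stop("cycles exceeds the trace horizon (", h, ")")
  cases <- sum(trace$entries[seq_len(cyc), PM_ENTRY_STATE[[disease]]])
  py <- person_years(trace$occupancy[, "event_free", drop = FALSE], cyc, midcycle)
  cases / py
}

person_years <- function(occ_cols, cycles, midcycle) {
  at_start <- sum(occ_cols[seq_len(cycles), ])
  if (!midcycle) return(at_start)
  at_end <- sum(occ_cols[1 + seq_len(cycles), ])
  (at_start + at_end) / 2
}

#' Validation comparison table
#'
#' Projects the model's lung-cancer mortality rate (over a truncated horizon
#' matching the external cohort's follow-up) and lifetime stroke incidence
#' rate, next to user-supplied reference values from observational cohorts.
#'
#' @param model a `pm_model`.
#' @param scenario scenario to project (the external cohorts were exposed,
#'   so the increased scenario by default).
#' @param mortality_cycles follow-up length for the mortality comparison.
#' @param reference optional named numeric vector with elements
#'   `lc_mortality` (per person-year) and `stroke_incidence` (per
#'   event-free person-year) to place alongside.
#' @return A `data.frame` with `quantity`, `model`, `reference`.
#' @export
validation_report <- function(model, scenario = "increased",
                              mortality_cycles = 15, reference = NULL) {
  tr_short <- run_cohort(model$params, scenario, horizon = mortality_cycles)
  tr_full <- model$traces[[scenario]]
  out <- data.frame(
    quantity = c(sprintf("lung-cancer mortality, %d-cycle run (per person-year)",
                         mortality_cycles),
                 "stroke incidence, lifetime run (per event-free person-year)"),
    model = c(cause_mortality_rate(tr_short, "dead_lc"),
              disease_incidence_rate(tr_full, "stroke")))
  pick <- function(nm) if (nm %in% names(reference)) reference[[nm]] else NA_real_
  out$reference <- c(pick("lc_mortality"), pick("stroke_incidence"))
  out
}
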