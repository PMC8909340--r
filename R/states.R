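## State space of the cohort model. Order is load-bearing: alive states first,
## absorbing death states last; propagation and accrual index into it by position.

PM_STATES <- c("event_free",
               "lc_y1", "lc_later",
               "mi_y1", "mi_post",
               "stroke_y1", "stroke_post",
               "copd",
               "dead_lc", "dead_chd", "dead_cvd", "dead_copd", "dead_other")
PM_ALIVE <- PM_STATES[1:8]
PM_DEAD <- PM_STATES[9:13]
PM_DISEASES <- c("lung_cancer", "mi", "stroke", "copd")

## per-disease state bookkeeping
PM_ENTRY_STATE <- c(lung_cancer = "lc_y1", mi = "mi_y1",
                    stroke = "stroke_y1", copd = "copd")
PM_CHRONIC_STATE <- c(lung_cancer = "lc_later", mi = "mi_post",
                      stroke = "stroke_post", copd = "copd")
PM_DEAD_STATE <- c(lung_cancer = "dead_lc", mi = "dead_chd",
                   stroke = "dead_cvd", copd = "dead_copd")

#' Health-state space of the cohort model
#'
#' Returns the 13 mutually exclusive, collectively exhaustive health states:
#' an event-free state, first-year and later-year states for lung cancer,
#' myocardial infarction and stroke, a single chronic COPD state, and five
#' absorbing cause-specific death states (lung cancer, coronary heart disease,
#' cardiovascular disease, COPD, other causes).
#'
#' @param which one of `"all"`, `"alive"`, `"dead"`.
#' @return Character vector of state names, in model order.
#' @export
#' @examples
#' state_space()
#' state_space("dead")
state_space <- function(which = c("all", "alive", "dead")) {
  switch(match.arg(which), all = PM_STATES, alive = PM_ALIVE, dead = PM_DEAD)
}
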