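## Second-order Monte Carlo probabilistic sensitivity analysis.
##
## Parameter uncertainty only: relative risks are lognormal (natural
## parameters recovered from the reported 95% CI), utilities beta and costs
## gamma (method-of-moments from the reported mean and an assumed coefficient
## of variation, since the source reports families but no spreads). Each draw
## samples every uncertain parameter once and evaluates both scenarios with
## the same draw (common random parameters); the cohort engine itself is
## deterministic given parameters, so no first-order variability is simulated.

#' Lognormal distribution from a relative risk's confidence interval
#'
#' `meanlog = log(point)` and `sdlog = (log(high) - log(low)) / (2 * 1.959964)`,
#' so the distribution's median equals the point estimate and the quoted
#' bounds sit at the 2.5 and 97.5 percentiles of a log-symmetric interval.
#'
#' @param point,low,high relative-risk point estimate and 95% bounds,
#'   `0 < low <= point <= high`.
#' @return A distribution spec (list with `family` and natural parameters).
#' @export
#' @examples
#' lognormal_from_ci(1.42, 1.02, 1.98)
lognormal_from_ci <- function(point, low, high) {
  if (low <= 0 || high <= 0 || point <= 0)
    stop("relative-risk bounds must be positive")
  if (low > point || point > high) stop("requires low <= point <= high")
  if (low == high)
    return(list(family = "degenerate", value = point))
  list(family = "lognormal", meanlog = log(point),
       sdlog = (log(high) - log(low)) / (2 * stats::qnorm(0.975)))
}

#' Beta distribution from a mean utility and coefficient of variation
#'
#' Method of moments: with variance `v = (cv * mean)^2`,
#' `shape1 = mean * (mean (1 - mean) / v - 1)` and
#' `shape2 = (1 - mean) * (mean (1 - mean) / v - 1)`.
#'
#' @param mean mean utility in `(0, 1)`.
#' @param cv coefficient of variation, `> 0`; the implied variance must stay
#'   below `mean * (1 - mean)`.
#' @return A distribution spec.
#' @export
beta_from_mean_cv <- function(mean, cv) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)")
  if (cv <= 0) stop("cv must be > 0")
  v <- (cv * mean)^2
  if (v >= mean * (1 - mean))
    stop("variance ", signif(v, 4), " infeasible for a beta with mean ", mean)
  s <- mean * (1 - mean) / v - 1
  list(family = "beta", shape1 = mean * s, shape2 = (1 - mean) * s)
}

#' Gamma distribution from a mean cost and coefficient of variation
#'
#' `shape = 1 / cv^2`, `scale = mean * cv^2`, so `shape * scale = mean` and
#' the coefficient of variation is `cv` exactly.
#'
#' @param mean mean cost, `> 0`.
#' @param cv coefficient of variation, `> 0`.
#' @return A distribution spec.
#' @export
gamma_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) stop("mean must be > 0")
  if (cv <= 0) stop("cv must be > 0")
  list(family = "gamma", shape = 1 / cv^2, scale = mean * cv^2)
}

#' Sample from a distribution spec
#'
#' @param spec a spec from [lognormal_from_ci()], [beta_from_mean_cv()],
#'   [gamma_from_mean_cv()] or a degenerate spec.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  switch(spec$family,
         degenerate = rep(spec$value, n),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         stop("unknown distribution family '", spec$family, "'"))
}

## evaluate a local expression under a private RNG stream, restoring the
## caller's stream afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

psa_uncertain <- function(p) {
  specs <- list(); base <- list(); kind <- character()
  for (d in names(p$diseases)) for (k in c("incidence", "mortality")) {
    rr <- p$diseases[[d]][[paste0("rr_", k)]]
    id <- paste0("rr_", d, "_", k)
    specs[[id]] <- lognormal_from_ci(rr$point, rr$ci_low, rr$ci_high)
    kind[id] <- "rr"
  }
  ucv <- p$psa$utility_cv; ccv <- p$psa$cost_cv
  for (st in names(p$rewards$state_utilities)) {
    id <- paste0("utility_", st)
    m <- p$rewards$state_utilities[[st]]
    specs[[id]] <- if (ucv > 0) beta_from_mean_cv(m, ucv) else
      list(family = "degenerate", value = m)
    kind[id] <- "utility"
  }
  for (st in setdiff(names(p$rewards$state_costs), "event_free")) {
    id <- paste0("cost_", st)
    m <- p$rewards$state_costs[[st]]
    specs[[id]] <- if (m > 0 && ccv > 0) gamma_from_mean_cv(m, ccv) else
      list(family = "degenerate", value = m)
    kind[id] <- "cost"
  }
  for (st in setdiff(names(p$rewards$death_costs), "dead_other")) {
    id <- paste0("death_cost_", st)
    m <- p$rewards$death_costs[[st]]
    specs[[id]] <- if (m > 0 && ccv > 0) gamma_from_mean_cv(m, ccv) else
      list(family = "degenerate", value = m)
    kind[id] <- "cost"
  }
  list(specs = specs, kind = kind)
}

apply_draw <- function(p, draw) {
  for (d in names(p$diseases)) for (k in c("incidence", "mortality"))
    p$diseases[[d]][[paste0("rr_", k)]]$point <- draw[[paste0("rr_", d, "_", k)]]
  for (st in names(p$rewards$state_utilities))
    p$rewards$state_utilities[[st]] <- draw[[paste0("utility_", st)]]
  for (st in setdiff(names(p$rewards$state_costs), "event_free"))
    p$rewards$state_costs[[st]] <- draw[[paste0("cost_", st)]]
  for (st in setdiff(names(p$rewards$death_costs), "dead_other"))
    p$rewards$death_costs[[st]] <- draw[[paste0("death_cost_", st)]]
  p
}

psa_quantiles <- c(0.025, 0.10, 0.50, 0.90, 0.975)

#' Run the probabilistic sensitivity analysis
#'
#' Draws the eight relative risks (lognormal), seven state utilities (beta)
#' and eleven costs (gamma) `n_draws` times, evaluates both scenarios per
#' draw with the calibration frozen at base case, and summarises costs and
#' QALYs per scenario. A draw whose sampled parameters make some state's exit
#' probability exceed 1 is rejected and counted; more than `max_reject_frac`
#' rejections abort the analysis.
#'
#' @param p a calibrated `pm_params` (or `pm_model`).
#' @param n_draws number of parameter draws, `>= 1`.
#' @param seed integer seed; the analysis is fully reproducible given the
#'   seed and does not disturb the caller's RNG stream.
#' @param max_reject_frac maximum tolerated fraction of infeasible draws.
#' @return An object of class `pm_psa`: list with `summary` (a data frame of
#'   mean, SD, min, percentiles, max per scenario and outcome), `draws` (one
#'   row per draw and scenario: cost, QALYs, life years), `parameter_draws`
#'   (the sampled parameter matrix, one row per draw), `n_draws`, `seed`,
#'   `n_rejected`.
#' @export
#' @examples
#' \donttest{
#' p <- calibrate_model(pm_params())
#' ps <- run_psa(p, n_draws = 200, seed = 42)
#' ps$summary
#' }
run_psa <- function(p, n_draws = 10000, seed = 1L, max_reject_frac = 0.01) {
  if (inherits(p, "pm_model")) p <- p$params
  if (n_draws < 1) stop("n_draws must be >= 1")
  p <- ensure_gompertz_a(p)
  un <- psa_uncertain(p)
  ids <- names(un$specs)

  draws_mat <- with_local_seed(seed, {
    m <- vapply(un$specs, sample_dist, numeric(n_draws), n = n_draws)
    if (n_draws == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, ids))
    m
  })

  res <- vector("list", n_draws)
  n_rejected <- 0L
  for (i in seq_len(n_draws)) {
    pi <- apply_draw(p, as.list(draws_mat[i, ]))
    oo <- tryCatch({
      lapply(list(standard = "standard", increased = "increased"),
             function(sc) accrue_outcomes(run_cohort(pi, sc), pi))
    }, pmcohort_infeasible = function(e) NULL)
    if (is.null(oo)) { n_rejected <- n_rejected + 1L; next }
    res[[i]] <- data.frame(
      draw = i, scenario = c("standard", "increased"),
      cost = c(oo$standard$cost, oo$increased$cost),
      qaly = c(oo$standard$qaly, oo$increased$qaly),
      life_years = c(oo$standard$life_years, oo$increased$life_years))
  }
  if (n_rejected > max_reject_frac * n_draws)
    stop("PSA aborted: ", n_rejected, " of ", n_draws,
         " draws were infeasible (> ", 100 * max_reject_frac, "%)")
  draws <- do.call(rbind, res)

  summarise <- function(v) {
    qs <- stats::quantile(v, psa_quantiles, names = FALSE)
    data.frame(mean = mean(v), sd = stats::sd(v), min = min(v),
               p2.5 = qs[1], p10 = qs[2], median = qs[3], p90 = qs[4],
               p97.5 = qs[5], max = max(v))
  }
  summ <- do.call(rbind, lapply(c("increased", "standard"), function(sc) {
    g <- draws[draws$scenario == sc, ]
    cbind(data.frame(scenario = sc, outcome = c("cost", "qaly")),
          rbind(summarise(g$cost), summarise(g$qaly)))
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, draws = draws,
                 parameter_draws = draws_mat, n_draws = n_draws,
                 seed = seed, n_rejected = n_rejected),
            class = "pm_psa")
}

#' @export
print.pm_psa <- function(x, ...) {
  cat(sprintf("probabilistic sensitivity analysis: %d draws (seed %s, %d rejected)\n",
              x$n_draws, format(x$seed), x$n_rejected))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Min-to-max range of a PSA outcome, as a percentage of the minimum
#'
#' @param x a `pm_psa`.
#' @param scenario `"standard"` or `"increased"`.
#' @param outcome `"cost"` or `"qaly"`.
#' @return `100 * (max - min) / min`.
#' @export
psa_range_pct <- function(x, scenario, outcome = c("cost", "qaly")) {
  outcome <- match.arg(outcome)
  row <- x$summary[x$summary$scenario == scenario &
                     x$summary$outcome == outcome, ]
  if (nrow(row) != 1) stop("no such scenario/outcome in the summary")
  if (row$min == 0) stop("minimum is zero; range percentage undefined")
  100 * (row$max - row$min) / row$min
}
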