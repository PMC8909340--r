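test_that("lognormal specs recover natural parameters from the CI", {
  sp <- lognormal_from_ci(1.42, 1.02, 1.98)
  expect_equal(sp$meanlog, 0.350656871613, tolerance = 1e-9)
  expect_equal(sp$sdlog, 0.169210817812, tolerance = 1e-9)
  expect_identical(lognormal_from_ci(1, 1, 1),
                   list(family = "degenerate", value = 1))
  expect_error(lognormal_from_ci(1.2, -0.1, 1.5), "positive")
  expect_error(lognormal_from_ci(1.2, 1.3, 1.5), "low <= point <= high")
})

test_that("the lognormal median matches the point estimate empirically", {
  sp <- lognormal_from_ci(1.42, 1.02, 1.98)
  med <- pmcohort:::with_local_seed(4242, median(sample_dist(sp, 1e6)))
  expect_lt(abs(med - 1.42) / 1.42, 0.005)
})

test_that("beta method-of-moments hits the documented shapes and limits", {
  sp <- beta_from_mean_cv(0.61, 0.1)
  expect_equal(sp$shape1, 38.39, tolerance = 1e-6)
  expect_equal(sp$shape2, 24.5444262295, tolerance = 1e-6)
  x <- pmcohort:::with_local_seed(7, sample_dist(beta_from_mean_cv(0.61, 1e-4), 1e5))
  expect_lt(stats::sd(x), 1e-3)
  expect_lt(abs(mean(pmcohort:::with_local_seed(8, sample_dist(sp, 1e6))) - 0.61) / 0.61,
            0.002)
  expect_error(beta_from_mean_cv(0.61, 1.5), "infeasible")
  expect_error(beta_from_mean_cv(1.2, 0.1), "\\(0, 1\\)")
})

test_that("gamma method-of-moments preserves mean and cv", {
  sp <- gamma_from_mean_cv(19495, 0.2)
  expect_equal(sp$shape, 25)
  expect_equal(sp$scale, 779.8)
  expect_equal(sp$shape * sp$scale, 19495)
  x <- pmcohort:::with_local_seed(9, sample_dist(sp, 1e6))
  expect_lt(abs(stats::sd(x) / mean(x) - 0.2) / 0.2, 0.01)
  expect_error(gamma_from_mean_cv(-5, 0.2), "> 0")
})

test_that("sampled RRs bracket the reported CI at the right percentiles", {
  p <- pm_params()
  rr <- p$diseases$stroke$rr_mortality
  x <- pmcohort:::with_local_seed(11, {
    sample_dist(lognormal_from_ci(rr$point, rr$ci_low, rr$ci_high), 1e5)
  })
  qs <- unname(stats::quantile(x, c(0.025, 0.975)))
  expect_equal(qs[1], rr$ci_low, tolerance = 0.02)
  expect_equal(qs[2], rr$ci_high, tolerance = 0.02)
})

test_that("the PSA is reproducible and internally consistent", {
  p <- calibrated_fixture()
  a <- run_psa(p, n_draws = 40, seed = 123)
  b <- run_psa(p, n_draws = 40, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$parameter_draws, b$parameter_draws)
  c <- run_psa(p, n_draws = 40, seed = 124)
  expect_false(identical(a$draws, c$draws))

  ## summary mean equals the mean of the emitted draw table exactly
  g <- a$draws[a$draws$scenario == "increased", ]
  expect_equal(a$summary$mean[a$summary$scenario == "increased" &
                                a$summary$outcome == "cost"],
               mean(g$cost))
  ## percentile grid monotone
  for (i in seq_len(nrow(a$summary))) {
    row <- as.numeric(a$summary[i, c("min", "p2.5", "p10", "median",
                                     "p90", "p97.5", "max")])
    expect_true(all(diff(row) >= 0))
  }
  ## the caller's RNG stream is untouched
  set.seed(555); before <- runif(3)
  set.seed(555); invisible(run_psa(p, n_draws = 3, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate distributions collapse every draw onto the base case", {
  p <- calibrated_fixture()
  p$psa$utility_cv <- 0
  p$psa$cost_cv <- 0
  for (d in names(p$diseases)) for (k in c("rr_incidence", "rr_mortality")) {
    p$diseases[[d]][[k]]$ci_low <- p$diseases[[d]][[k]]$point
    p$diseases[[d]][[k]]$ci_high <- p$diseases[[d]][[k]]$point
  }
  base <- accrue_outcomes(run_cohort(p, "increased"), p)
  ps <- run_psa(p, n_draws = 3, seed = 5)
  inc <- ps$draws[ps$draws$scenario == "increased", ]
  expect_equal(inc$cost, rep(base$cost, 3), tolerance = 1e-12)
  expect_equal(inc$qaly, rep(base$qaly, 3), tolerance = 1e-12)
})

test_that("with all RR draws at or above 1, the increased arm costs more", {
  p <- calibrated_fixture()
  ps <- run_psa(p, n_draws = 150, seed = 31)
  rr_cols <- grep("^rr_", colnames(ps$parameter_draws))
  ok <- rowSums(ps$parameter_draws[, rr_cols] < 1) == 0
  done <- unique(ps$draws$draw)
  for (i in done[ok[done]]) {
    g <- ps$draws[ps$draws$draw == i, ]
    expect_gte(g$cost[g$scenario == "increased"],
               g$cost[g$scenario == "standard"])
  }
})

test_that("range percentages follow the min-max formula", {
  mk <- function(min, max) {
    structure(list(summary = data.frame(scenario = "increased",
                                        outcome = "cost", min = min,
                                        max = max)), class = "pm_psa")
  }
  expect_equal(psa_range_pct(mk(5382, 12628), "increased", "cost"),
               100 * (12628 - 5382) / 5382)
  expect_equal(round(psa_range_pct(mk(5382, 12628), "increased", "cost"), 1),
               134.6)
  expect_equal(round(psa_range_pct(mk(18.78, 35.39), "increased", "cost"), 1),
               88.4)
  expect_equal(psa_range_pct(mk(7, 7), "increased", "cost"), 0)
  expect_error(psa_range_pct(mk(0, 4), "increased", "cost"), "undefined")
})
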