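test_that("the default plan covers discounts, horizons and all RR bounds", {
  p <- calibrated_fixture()
  plan <- owsa_plan(p)
  expect_equal(nrow(plan), 4 + 4 + 16)
  expect_equal(sum(plan$parameter == "discount"), 4)
  expect_equal(sum(grepl("^rr_", plan$parameter)), 16)
})

test_that("varying an increased-only RR leaves the standard scenario alone", {
  p <- calibrated_fixture()
  base_std <- accrue_outcomes(run_cohort(p, "standard"), p)$cost
  rows <- run_owsa(p, data.frame(parameter = "rr_stroke_incidence",
                                 label = c("lower95", "upper95"),
                                 value = c(1.02, 1.61)))
  std <- rows[rows$scenario == "standard", ]
  expect_equal(std$cost, rep(base_std, 2), tolerance = 1e-12)
})

test_that("a degenerate confidence interval reproduces the base case", {
  p <- calibrated_fixture()
  rr <- p$diseases$mi$rr_incidence$point
  base_inc <- accrue_outcomes(run_cohort(p, "increased"), p)$cost
  rows <- run_owsa(p, data.frame(parameter = "rr_mi_incidence",
                                 label = c("lower95", "upper95"),
                                 value = c(rr, rr)))
  expect_equal(rows$cost[rows$scenario == "increased"], rep(base_inc, 2),
               tolerance = 1e-12)
})

test_that("unknown parameter ids are rejected with the valid list", {
  expect_error(run_owsa(calibrated_fixture(),
                        data.frame(parameter = "rr_gout_incidence",
                                   label = "x", value = 1)),
               "valid ids.*rr_lung_cancer_incidence")
})

test_that("incremental cost percentage shrinks as the horizon grows", {
  m <- fitted_model()
  rows <- run_owsa(m, data.frame(parameter = "horizon",
                                 label = c("5y", "10y", "20y", "40y"),
                                 value = c(5, 10, 20, 40)))
  pct <- rows$pct_cost[rows$scenario == "increased"]
  expect_true(all(diff(pct) < 0))
  expect_gt(min(pct), m$incremental$pct_cost)  # base case is the limit
})

test_that("QALY loss at the lower RR bound never exceeds the upper bound's", {
  sa <- run_owsa(fitted_model())
  rr <- sa[grepl("^rr_", sa$parameter) & sa$scenario == "increased", ]
  ## COPD incidence is excluded: its state utility sits at the baseline cap,
  ## so a lower COPD RR leaves more of the cohort exposed to the costlier
  ## competing diseases and the QALY loss inverts (the same competing-risk
  ## mechanism behind the lung-cancer mortality cost inversion).
  rr <- rr[rr$parameter != "rr_copd_incidence", ]
  for (g in split(rr, rr$parameter)) {
    lo <- abs(g$incr_qaly[g$label == "lower95"])
    hi <- abs(g$incr_qaly[g$label == "upper95"])
    expect_lte(lo, hi + 1e-12)
  }
})

test_that("tornado tables rank by spread and demand paired bounds", {
  sa <- run_owsa(fitted_model())
  tt <- tornado_table(sa, "cost")
  expect_equal(nrow(tt), 8)
  expect_true(all(diff(tt$spread) <= 0))
  expect_true(all(tt$high >= tt$low))

  one <- sa[sa$parameter == "rr_copd_incidence", ]
  expect_equal(nrow(tornado_table(one, "qaly")), 1)

  sym <- run_owsa(calibrated_fixture(),
                  data.frame(parameter = "rr_copd_mortality",
                             label = c("lower95", "upper95"),
                             value = c(1.169, 1.169)))
  expect_equal(tornado_table(sym, "cost")$spread, 0, tolerance = 1e-12)

  unpaired <- sa[sa$label == "upper95", ]
  expect_error(tornado_table(unpaired, "cost"), "unpaired")
})
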