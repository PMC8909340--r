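test_that("transition matrix rows are valid probabilities", {
  p <- calibrated_fixture()
  for (age in c(40, 45, 62, 85, 99)) for (sc in c("standard", "increased")) {
    P <- transition_matrix(p, age, sc)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(rowSums(P)), rep(1, 13), tolerance = 1e-12)
  }
  ## absorbing death states
  P <- transition_matrix(p, 70, "standard")
  for (st in state_space("dead")) {
    e <- numeric(13); names(e) <- state_space(); e[st] <- 1
    expect_equal(P[st, ], e)
  }
  expect_error(transition_matrix(p, 120, "standard"), "horizon")
  expect_error(transition_matrix(p, 60, "nope"), "unknown scenario")
})

test_that("event-free exits reproduce hand-computed values at age 45", {
  p <- pmcohort:::ensure_gompertz_a(pm_params())
  p$background$calibration_scale <- 0  # isolate the disease exits
  P <- transition_matrix(p, 45, "standard")
  expect_equal(P["event_free", "event_free"],
               1 - (0.0001 + 0.0004 + 0.0011 + 0.008), tolerance = 1e-12)
  P <- transition_matrix(p, 45, "increased")
  expect_equal(P["event_free", "lc_y1"], 0.0001 * 1.42, tolerance = 1e-12)
  expect_equal(P["event_free", "copd"], 0.008 * 1.08, tolerance = 1e-12)
})

test_that("first-year disease states drain into their chronic states", {
  p <- calibrated_fixture()
  P <- transition_matrix(p, 50, "standard")
  expect_equal(unname(P["lc_y1", "lc_y1"]), 0)
  expect_gt(P["lc_y1", "lc_later"], 0.5)
  expect_equal(unname(P["mi_y1", "mi_y1"]), 0)
  ## no cross-disease transitions
  expect_equal(unname(P["copd", "stroke_y1"]), 0)
  expect_equal(unname(P["stroke_post", "mi_y1"]), 0)
})

test_that("cohort propagation conserves mass and death is monotone", {
  p <- calibrated_fixture()
  for (sc in c("standard", "increased")) {
    tr <- run_cohort(p, sc)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 61), tolerance = 1e-10)
    dead <- rowSums(tr$occupancy[, state_space("dead")])
    expect_true(all(diff(dead) >= -1e-15))
  }
})

test_that("propagation agrees with explicit matrix multiplication", {
  p <- calibrated_fixture()
  tr <- run_cohort(p, "increased", horizon = 20)
  v <- c(1, numeric(12))
  for (t in 1:20) {
    P <- transition_matrix(p, 40 + t - 1, "increased")
    inflow <- drop(v %*% P) - v * diag(P)
    expect_equal(unname(tr$entries[t, ]), unname(inflow), tolerance = 1e-14)
    v <- drop(v %*% P)
    expect_equal(unname(tr$occupancy[t + 1, ]), unname(v), tolerance = 1e-14)
  }
})

test_that("a frozen-age chain equals the matrix power", {
  z <- toy_params(incidence = 0.01, disease_mortality = 0.05,
                  background_q = 0.02)
  P <- transition_matrix(z, 47, "standard")  # constant schedules: age-free
  tr <- run_cohort(z, "standard", horizon = 12)
  Pt <- Reduce(`%*%`, rep(list(P), 12))
  expect_equal(unname(tr$occupancy[13, ]), unname(Pt[1, ]), tolerance = 1e-12)
})

test_that("pure background survival is exactly geometric", {
  q <- 0.03
  z <- toy_params(background_q = q)
  tr <- run_cohort(z, "standard")
  expect_equal(unname(tr$occupancy[, "event_free"]), (1 - q)^(0:60),
               tolerance = 1e-10)
  ## and with nothing at all, the cohort never moves
  z0 <- toy_params()
  tr0 <- run_cohort(z0, "standard")
  expect_equal(unname(tr0$occupancy[, "event_free"]), rep(1, 61))
})

test_that("increased exposure dominates standard in cumulative mortality", {
  for (seed in c(2, 5, 9)) {
    p <- random_param_set(seed)  # RR points drawn in [1, 2]
    dead_s <- rowSums(run_cohort(p, "standard")$occupancy[, 9:13])
    dead_i <- rowSums(run_cohort(p, "increased")$occupancy[, 9:13])
    expect_true(all(dead_i - dead_s >= -1e-12))
  }
})

test_that("infeasible exits are reported with state and age", {
  z <- toy_params_list(incidence = 0.3)  # 4 x 0.3 > 1
  p <- as_pm_params_quiet(z)
  expect_error(run_cohort(p, "standard"), "event_free.*age 40")
  expect_error(transition_matrix(p, 41, "standard"),
               class = "pmcohort_infeasible")
})

test_that("trace exports one row per cycle with occupancy and entries", {
  tr <- run_cohort(calibrated_fixture(), "standard")
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 61)
  expect_equal(df$age, 40:100)
  expect_true(all(c("event_free", "entry_dead_lc") %in% names(df)))
  expect_equal(df$entry_event_free, rep(0, 61))
})
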