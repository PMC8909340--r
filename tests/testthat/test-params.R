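test_that("packaged inputs load and validate", {
  p <- pm_params()
  expect_s3_class(p, "pm_params")
  expect_identical(validate_params(p), character(0))
  expect_equal(p$diseases$lung_cancer$rr_incidence$point, 1.42)
  expect_equal(p$diseases$stroke$rr_mortality$ci_low, 0.94)
  expect_equal(p$rewards$state_costs[["lc_y1"]], 19495)
  expect_equal(p$rewards$state_utilities[["copd"]], 0.8)
  expect_equal(p$settings$horizon, 60)
  ## COPD mortality: zero before 70
  expect_equal(schedule_value(p$diseases$copd$mortality, c(55, 72, 90)),
               c(0, 2e-4, 9e-4))
})

test_that("loading rejects out-of-range and malformed inputs by name", {
  x <- toy_params_list()
  x$rewards$state_utilities$lc_y1 <- 1.2
  expect_error(as_pm_params(x), "lc_y1.*1\\.2.*\\[0, 1\\]")
  x <- toy_params_list()
  x$diseases$mi$rr_incidence$point <- "high"
  expect_error(as_pm_params(x), "rr_incidence")
  x <- toy_params_list()
  x$rewards <- NULL
  expect_error(as_pm_params(x), "missing required key 'rewards'")
})

test_that("save/load round-trips a parameter set through YAML and JSON", {
  p <- pm_params()
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    save_params(p, f)
    p2 <- load_params(f)
    expect_equal(unclass(p2), unclass(p), tolerance = 1e-10)
    unlink(f)
  }
})

test_that("validate_params flags joint-exit and RR-ordering violations", {
  x <- toy_params_list(incidence = 0.9)  # 4 x 0.9 > 1 from event-free
  p <- as_pm_params_quiet(x)
  v <- validate_params(p)
  expect_true(any(grepl("exit probability > 1", v)))

  x <- toy_params_list()
  x$diseases$stroke$rr_mortality$ci_low <- 1.9  # above the point estimate
  v <- validate_params(as_pm_params_quiet(x))
  expect_true(any(grepl("stroke\\$rr_mortality", v)))
})

test_that("validate_params rejects single-field mutations of the fixture", {
  base <- yaml::read_yaml(system.file("extdata", "paper_2022.yaml",
                                      package = "pmcohort"))
  mutate <- list(
    function(x) { x$diseases$copd$incidence$value[2] <- 1.4; x },
    function(x) { x$diseases$mi$incidence$age_lower <- c(40, 30, 60, 70, 80); x },
    function(x) { x$diseases$lung_cancer$rr_mortality$per_increment <- 0; x },
    function(x) { x$rewards$death_costs$dead_lc <- -1; x },
    function(x) { x$rewards$state_utilities$mi_y1 <- -0.2; x },
    function(x) { x$scenarios$increased$concentration <- 5; x },
    function(x) { x$settings$cycle_length <- 2; x })
  for (f in mutate) {
    rejected <- tryCatch(length(validate_params(as_pm_params_quiet(f(base)))) > 0,
                         error = function(e) TRUE)
    expect_true(rejected)
  }
})

test_that("cpi adjustment scales linearly and composes", {
  expect_equal(cpi_adjust(100, 100, 110), 110)
  expect_equal(cpi_adjust(42.5, 97, 97), 42.5)
  expect_equal(cpi_adjust(250, 80, 100), 312.5)
  expect_equal(cpi_adjust(cpi_adjust(200, 80, 95), 95, 120),
               cpi_adjust(200, 80, 120))
  expect_error(cpi_adjust(-1, 100, 100), "positive")
})

test_that("rate-to-probability conversion is bounded and monotone", {
  expect_equal(rate_to_prob(0), 0)
  expect_equal(rate_to_prob(0.2109), 0.190144951663, tolerance = 1e-10)
  r <- seq(0, 3, by = 0.1)
  expect_true(all(diff(rate_to_prob(r)) > 0))
  expect_true(all(rate_to_prob(r) >= 0 & rate_to_prob(r) < 1))
  expect_error(rate_to_prob(-0.1), ">= 0")
})

test_that("relative-risk scaling is log-linear in concentration", {
  rr <- relative_risk(1.42, 1.02, 1.98, per_increment = 10)
  expect_equal(scale_rr(rr, 10), 1.42)
  expect_equal(scale_rr(rr, 0), 1.0)
  expect_equal(scale_rr(relative_risk(1.2, per_increment = 5), 10), 1.44)
  for (rr in list(relative_risk(1.08), relative_risk(1.9, 1.5, 2.2))) {
    expect_equal(scale_rr(rr, 3 + 4), scale_rr(rr, 3) * scale_rr(rr, 4),
                 tolerance = 1e-12)
  }
})
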