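# Logistic workload and sample-size determination.

test_that("the fitted estimand equals the closed-form log odds ratio for a 2x2 table", {
  # exposed: 20/100 events; unexposed: 10/100 events
  df <- data.frame(
    x = rep(c(1, 0), each = 100),
    y = c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  )
  f <- fit_logistic(df, outcome = "y", interest = "x")
  expect_true(f$converged)
  expect_equal(f$q, log((20 * 90) / (10 * 80)), tolerance = 1e-6)
  expect_equal(f$q, log(2.25), tolerance = 1e-6)
  # Wald CI structure
  expect_equal(f$ci, c(f$q - 1.96 * sqrt(f$v), f$q + 1.96 * sqrt(f$v)))
  expect_true(f$ci[1] <= f$q && f$q <= f$ci[2])
})

test_that("a null relationship yields a non-significant coefficient", {
  set.seed(31)
  df <- data.frame(x = rbinom(10000, 1, 0.5), z = rnorm(10000),
                   y = rbinom(10000, 1, 0.3))
  f <- fit_logistic(df, outcome = "y", interest = "x")
  expect_true(f$converged)
  expect_lt(abs(f$q), 3 * sqrt(f$v))
})

test_that("separation and degenerate inputs are reported as non-convergence", {
  sep <- data.frame(x = rep(c(0, 1), each = 10), y = rep(c(0, 1), each = 10))
  f <- fit_logistic(sep, outcome = "y", interest = "x")
  expect_false(f$converged)
  expect_true(is.na(f$q))

  const <- data.frame(x = rbinom(50, 1, 0.5), y = rep(0, 50))
  expect_false(fit_logistic(const, outcome = "y", interest = "x")$converged)

  expect_error(fit_logistic(data.frame(x = 1, y = 2), "y", "x"),
               class = "synthrep_schema_error")
  expect_error(fit_logistic(data.frame(x = c(1, 0), y = c(0.5, 0)), "y", "x"),
               class = "synthrep_schema_error")
  expect_error(fit_logistic(data.frame(x = c(1, 0), y = c(1, 0)), "y", "w"),
               class = "synthrep_schema_error")
})

test_that("the analytic sample size is monotone in power and rejects a null effect", {
  spec <- validation_spec()
  ns <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95), function(pw)
    analytic_sample_size(spec, power = pw), integer(1))
  expect_true(all(diff(ns) > 0))
  expect_error(analytic_sample_size(toy_spec(beta = 0)),
               class = "synthrep_config_error")
  expect_error(analytic_sample_size(spec, power = 1.2),
               class = "synthrep_value_error")
})

test_that("the analytic sample size is consistent with brute-force power simulation", {
  # single balanced binary covariate, OR = 1.8, event rate 0.12; the oracle
  # is a direct data-generating simulation independent of the package
  spec <- toy_spec(beta = log(1.8), rate = 0.12)
  n_star <- analytic_sample_size(spec)
  sim_power <- function(n, reps = 400) {
    hits <- 0L
    for (r in seq_len(reps)) {
      set.seed(1000 + 7 * r + n)
      x <- rbinom(n, 1, 0.5)
      b0 <- uniroot(function(b) mean(plogis(b + log(1.8) * x)) - 0.12,
                    c(-10, 10))$root
      y <- rbinom(n, 1, plogis(b0 + log(1.8) * x))
      ft <- suppressWarnings(glm(y ~ x, family = binomial()))
      z <- coef(ft)[["x"]] / sqrt(vcov(ft)["x", "x"])
      hits <- hits + (abs(z) > 1.96)
    }
    hits / reps
  }
  # within 25% of the empirical 80%-power size: power is below target a
  # quarter below n_star and above target a quarter above it
  expect_lt(sim_power(round(0.75 * n_star)), 0.80)
  expect_gt(sim_power(round(1.25 * n_star)), 0.80)
})

test_that("sample-size calibration finds the empirical power target", {
  pop <- toy_pop()  # OR = 2, rate 0.5: strong effect, small n
  n_cal <- calibrate_sample_size(pop, floor_n = 20, step = 10, reps = 300,
                                 target = 0.8, seed = 31)
  expect_gte(as.integer(n_cal), 20L)

  # brute-force grid over the same candidates with an independent seed
  grid_power <- function(n) empirical_power(pop, n, reps = 300, seed = 77)
  oracle_n <- NA
  for (n in seq(20, 400, by = 10)) {
    if (grid_power(n) >= 0.8) { oracle_n <- n; break }
  }
  expect_lte(abs(as.integer(n_cal) - oracle_n), 20)

  # re-estimated power at the calibrated n stays near the target
  pw <- empirical_power(pop, as.integer(n_cal), reps = 300, seed = 99)
  expect_gte(pw, 0.8 - 3 * sqrt(0.8 * 0.2 / 300))

  # a floor that already meets the target is returned unchanged
  expect_identical(as.integer(calibrate_sample_size(pop, floor_n = 500, step = 10,
                                                    reps = 200, seed = 31)), 500L)
  expect_error(calibrate_sample_size(pop, floor_n = 5), class = "synthrep_value_error")
})
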