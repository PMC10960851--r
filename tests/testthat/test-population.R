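# Population simulation: archetype presets, copula marginals, intercept
# calibration, estimand definition, and sampling semantics.

test_that("built-in archetypes carry the study dataset characteristics", {
  specs <- builtin_archetypes()
  expect_named(specs, c("n0147_like", "cchs_like", "dccg_like"))

  expect_equal(specs$n0147_like$study_n, 1420L)
  expect_equal(specs$n0147_like$n_pop, 1365135)
  expect_equal(specs$n0147_like$target_event_rate, 0.12)
  expect_equal(exp(specs$n0147_like$target_log_or), 1.8)

  expect_equal(specs$cchs_like$study_n, 903L)
  expect_equal(specs$cchs_like$n_pop, 35440000)
  expect_equal(specs$cchs_like$target_event_rate, 0.63)
  expect_equal(exp(specs$cchs_like$target_log_or), 1.47)

  expect_equal(specs$dccg_like$study_n, 2625L)
  expect_equal(specs$dccg_like$n_pop, 30000)
  expect_equal(specs$dccg_like$target_event_rate, 0.16)
  expect_equal(exp(specs$dccg_like$target_log_or), 1.58)

  for (s in specs) {
    expect_length(s$covariates, 6)
    expect_true(s$interest %in% vapply(s$covariates, `[[`, character(1), "name"))
  }
})

test_that("archetype validation rejects malformed specifications", {
  covs <- list(covariate_binary("x", 0.5, interest = TRUE),
               covariate_binary("w", 0.3))
  good <- archetype_spec("ok", 1000, 100, 0.3, log(2), covs)
  expect_s3_class(good, "archetype_spec")

  expect_error(archetype_spec("bad", 1000, 100, 1.2, log(2), covs),
               class = "synthrep_config_error")
  expect_error(
    archetype_spec("bad", 1000, 100, 0.3, log(2),
                   list(covariate_binary("x", 0.5), covariate_binary("w", 0.3))),
    class = "synthrep_config_error")
  badR <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(archetype_spec("bad", 1000, 100, 0.3, log(2), covs, badR),
               class = "synthrep_config_error")
  expect_error(archetype_spec("bad", 1000, 100, 0.3, log(2), covs,
                              matrix(c(1, 0.5, 0.2, 1), 2)),
               class = "synthrep_config_error")
})

test_that("intercept calibration is exact in the symmetric null case", {
  # no covariate effects and a 50% target rate force a zero intercept
  spec <- toy_spec(beta = 0, rate = 0.5)
  pop <- build_population(spec, seed = 2, cap = 20000)
  expect_lt(abs(pop$intercept), 1e-6)
})

test_that("realized event rate matches the target after calibration", {
  pop <- n0147_pop()
  expect_lt(abs(pop$realized_event_rate - 0.12), 0.005)

  # the calibration contract itself is on the expected rate: the calibrated
  # intercept puts the population-average event probability within 1e-4 of
  # the target, before Bernoulli noise
  toy <- toy_pop()
  eta <- toy$intercept + log(2) * toy$records$x
  expect_lt(abs(mean(plogis(eta)) - 0.5), 1e-4)
  # realized rate then differs from the target only by binomial noise
  expect_lt(abs(toy$realized_event_rate - 0.5),
            4 * sqrt(0.25 / toy$n_sim))
})

test_that("the stored estimand is exactly the full-population refit", {
  pop <- toy_pop()
  refit <- stats::glm(y ~ ., data = pop$records, family = stats::binomial())
  expect_equal(unname(coef(refit)[pop$interest]), pop$true_estimand,
               tolerance = 1e-10)
})

test_that("population estimand recovers the generating coefficient", {
  # independent large-sample brute-force fit of the same generating process
  # as the oracle for the single-binary-covariate population
  pop <- toy_pop()
  nbig <- 200000
  set.seed(21)
  x <- rbinom(nbig, 1, 0.5)
  b0 <- uniroot(function(b) mean(plogis(b + log(2) * x)) - 0.5, c(-5, 5),
                tol = 1e-10)$root
  y <- rbinom(nbig, 1, plogis(b0 + log(2) * x))
  oracle_fit <- glm(y ~ x, family = binomial())
  se_comb <- sqrt(vcov(oracle_fit)["x", "x"] + 16.5 / pop$n_sim)
  expect_lt(abs(pop$true_estimand - log(2)), 3 * sqrt(16.5 / pop$n_sim))
  expect_lt(abs(pop$true_estimand - coef(oracle_fit)[["x"]]), 3 * se_comb)
})

test_that("copula marginals reproduce the declared distributions", {
  spec <- archetype_spec(
    "marg", n_pop = 1e6, study_n = 100, target_event_rate = 0.3,
    target_log_or = log(1.5),
    covariates = list(
      covariate_binary("x", p = 0.25, interest = TRUE),
      covariate_continuous("g", "gamma", list(shape = 4, rate = 0.3)),
      covariate_continuous("z", "normal", list(mean = 10, sd = 2)),
      covariate_categorical("c", c("a", "b", "d"), c(0.2, 0.5, 0.3))
    ),
    dependence = {
      R <- diag(4); R[1, 2] <- R[2, 1] <- 0.3; R[2, 3] <- R[3, 2] <- 0.4; R
    }
  )
  pop <- build_population(spec, seed = 3, cap = 100000)
  r <- pop$records
  ks_g <- suppressWarnings(ks.test(r$g, pgamma, shape = 4, rate = 0.3))
  ks_z <- suppressWarnings(ks.test(r$z, pnorm, 10, 2))
  expect_lt(unname(ks_g$statistic), 0.02)
  expect_lt(unname(ks_z$statistic), 0.02)
  expect_lt(abs(mean(r$x) - 0.25), 0.01)
  expect_lt(max(abs(prop.table(table(r$c)) - c(0.2, 0.5, 0.3))), 0.01)
  # dependence actually induced
  expect_gt(cor(r$x, r$g), 0.1)
})

test_that("draw_sample is seed-deterministic with-replacement sampling", {
  pop <- toy_pop()
  s1 <- draw_sample(pop, 500, seed = 4)
  s2 <- draw_sample(pop, 500, seed = 4)
  s3 <- draw_sample(pop, 500, seed = 8)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_false(identical(attr(s1, "row_ids"), attr(s3, "row_ids")))
  expect_equal(nrow(s1), 500)

  big <- draw_sample(pop, pop$n_sim + 5000, seed = 4)
  expect_equal(nrow(big), pop$n_sim + 5000)
  expect_gt(anyDuplicated(attr(big, "row_ids")), 0)

  expect_error(draw_sample(pop, 0, seed = 1), class = "synthrep_value_error")
})

test_that("archetype YAML round-trips through serialization", {
  spec <- builtin_archetypes()$dccg_like
  path <- withr::local_tempfile(fileext = ".yaml")
  write_archetype(spec, path)
  back <- read_archetype(path)
  expect_equal(back$study_n, spec$study_n)
  expect_equal(back$target_log_or, spec$target_log_or, tolerance = 1e-9)
  expect_equal(unname(back$dependence), unname(spec$dependence), tolerance = 1e-8)
  expect_equal(vapply(back$covariates, `[[`, character(1), "kind"),
               vapply(spec$covariates, `[[`, character(1), "kind"))
})
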