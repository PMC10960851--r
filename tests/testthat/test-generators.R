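# Sequential tree-based synthesizer and the parametric oracle baseline.

make_train <- function(n = 400, seed = 13) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  data.frame(
    v1 = x,
    v2 = factor(ifelse(runif(n) < 0.2 + 0.6 * x, "high", "low")),
    g = rgamma(n, shape = 3, rate = 0.5) + 2 * x,
    y = rbinom(n, 1, plogis(-1 + x))
  )
}

test_that("a p-column table yields p - 1 conditional models in sequence", {
  tr <- make_train()
  m <- fit_sequential(tr, order = names(tr), control = seq_control("cart"))
  expect_length(m$models, 3)
  expect_identical(m$variable_order, names(tr))

  # one-variable table degenerates to marginal resampling
  one <- fit_sequential(tr[, "g", drop = FALSE], control = seq_control("cart"))
  expect_length(one$models, 0)
  d <- generate(one, 1000, seed = 2)
  expect_true(all(d$g %in% tr$g))

  expect_error(fit_sequential(tr[0, ]), class = "synthrep_value_error")
  expect_error(fit_sequential(tr, order = c("v1", "v2")),
               class = "synthrep_config_error")
})

test_that("a deterministic dependency is learned and reproduced", {
  set.seed(17)
  tr <- data.frame(a = rbinom(300, 1, 0.5))
  tr$b <- tr$a
  for (lrn in c("cart", "boosted")) {
    m <- fit_sequential(tr, order = c("a", "b"),
                        control = seq_control(lrn))
    # exhaustive check on the binary truth table: the fitted conditional
    # puts essentially all mass on the matching class
    P <- synthrep:::predict_class_probs(
      m$models[["b"]],
      data.frame(a = factor(c("0", "1"), levels = c("0", "1"))))
    expect_gt(P[1, "0"], 0.99)
    expect_gt(P[2, "1"], 0.99)

    d <- generate(m, 5000, seed = 3)
    expect_gte(mean(d$a == d$b), 0.99)
  }
})

test_that("generation preserves schema, respects k, and is seed-deterministic", {
  tr <- make_train()
  sch <- infer_schema(tr)
  sch$g$support <- c(0, Inf)
  for (lrn in c("cart", "boosted")) {
    m <- fit_sequential(tr, schema = sch, control = seq_control(lrn))
    d <- generate(m, 10 * nrow(tr), seed = 4)
    expect_equal(nrow(d), 10 * nrow(tr))          # 10x amplification
    expect_identical(names(d), names(tr))
    expect_true(all(d$v1 %in% c(0, 1)))
    expect_s3_class(d$v2, "factor")
    expect_identical(levels(d$v2), levels(tr$v2))
    expect_true(all(d$y %in% c(0, 1)))
    expect_true(all(d$g >= 0))                    # boundary correction
    expect_identical(as.data.frame(generate(m, 50, seed = 9)),
                     as.data.frame(generate(m, 50, seed = 9)))
    expect_error(generate(m, 0), class = "synthrep_value_error")
  }
})

test_that("sampled class frequencies follow the conditional model probabilities", {
  tr <- make_train(n = 600, seed = 19)
  m <- fit_sequential(tr, order = c("v1", "v2", "g", "y"),
                      control = seq_control("cart"))
  d <- generate(m, 20000, seed = 6)
  # at a fixed predecessor value the deep CART leaf reproduces the empirical
  # conditional distribution of the training data
  for (xv in c(0, 1)) {
    p_tr <- prop.table(table(tr$v2[tr$v1 == xv]))
    obs <- table(d$v2[d$v1 == xv])
    expect_gt(suppressWarnings(chisq.test(obs, p = p_tr)$p.value), 0.001)
  }
})

test_that("kernel-smoothed continuous synthesis preserves the training mean", {
  tr <- make_train(n = 500, seed = 23)
  for (lrn in c("cart", "boosted")) {
    m <- fit_sequential(tr, order = c("v1", "g", "v2", "y"),
                        control = seq_control(lrn))
    k <- 40000
    d <- generate(m, k, seed = 8)
    tol <- 4 * sd(tr$g) * sqrt(1 / k + 1 / nrow(tr))
    expect_lt(abs(mean(d$g) - mean(tr$g)), tol)
  }
})

test_that("the oracle generator reproduces the sample's distribution and estimand", {
  pop <- validation_pop()
  s <- draw_sample(pop, 1000, seed = 41)
  om <- fit_oracle(s, outcome = "y")
  k <- 100000
  d <- generate(om, k, seed = 42)

  # event rate: binomial Monte Carlo error around the sample rate
  p <- mean(s$y)
  expect_lt(abs(mean(d$y) - p), 3 * sqrt(p * (1 - p) / k))

  # covariate marginals are bootstrap copies
  expect_lt(unname(suppressWarnings(ks.test(d$z1, s$z1)$statistic)), 0.02)
  expect_lt(abs(mean(d$exposure) - mean(s$exposure)), 0.01)

  # large-k refit recovers the sample coefficient
  fs <- fit_logistic(s, "y", "exposure")
  fk <- fit_logistic(d, "y", "exposure")
  expect_lt(abs(fk$q - fs$q), 3 * sqrt(2 * fs$v * 1000 / k + fk$v))

  # a sample with an unfittable outcome cannot back an oracle
  bad <- s; bad$y <- 0L
  expect_error(fit_oracle(bad), class = "synthrep_oracle_unavailable")
})
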