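# Shared fixtures, built once per test run and cached. All fixture seeds are
# small fixed integers.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# Single balanced binary covariate, strong effect, balanced outcome.
toy_spec <- function(beta = log(2), rate = 0.5, p = 0.5) {
  archetype_spec("toy", n_pop = 200000, study_n = 200,
                 target_event_rate = rate, target_log_or = beta,
                 covariates = list(covariate_binary("x", p = p, interest = TRUE)))
}

toy_pop <- function() cached("toy_pop", function() {
  build_population(toy_spec(), seed = 5, cap = 50000)
})

# Small mixed-covariate archetype whose 80%-power sample size is near 1000;
# used for oracle-generator validation of the inferential machinery.
validation_spec <- function() {
  nms <- c("exposure", "z1", "z2")
  R <- diag(3); dimnames(R) <- list(nms, nms)
  R["exposure", "z1"] <- R["z1", "exposure"] <- 0.2
  R["z1", "z2"] <- R["z2", "z1"] <- 0.15
  archetype_spec("validation", n_pop = 200000, study_n = 1000,
                 target_event_rate = 0.15, target_log_or = log(1.8),
                 covariates = list(
                   covariate_binary("exposure", p = 0.30, interest = TRUE),
                   covariate_continuous("z1", "normal", list(mean = 0, sd = 1), beta = 0.3),
                   covariate_binary("z2", p = 0.4, beta = 0.25)
                 ),
                 dependence = R)
}

validation_pop <- function() cached("validation_pop", function() {
  build_population(validation_spec(), seed = 11, cap = 40000)
})

n0147_pop <- function() cached("n0147_pop", function() {
  build_population(builtin_archetypes()$n0147_like, seed = 7, cap = 50000)
})

dccg_pop <- function() cached("dccg_pop", function() {
  build_population(builtin_archetypes()$dccg_like, seed = 9, cap = 30000)
})

# Sequential-synthesis emulation run shared by the acceptance checks:
# fast CART mode, 200 iterations, 10 synthetic datasets, no amplification.
cart_run <- function() cached("cart_run", function() {
  run_simulation(n0147_pop(), nsim = 200, generators = "sequential",
                 learner = "cart", m_max = 10, amplifications = 1,
                 master_seed = 101)
})

# Convenience constructor for hand-built estimates in metric tests.
fe <- function(q, v, n_fit = 100) synthrep:::new_fitted_estimate(q, v, TRUE, n_fit)
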