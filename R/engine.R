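# The simulation engine: orchestrates the factorial design over generative
# model, adjustment mode, number of synthetic datasets m, and amplification,
# and emits tidy per-scenario summaries.

#' Full factorial scenario grid
#'
#' The Cartesian product of generative models, adjustment modes, numbers of
#' synthetic datasets and amplification levels. With 2 generators, 2 modes,
#' m = 1..20 and 4 amplification levels this is the full 320-scenario design.
#'
#' @param generators Character vector of generator labels.
#' @param modes `"single"` and/or `"multiple"`.
#' @param m Integer vector of numbers of synthetic datasets.
#' @param amplifications Numeric vector of amplification factors (`k = a * n`).
#' @return Tibble with one row per scenario.
#' @export
#' @examples
#' nrow(scenario_grid())  # 320
scenario_grid <- function(generators = c("sequential", "oracle"),
                          modes = c("single", "multiple"),
                          m = 1:20, amplifications = c(1, 2, 5, 10)) {
  g <- expand.grid(generator = generators, mode = modes, m = m,
                   amplification = amplifications,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g)
}

fit_generator <- function(kind, sample, schema, learner, seed) {
  with_seed(seed, switch(kind,
    sequential = fit_sequential(sample, schema = schema, outcome = "y",
                                control = seq_control(learner = learner)),
    oracle = fit_oracle(sample, outcome = "y", schema = schema),
    stop_config(sprintf("unknown generator '%s'", kind))
  ))
}

#' Run the replicability simulation for one archetype population
#'
#' For each of `nsim` iterations: draw a study sample of size `n` with
#' replacement, fit the real-data logistic workload, fit each generative
#' model once on the sample, and for every amplification level generate
#' `m_max` synthetic datasets of size `k = a * n` and fit the workload on
#' each. Scenarios with smaller m reuse prefixes of the `m_max` generated
#' datasets, exactly as a custodian would release the first m of a batch;
#' each dataset's generation seed depends only on its own index, so prefix
#' reuse is reproducible across runs with different `m_max`. Failures of the
#' generator, the generation step or the workload fit are recorded and the
#' affected iteration is treated as missing when metrics are aggregated.
#'
#' @param pop A `synth_population`.
#' @param nsim Number of simulation iterations.
#' @param n Study sample size; defaults to the archetype's `study_n`.
#' @param generators Generator kinds to evaluate (`"sequential"`, `"oracle"`).
#' @param learner Conditional learner for the sequential synthesizer
#'   (`"boosted"` or `"cart"`).
#' @param m_max Number of synthetic datasets generated per model.
#' @param amplifications Amplification factors (`k = a * n`).
#' @param master_seed Master seed; two runs with the same master seed produce
#'   identical results.
#' @param progress Print a progress message every 50 iterations.
#' @return A `replicability_sim` object holding per-iteration real and
#'   synthetic estimates; summarize with [summarize_scenarios()].
#' @export
run_simulation <- function(pop, nsim = 1000, n = NULL,
                           generators = "sequential", learner = "boosted",
                           m_max = 20, amplifications = 1,
                           master_seed = 1L, progress = FALSE) {
  stopifnot(inherits(pop, "synth_population"))
  if (nsim < 1) stop_value("nsim must be >= 1")
  n <- as.integer(n %||% pop$spec$study_n)
  G <- length(generators); A <- length(amplifications)

  dims <- c(nsim, G, A, m_max)
  Q <- array(NA_real_, dims); V <- array(NA_real_, dims)
  C <- array(FALSE, dims)
  real_q <- rep(NA_real_, nsim); real_v <- rep(NA_real_, nsim)
  real_conv <- logical(nsim)

  for (i in seq_len(nsim)) {
    it_seed <- spawn_seed(master_seed, i)
    s <- draw_sample(pop, n, seed = it_seed)
    real <- fit_logistic(s, outcome = "y", interest = pop$interest)
    real_conv[i] <- real$converged
    if (real$converged) { real_q[i] <- real$q; real_v[i] <- real$v }

    for (g in seq_len(G)) {
      model <- tryCatch(
        fit_generator(generators[g], s, pop$schema, learner,
                      seed = spawn_seed(master_seed, i, 1000 + g)),
        error = function(e) NULL
      )
      if (is.null(model)) next
      for (a in seq_len(A)) {
        k <- as.integer(round(amplifications[a] * n))
        for (j in seq_len(m_max)) {
          f <- tryCatch({
            d <- generate(model, k, seed = spawn_seed(master_seed, i, 2000 + g, a, j))
            fit_logistic(d, outcome = "y", interest = pop$interest)
          }, error = function(e) NULL)
          if (!is.null(f) && f$converged) {
            Q[i, g, a, j] <- f$q; V[i, g, a, j] <- f$v; C[i, g, a, j] <- TRUE
          }
        }
      }
    }
    if (progress && i %% 50 == 0) message(sprintf("iteration %d / %d", i, nsim))
  }

  structure(
    list(archetype = pop$spec$name, e_p = pop$true_estimand, n = n,
         nsim = nsim, m_max = m_max, generators = generators,
         amplifications = amplifications, learner = learner,
         master_seed = master_seed,
         real = list(q = real_q, v = real_v, converged = real_conv),
         synth = list(q = Q, v = V, converged = C)),
    class = "replicability_sim"
  )
}

#' @export
print.replicability_sim <- function(x, ...) {
  cat(sprintf("<replicability_sim '%s'> nsim=%d n=%d m_max=%d generators=%s amp=%s\n",
              x$archetype, x$nsim, x$n, x$m_max,
              paste(x$generators, collapse = "/"),
              paste(x$amplifications, collapse = "/")))
  cat(sprintf("  real-fit failures: %d\n", sum(!x$real$converged)))
  invisible(x)
}

# Combined estimate for one iteration of one scenario, or NULL if any needed
# fit is missing.
scenario_estimate <- function(sim, i, g, a, mode, m) {
  k <- as.integer(round(sim$amplifications[a] * sim$n))
  if (mode == "multiple") {
    if (!all(sim$synth$converged[i, g, a, seq_len(m)])) return(NULL)
    fits <- lapply(seq_len(m), function(j) {
      new_fitted_estimate(sim$synth$q[i, g, a, j], sim$synth$v[i, g, a, j], TRUE, k)
    })
    combine_estimates(fits, n = sim$n, k = k)
  } else {
    # The unadjusted path always analyses the first released dataset; m does
    # not enter, matching its use as a naive single-dataset baseline.
    if (!sim$synth$converged[i, g, a, 1]) return(NULL)
    single_estimate(new_fitted_estimate(sim$synth$q[i, g, a, 1],
                                        sim$synth$v[i, g, a, 1], TRUE, k))
  }
}

#' Aggregate a simulation run into per-scenario metric summaries
#'
#' Computes, for every requested scenario (generator x mode x m x
#' amplification), the eight replicability metrics with Monte Carlo standard
#' errors: decision agreement, estimate agreement, standardized-difference
#' pass rate and CI overlap against the real-sample analysis, and bias,
#' bias-eliminated coverage, power and empirical SE against the population
#' estimand. Iterations with a failed real fit, generator fit, or any needed
#' synthetic fit are excluded listwise and counted in `n_missing`; scenarios
#' missing more than half their iterations are flagged.
#'
#' @param sim A `replicability_sim` from [run_simulation()].
#' @param modes Modes to evaluate.
#' @param m_values Values of m to evaluate (defaults to `1:m_max`).
#' @return Tidy tibble: one row per scenario and metric, with columns
#'   `archetype`, `generator`, `mode`, `m`, `amplification`, `metric`,
#'   `value`, `mcse`, `n_used`, `n_missing`, `flagged`.
#' @export
summarize_scenarios <- function(sim, modes = c("single", "multiple"),
                                m_values = NULL) {
  stopifnot(inherits(sim, "replicability_sim"))
  m_values <- m_values %||% seq_len(sim$m_max)
  if (max(m_values) > sim$m_max) stop_value("m_values exceed the generated m_max")
  rows <- list()

  for (g in seq_along(sim$generators)) {
    for (a in seq_along(sim$amplifications)) {
      for (mode in modes) {
        for (m in m_values) {
          dec <- est <- std <- ovl <- qs <- sig <- rep(NA_real_, sim$nsim)
          ci_lo <- ci_hi <- rep(NA_real_, sim$nsim)
          for (i in seq_len(sim$nsim)) {
            if (!sim$real$converged[i]) next
            ce <- scenario_estimate(sim, i, g, a, mode, m)
            if (is.null(ce)) next
            re <- new_fitted_estimate(sim$real$q[i], sim$real$v[i], TRUE, sim$n)
            dec[i] <- decision_agreement(re, ce)
            est[i] <- estimate_agreement(re$ci, ce$q_bar)
            std[i] <- standardized_difference(re, ce)$pass
            ovl[i] <- ci_overlap(re$ci, ce$ci)
            qs[i] <- ce$q_bar
            sig[i] <- as.numeric(abs(ce$z) > 1.96)
            ci_lo[i] <- ce$ci[1]; ci_hi[i] <- ce$ci[2]
          }
          used <- which(!is.na(qs))
          n_used <- length(used)
          n_missing <- sim$nsim - n_used
          if (n_used == 0) next
          q_mean <- mean(qs[used])
          cov_val <- mean(ci_lo[used] <= q_mean & q_mean <= ci_hi[used])
          se_emp <- if (n_used > 1) stats::sd(qs[used]) else NA_real_
          vals <- c(
            decision_agreement = mean(dec[used]),
            estimate_agreement = mean(est[used]),
            standardized_difference = mean(std[used]),
            ci_overlap = mean(ovl[used]),
            bias = q_mean - sim$e_p,
            coverage = cov_val,
            power = mean(sig[used]),
            emp_se = se_emp
          )
          mcses <- c(
            decision_agreement = mcse_coverage(vals[["decision_agreement"]], n_used),
            estimate_agreement = mcse_coverage(vals[["estimate_agreement"]], n_used),
            standardized_difference = mcse_coverage(vals[["standardized_difference"]], n_used),
            ci_overlap = stats::sd(ovl[used]) / sqrt(n_used),
            bias = se_emp / sqrt(n_used),
            coverage = mcse_coverage(cov_val, n_used),
            power = mcse_coverage(vals[["power"]], n_used),
            emp_se = if (n_used > 1) se_emp / sqrt(2 * (n_used - 1)) else NA_real_
          )
          rows[[length(rows) + 1]] <- tibble::tibble(
            archetype = sim$archetype,
            generator = sim$generators[g],
            mode = mode,
            m = as.integer(m),
            amplification = sim$amplifications[a],
            metric = names(vals),
            value = unname(vals),
            mcse = unname(mcses),
            n_used = n_used,
            n_missing = n_missing,
            flagged = n_missing > sim$nsim / 2
          )
        }
      }
    }
  }
  if (length(rows) == 0) stop_value("no scenario produced any usable iteration")
  dplyr::bind_rows(rows)
}

#' Write tidy scenario results to CSV
#'
#' @param results Tibble from [summarize_scenarios()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' Plot metric-vs-m curves per scenario
#'
#' One panel per metric, with one line per adjustment mode, faceted rows by
#' amplification when several levels are present, and Monte Carlo SE ribbons.
#'
#' @param results Tibble from [summarize_scenarios()].
#' @param metrics Metrics to include (default: all present).
#' @param file Optional path; when given, the figure is saved there.
#' @return The ggplot object, invisibly.
#' @export
report_results <- function(results, metrics = NULL, file = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    stop_value("results are empty; nothing to report")
  }
  metrics <- metrics %||% unique(results$metric)
  df <- results[results$metric %in% metrics, , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$value,
                                        colour = .data$mode,
                                        linetype = factor(.data$amplification))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$mcse,
                                      ymax = .data$value + .data$mcse,
                                      fill = .data$mode,
                                      group = interaction(.data$mode, .data$amplification)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of synthetic datasets m", y = "metric value",
                  colour = "mode", fill = "mode", linetype = "amplification") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 10, height = 7)
  invisible(p)
}

#' Membership-disclosure risk of pooled synthetic datasets
#'
#' Draws one study sample, fits the requested generative model, pools `m`
#' generated synthetic datasets of size `k = amplification * n`, and runs the
#' membership attack against an attack sample with member fraction
#' `n / N_pop` (the nominal population size, even when the simulated
#' population is capped).
#'
#' @param pop A `synth_population`.
#' @param n Study sample size; defaults to the archetype's `study_n`.
#' @param m Number of pooled synthetic datasets.
#' @param amplification Amplification factor.
#' @param generator `"sequential"` or `"oracle"`.
#' @param learner Sequential-synthesis learner.
#' @param config Optional [attack_config()]; by default all covariates (not
#'   the outcome) are quasi-identifiers, `h = 0`, 20 continuous bins and
#'   member fraction `n / N_pop`.
#' @param seed Integer seed.
#' @return List with the `attack_result` and the scenario settings.
#' @export
evaluate_membership_disclosure <- function(pop, n = NULL, m = 10,
                                           amplification = 1,
                                           generator = "sequential",
                                           learner = "boosted",
                                           config = NULL, seed = 1L) {
  stopifnot(inherits(pop, "synth_population"))
  n <- as.integer(n %||% pop$spec$study_n)
  s <- draw_sample(pop, n, seed = spawn_seed(seed, 1))
  model <- fit_generator(generator, s, pop$schema, learner,
                         seed = spawn_seed(seed, 2))
  k <- as.integer(round(amplification * n))
  pooled <- dplyr::bind_rows(lapply(seq_len(m), function(j) {
    generate(model, k, seed = spawn_seed(seed, 3, j))
  }))
  config <- config %||% attack_config(
    quasi_identifiers = setdiff(names(pop$records), "y"),
    member_fraction = n / pop$n_pop
  )
  att <- build_attack_sample(pop, attr(s, "row_ids"), config,
                             seed = spawn_seed(seed, 4))
  res <- membership_attack(pooled, att, config, schema = pop$schema)
  list(result = res, archetype = pop$spec$name, generator = generator,
       m = m, amplification = amplification, n = n,
       member_fraction = config$member_fraction, seed = seed)
}
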