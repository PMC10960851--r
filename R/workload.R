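# The analytic workload: logistic regression with Wald inference, plus
# sample-size determination (analytic floor and empirical power calibration).

new_fitted_estimate <- function(q, v, converged, n_fit, z_crit = 1.96) {
  if (!converged || !is.finite(q) || !is.finite(v)) {
    return(structure(list(q = NA_real_, v = NA_real_,
                          ci = c(NA_real_, NA_real_), p_value = NA_real_,
                          converged = FALSE, n_fit = n_fit),
                     class = "fitted_estimate"))
  }
  se <- sqrt(v)
  structure(
    list(q = q, v = v, ci = c(q - z_crit * se, q + z_crit * se),
         p_value = 2 * stats::pnorm(-abs(q) / se),
         converged = TRUE, n_fit = n_fit),
    class = "fitted_estimate"
  )
}

#' @export
print.fitted_estimate <- function(x, ...) {
  if (!x$converged) {
    cat("<fitted_estimate> (not converged)\n")
  } else {
    cat(sprintf("<fitted_estimate> q = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                x$q, sqrt(x$v), x$ci[1], x$ci[2], x$p_value))
  }
  invisible(x)
}

#' Fit the logistic-regression workload and extract the estimand
#'
#' Fits a maximum-likelihood logistic regression of the binary outcome on all
#' other columns as main effects and returns the coefficient of interest with
#' its variance, large-sample Wald 95% confidence interval (critical value
#' 1.96) and normal p-value. Non-convergence — including separation, detected
#' as an exploding standard error — is reported through `converged = FALSE`
#' rather than an error, so the simulation engine can treat the iteration as
#' missing.
#'
#' @param sample Rectangular table of covariates plus the outcome column.
#' @param outcome Name of the binary outcome column.
#' @param interest Name of the (binary, numerically coded) covariate of
#'   interest whose coefficient is the estimand.
#' @param z_crit Wald critical value (fixed at 1.96 throughout the package).
#' @return A `fitted_estimate`: list with `q`, `v`, `ci`, `p_value`,
#'   `converged`, `n_fit`.
#' @export
fit_logistic <- function(sample, outcome = "y", interest, z_crit = 1.96) {
  if (!is.data.frame(sample)) stop_schema("sample must be a data frame")
  if (!outcome %in% names(sample)) stop_schema(sprintf("outcome column '%s' not found", outcome))
  if (!interest %in% names(sample)) stop_schema(sprintf("interest column '%s' not found", interest))
  if (nrow(sample) < 2) stop_schema("need at least 2 rows to fit the workload")
  yv <- sample[[outcome]]
  if (!all(yv %in% c(0, 1))) stop_schema("outcome must be binary 0/1")
  n_fit <- nrow(sample)
  if (length(unique(yv)) < 2) {
    return(new_fitted_estimate(NA_real_, NA_real_, FALSE, n_fit))
  }

  fml <- stats::reformulate(setdiff(names(sample), outcome), response = outcome)
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = sample)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(new_fitted_estimate(NA_real_, NA_real_, FALSE, n_fit))

  cf <- stats::coef(fit)
  if (!interest %in% names(cf) || !is.finite(cf[[interest]])) {
    return(new_fitted_estimate(NA_real_, NA_real_, FALSE, n_fit))
  }
  q <- unname(cf[[interest]])
  v <- tryCatch(unname(stats::vcov(fit)[interest, interest]), error = function(e) NA_real_)
  ok <- fit$converged && is.finite(v) && v >= 0 && sqrt(v) < 10
  new_fitted_estimate(q, v, ok, n_fit, z_crit = z_crit)
}

#' Analytic sample-size floor for the logistic workload
#'
#' Closed-form sample size for detecting the archetype's target log odds
#' ratio on a binary covariate of interest at the target event rate, in the
#' Hsieh variance-inflation style. The event probabilities at the two
#' exposure levels are solved from the overall event rate and the odds ratio;
#' the Wald variance of the log odds ratio is the usual two-group form
#' `[1/(p0 q0 (1-px)) + 1/(p1 q1 px)] / n`, and the multiple-covariate
#' inflation `1 / (1 - rho^2)` uses the squared multiple correlation of the
#' covariate of interest with the remaining covariates on the latent copula
#' scale. Covariate adjustment and event-rate heterogeneity are only
#' approximated, so this value serves as a floor for the empirical
#' calibration in [calibrate_sample_size()], which is authoritative.
#'
#' @param spec An [archetype_spec()].
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level.
#' @return Integer sample size.
#' @export
analytic_sample_size <- function(spec, power = 0.8, alpha = 0.05) {
  stopifnot(inherits(spec, "archetype_spec"))
  if (!is.numeric(power) || power <= 0 || power >= 1) {
    stop_value("power must lie in (0, 1)")
  }
  beta <- spec$target_log_or
  if (abs(beta) < 1e-12) {
    stop_config("null effect (OR = 1): no finite sample size achieves the target power")
  }
  i_int <- match(spec$interest, vapply(spec$covariates, `[[`, character(1), "name"))
  px <- spec$covariates[[i_int]]$p
  pbar <- spec$target_event_rate
  # event rates by exposure level consistent with the overall rate and OR
  orr <- exp(beta)
  p1_of <- function(p0) { o <- orr * p0 / (1 - p0); o / (1 + o) }
  p0 <- stats::uniroot(function(p0) (1 - px) * p0 + px * p1_of(p0) - pbar,
                       c(1e-10, 1 - 1e-10), tol = 1e-12)$root
  p1 <- p1_of(p0)
  v1 <- 1 / (p0 * (1 - p0) * (1 - px)) + 1 / (p1 * (1 - p1) * px)
  R <- spec$dependence
  rho2 <- 0
  if (nrow(R) > 1) {
    r <- R[i_int, -i_int]
    rho2 <- drop(r %*% solve(R[-i_int, -i_int], r))
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- v1 * z^2 / (beta^2 * (1 - rho2))
  as.integer(ceiling(n))
}

#' Empirical power of the real-data workload at a given sample size
#'
#' @param pop A `synth_population`.
#' @param n Sample size.
#' @param reps Number of Monte Carlo repetitions.
#' @param seed Integer seed.
#' @param z_crit Wald critical value.
#' @return Proportion of converged fits with a significant coefficient of
#'   interest.
#' @export
empirical_power <- function(pop, n, reps = 1000, seed = 1L, z_crit = 1.96) {
  sig <- logical(reps)
  conv <- logical(reps)
  for (r in seq_len(reps)) {
    s <- draw_sample(pop, n, seed = spawn_seed(seed, r))
    f <- fit_logistic(s, outcome = "y", interest = pop$interest, z_crit = z_crit)
    conv[r] <- f$converged
    sig[r] <- f$converged && abs(f$q) / sqrt(f$v) > z_crit
  }
  if (!any(conv)) return(NA_real_)
  mean(sig[conv])
}

#' Calibrate the study sample size to a target empirical power
#'
#' Starting from an analytic floor, the sample size is incremented in fixed
#' steps and the empirical power re-estimated by Monte Carlo until the target
#' is reached: the returned n is the smallest candidate whose empirical power
#' meets the target. Deterministic given the seed.
#'
#' @param pop A `synth_population`.
#' @param floor_n Starting sample size (>= 10), e.g. from
#'   [analytic_sample_size()].
#' @param step Increment between candidate sizes.
#' @param reps Monte Carlo repetitions per candidate.
#' @param target Target power.
#' @param seed Integer seed.
#' @return The calibrated sample size (integer), with the achieved empirical
#'   power attached as attribute `power`.
#' @export
calibrate_sample_size <- function(pop, floor_n, step = 10, reps = 1000,
                                  target = 0.8, seed = 1L) {
  stopifnot(inherits(pop, "synth_population"))
  if (floor_n < 10) stop_value("floor_n must be >= 10")
  n <- as.integer(floor_n)
  repeat {
    pw <- empirical_power(pop, n, reps = reps, seed = spawn_seed(seed, n))
    if (!is.na(pw) && pw >= target) {
      return(structure(n, power = pw))
    }
    n <- n + as.integer(step)
    if (n > pop$n_sim * 10) {
      synthrep_error("sample-size search exceeded 10x the population without reaching the target power",
                     "synthrep_calibration_error")
    }
  }
}
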