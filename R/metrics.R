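# The eight replicability metrics, plus Monte Carlo standard errors and the
# no-bias expected estimate agreement.
#
# Four metrics compare the synthetic-data analysis with the real-sample
# analysis (decision agreement, estimate agreement, standardized difference,
# CI overlap); four assess the validity of population inferences in the
# Morris simulation-study style (bias, bias-eliminated coverage, power,
# empirical SE).

est_point <- function(x) if (inherits(x, "combined_estimate")) x$q_bar else x$q
est_var <- function(x) if (inherits(x, "combined_estimate")) x$t_f else x$v
est_sig <- function(x, z_crit = 1.96) abs(est_point(x)) / sqrt(est_var(x)) > z_crit

#' Decision agreement between real and synthetic analyses
#'
#' Returns 1 when the two analyses lead to the same conclusion: both
#' significant (normal reference, critical value 1.96) with coefficients of
#' the same sign, or both non-significant. When neither estimate is
#' significant the direction is not compared, since no directional claim is
#' made.
#'
#' @param real A `fitted_estimate` from the real sample.
#' @param synth A `combined_estimate` from the synthetic data.
#' @param z_crit Critical value.
#' @return 0 or 1.
#' @export
decision_agreement <- function(real, synth, z_crit = 1.96) {
  sr <- est_sig(real, z_crit); ss <- est_sig(synth, z_crit)
  if (sr && ss) {
    as.integer(sign(est_point(real)) == sign(est_point(synth)))
  } else {
    as.integer(!sr && !ss)
  }
}

#' Estimate agreement: synthetic estimate inside the real-data CI
#'
#' Returns 1 when the synthetic point estimate falls inside the closed 95%
#' confidence interval of the real-data estimate.
#'
#' @param real_ci Real-data confidence interval `c(lower, upper)`.
#' @param synth_q Synthetic point estimate.
#' @return 0 or 1.
#' @export
estimate_agreement <- function(real_ci, synth_q) {
  as.integer(real_ci[1] <= synth_q && synth_q <= real_ci[2])
}

#' Standardized difference between real and synthetic estimates
#'
#' The Z statistic for the difference of estimates,
#' `(q_synth - q_real) / sqrt(v_real + V_synth)`, pooling the real variance
#' with the synthetic analysis variance (the adjusted `T_f` for combined
#' estimates, the plain variance for the single path). The pass indicator is
#' strict: `|Z| < 1.96`.
#'
#' @inheritParams decision_agreement
#' @return List with `z` and `pass` (0/1).
#' @export
standardized_difference <- function(real, synth, z_crit = 1.96) {
  z <- (est_point(synth) - est_point(real)) / sqrt(est_var(real) + est_var(synth))
  list(z = z, pass = as.integer(abs(z) < z_crit))
}

#' Proportion overlap of the real and synthetic confidence intervals
#'
#' The symmetric average of the overlap width as a fraction of each
#' interval's width, clamped at 0 for disjoint intervals so the metric lies
#' in `[0, 1]` and equals 1 only for identical intervals.
#'
#' @param real_ci,synth_ci Confidence intervals `c(lower, upper)`.
#' @return Overlap proportion in `[0, 1]`.
#' @export
ci_overlap <- function(real_ci, synth_ci) {
  w <- max(0, min(real_ci[2], synth_ci[2]) - max(real_ci[1], synth_ci[1]))
  if (w == 0) return(0)
  0.5 * (w / (real_ci[2] - real_ci[1]) + w / (synth_ci[2] - synth_ci[1]))
}

#' Population-inference metrics across simulation iterations
#'
#' Standard simulation-study summaries: `bias()` is the mean estimate minus
#' the population truth; `bias_eliminated_coverage()` is the proportion of
#' confidence intervals containing the mean estimate across iterations
#' (isolating interval-width correctness from bias); `power_rate()` is the
#' proportion of significant iterations; `emp_se()` is the sample standard
#' deviation (n - 1 denominator) of the estimates. Missing iterations (failed
#' fits) are excluded.
#'
#' @param q_list Numeric vector of per-iteration point estimates.
#' @param e_p Population truth on the log-odds scale.
#' @param ci_list Two-column matrix (or list of length-2 vectors) of
#'   per-iteration confidence intervals.
#' @param q_mean Reference value for bias-eliminated coverage, normally the
#'   mean estimate across iterations.
#' @param significant Logical/0-1 vector of per-iteration significance.
#' @return A scalar metric value.
#' @export
bias <- function(q_list, e_p) mean(q_list, na.rm = TRUE) - e_p

#' @rdname bias
#' @export
bias_eliminated_coverage <- function(ci_list, q_mean) {
  if (is.list(ci_list)) ci_list <- do.call(rbind, ci_list)
  ok <- stats::complete.cases(ci_list)
  mean(ci_list[ok, 1] <= q_mean & q_mean <= ci_list[ok, 2])
}

#' @rdname bias
#' @export
power_rate <- function(significant) mean(significant, na.rm = TRUE)

#' @rdname bias
#' @export
emp_se <- function(q_list) stats::sd(q_list, na.rm = TRUE)

#' Monte Carlo standard error of a simulated proportion
#'
#' `sqrt(p * (1 - p) / nsim)`; at a coverage of 0.95 over 1000 iterations
#' this is 0.0069, i.e. about 0.7% — the precision rationale for running 1000
#' iterations per scenario.
#'
#' @param p Proportion.
#' @param nsim Number of simulation iterations.
#' @return Standard error.
#' @export
mcse_coverage <- function(p, nsim) sqrt(p * (1 - p) / nsim)

#' Expected estimate agreement under no bias
#'
#' When the real and synthetic estimators are independent normals with equal
#' variance and no bias, the probability that the synthetic estimate falls
#' inside the real Wald interval is `2 * pnorm(z_crit / sqrt(2)) - 1`: about
#' 0.834 at the 1.96 critical value, i.e. the often-quoted 83% benchmark for
#' estimate agreement.
#'
#' @param z_crit Wald critical value.
#' @return Probability.
#' @export
expected_estimate_agreement <- function(z_crit = 1.96) {
  2 * stats::pnorm(z_crit / sqrt(2)) - 1
}
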