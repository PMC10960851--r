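# Combining rules for fully synthetic data, and the unadjusted single-dataset
# path.

#' Combine logistic fits from m fully synthetic datasets
#'
#' Implements the fully-synthetic multiple-imputation combining rules: the
#' combined parameter `q_bar` and mean within-dataset variance `v_bar` are
#' arithmetic means across the m synthetic fits, the adjusted variance is
#' `T_f = v_bar * (k/n + 1/m)` where `k` is the synthetic and `n` the real
#' dataset size, and the adjusted large-sample 95% confidence interval is
#' `q_bar +/- 1.96 * sqrt(T_f)`. The `k/n` term prices amplification: for
#' `k > n` the adjusted variance grows, and even at `m = 1`, `k = n` the
#' variance doubles relative to `v_bar`, widening the interval by `sqrt(2)`
#' compared with the unadjusted single-dataset analysis.
#'
#' @param estimates List of `m >= 1` converged [fit_logistic()] estimates, all
#'   from synthetic datasets of the same size `k`.
#' @param n Real (training) dataset size.
#' @param k Synthetic dataset size.
#' @param z_crit Critical value of the large-sample normal reference.
#' @return A `combined_estimate`: list with `q_bar`, `v_bar`, `t_f`, `ci`,
#'   `z`, `p_value`, `m`, `k`, `n`, `mode = "multiple"`.
#' @export
#' @examples
#' fits <- replicate(4, synthrep:::new_fitted_estimate(0.5, 0.04, TRUE, 100),
#'                   simplify = FALSE)
#' combine_estimates(fits, n = 100, k = 100)
combine_estimates <- function(estimates, n, k, z_crit = 1.96) {
  if (length(estimates) < 1) stop_value("need at least one estimate to combine")
  if (!all(vapply(estimates, inherits, logical(1), "fitted_estimate"))) {
    stop_schema("estimates must be fitted_estimate objects")
  }
  if (!all(vapply(estimates, `[[`, logical(1), "converged"))) {
    synthrep_error("all synthetic-data fits must have converged",
                   "synthrep_incomplete_replicates")
  }
  m <- length(estimates)
  q_bar <- mean(vapply(estimates, `[[`, numeric(1), "q"))
  v_bar <- mean(vapply(estimates, `[[`, numeric(1), "v"))
  t_f <- v_bar * (k / n + 1 / m)
  se <- sqrt(t_f)
  z <- q_bar / se
  structure(
    list(q_bar = q_bar, v_bar = v_bar, t_f = t_f,
         ci = c(q_bar - z_crit * se, q_bar + z_crit * se),
         z = z, p_value = 2 * stats::pnorm(-abs(z)),
         m = m, k = as.integer(k), n = as.integer(n), mode = "multiple"),
    class = "combined_estimate"
  )
}

#' Unadjusted single synthetic-dataset analysis
#'
#' Passes one synthetic-data fit through unchanged — the naive analysis a data
#' user would run on a single released synthetic dataset, with no combining
#' rule adjustment. Its confidence interval and p-value are exactly those of
#' the underlying fit.
#'
#' @param estimate A converged [fit_logistic()] estimate.
#' @return A `combined_estimate` with `mode = "single"` and `t_f` equal to the
#'   fit's variance.
#' @export
single_estimate <- function(estimate) {
  stopifnot(inherits(estimate, "fitted_estimate"))
  if (!estimate$converged) {
    synthrep_error("the synthetic-data fit did not converge",
                   "synthrep_incomplete_replicates")
  }
  structure(
    list(q_bar = estimate$q, v_bar = estimate$v, t_f = estimate$v,
         ci = estimate$ci, z = estimate$q / sqrt(estimate$v),
         p_value = estimate$p_value,
         m = 1L, k = estimate$n_fit, n = estimate$n_fit, mode = "single"),
    class = "combined_estimate"
  )
}

#' @export
print.combined_estimate <- function(x, ...) {
  cat(sprintf("<combined_estimate mode=%s m=%d k=%d n=%d>\n", x$mode, x$m, x$k, x$n))
  cat(sprintf("  q_bar = %.4f, T_f = %.5f, 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$q_bar, x$t_f, x$ci[1], x$ci[2], x$p_value))
  invisible(x)
}
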