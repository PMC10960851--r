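# Membership disclosure: can an adversary holding the pooled synthetic
# datasets tell whether a target individual was in the generative model's
# training data? Scored as an F1 relative to a naive all-member attack.

#' Configuration of the membership-disclosure attack
#'
#' The attack procedure follows the nearest-record matching construction: the
#' adversary holds an attack sample of `a` target individuals of whom a
#' fraction `rho` are training members (the population sampling fraction
#' `n / N` by default), and predicts "member" for every target whose
#' generalized Hamming distance to its nearest pooled synthetic record is at
#' most `h` on the quasi-identifiers. Continuous quasi-identifiers are
#' discretized into equal-width bins for matching. The baseline is the naive
#' attack that declares every target a member, which has precision `rho` and
#' recall 1, hence `F1_naive = 2 * rho / (1 + rho)`; the reported risk is
#' `relative F1 = F1 - F1_naive` (unclamped, so it can be negative). The
#' construction details are a documented reconstruction of the metric, which
#' the source literature does not fully restate.
#'
#' @param quasi_identifiers Character vector of columns the adversary knows.
#' @param member_fraction Fraction `rho` of attack targets that are training
#'   members; use the study sampling fraction `n / N_pop`.
#' @param attack_sample_size Number of attack targets `a`; defaults to
#'   `min(1000, n_sim / 10)` at attack-sample construction.
#' @param hamming_threshold Maximum distance `h` for a "member" call
#'   (default 0: exact match on all quasi-identifiers).
#' @param continuous_bins Number of equal-width bins for continuous columns.
#' @return An `attack_config`.
#' @export
attack_config <- function(quasi_identifiers, member_fraction,
                          attack_sample_size = NULL,
                          hamming_threshold = 0L, continuous_bins = 20L) {
  if (length(quasi_identifiers) < 1) stop_config("quasi_identifiers must be nonempty")
  if (member_fraction < 0 || member_fraction > 1) {
    stop_config("member_fraction must lie in [0, 1]")
  }
  if (hamming_threshold < 0) stop_config("hamming_threshold must be >= 0")
  structure(
    list(quasi_identifiers = quasi_identifiers,
         member_fraction = member_fraction,
         attack_sample_size = attack_sample_size,
         hamming_threshold = as.integer(hamming_threshold),
         continuous_bins = as.integer(continuous_bins)),
    class = "attack_config"
  )
}

#' Build the labeled attack sample for a membership attack
#'
#' Draws `a` target individuals from the simulated population:
#' `round(rho * a)` distinct training members and the remainder from
#' population rows outside the training sample, with membership labels.
#'
#' @param pop A `synth_population`.
#' @param training_ids Population row indices of the generative model's
#'   training sample (the `row_ids` attribute of [draw_sample()]).
#' @param config An [attack_config()].
#' @param seed Integer seed.
#' @return Tibble of quasi-identifier columns plus logical `is_member`.
#' @export
build_attack_sample <- function(pop, training_ids, config, seed = 1L) {
  stopifnot(inherits(pop, "synth_population"), inherits(config, "attack_config"))
  a <- config$attack_sample_size %||% min(1000L, floor(pop$n_sim / 10))
  rho <- config$member_fraction
  n_mem <- round(rho * a)
  if (n_mem < 1) stop_config("member_fraction * attack_sample_size rounds to zero members")
  uniq <- unique(training_ids)
  n_mem <- min(n_mem, length(uniq))
  non_ids <- setdiff(seq_len(pop$n_sim), uniq)
  if (a - n_mem > length(non_ids)) stop_config("not enough non-member rows in the population")
  with_seed(seed, {
    mem <- uniq[sample.int(length(uniq), n_mem)]
    non <- non_ids[sample.int(length(non_ids), a - n_mem)]
    ids <- c(mem, non)
    out <- pop$records[ids, config$quasi_identifiers, drop = FALSE]
    out$is_member <- c(rep(TRUE, n_mem), rep(FALSE, a - n_mem))
    out
  })
}

# Integer codes for generalized Hamming matching: categorical columns by
# level, continuous columns by equal-width bin over the pooled range.
qi_codes <- function(synth, attack, cols, schema, bins) {
  code1 <- function(nm) {
    s <- synth[[nm]]; t <- attack[[nm]]
    kind <- schema[[nm]]$kind %||% if (is.numeric(s) && length(unique(s)) > 15) "continuous" else "categorical"
    if (kind == "continuous") {
      rng <- range(c(s, t), finite = TRUE)
      if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
      br <- seq(rng[1], rng[2], length.out = bins + 1)
      list(s = findInterval(s, br, all.inside = TRUE),
           t = findInterval(t, br, all.inside = TRUE))
    } else {
      lv <- sort(unique(as.character(c(s, t))))
      list(s = match(as.character(s), lv), t = match(as.character(t), lv))
    }
  }
  codes <- lapply(cols, code1)
  list(s = do.call(cbind, lapply(codes, `[[`, "s")),
       t = do.call(cbind, lapply(codes, `[[`, "t")))
}

#' Run the membership-disclosure attack on pooled synthetic data
#'
#' Each attack target's generalized Hamming distance (0/1 mismatch per
#' quasi-identifier; continuous values mismatch unless they share a
#' discretization bin) to its nearest pooled synthetic record is computed;
#' the target is predicted to be a member when the minimum distance is at
#' most the configured threshold. Precision, recall and F1 are evaluated
#' against the membership labels, with F1 defined as 0 when no positives are
#' predicted, and reported relative to the naive all-member attack.
#'
#' @param pooled_synthetic The `m` synthetic datasets row-bound together.
#' @param attack_sample Labeled table from [build_attack_sample()].
#' @param config An [attack_config()].
#' @param schema Optional `synthrep_schema` declaring column kinds.
#' @return An `attack_result`: list with `precision`, `recall`, `f1`,
#'   `f1_naive`, `relative_f1`, `n_predicted_members`.
#' @export
membership_attack <- function(pooled_synthetic, attack_sample, config, schema = NULL) {
  stopifnot(inherits(config, "attack_config"))
  if (nrow(pooled_synthetic) == 0) stop_value("pooled synthetic data is empty")
  cols <- config$quasi_identifiers
  if (!all(cols %in% names(pooled_synthetic)) || !all(cols %in% names(attack_sample))) {
    stop_schema("quasi-identifiers missing from the synthetic or attack table")
  }
  schema <- schema %||% infer_schema(pooled_synthetic[, cols, drop = FALSE])
  cd <- qi_codes(pooled_synthetic, attack_sample, cols, schema, config$continuous_bins)
  h <- config$hamming_threshold

  if (h == 0) {
    skey <- do.call(paste, c(as.data.frame(cd$s), sep = "\r"))
    tkey <- do.call(paste, c(as.data.frame(cd$t), sep = "\r"))
    predicted <- tkey %in% skey
  } else {
    st <- t(cd$s)
    predicted <- logical(nrow(cd$t))
    for (i in seq_len(nrow(cd$t))) {
      d <- colSums(st != cd$t[i, ])
      predicted[i] <- min(d) <= h
    }
  }

  actual <- attack_sample$is_member
  tp <- sum(predicted & actual)
  precision <- if (sum(predicted) == 0) 0 else tp / sum(predicted)
  recall <- if (sum(actual) == 0) 0 else tp / sum(actual)
  f1 <- if (sum(predicted) == 0 || (precision + recall) == 0) 0 else
    2 * precision * recall / (precision + recall)
  rho <- config$member_fraction
  f1_naive <- 2 * rho / (1 + rho)
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         f1_naive = f1_naive, relative_f1 = f1 - f1_naive,
         n_predicted_members = sum(predicted)),
    class = "attack_result"
  )
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("<attack_result> precision %.3f, recall %.3f, F1 %.4f, naive F1 %.4f, relative F1 %.4f\n",
              x$precision, x$recall, x$f1, x$f1_naive, x$relative_f1))
  invisible(x)
}
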