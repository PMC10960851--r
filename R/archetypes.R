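# Archetype specifications: declarative descriptions of simulated finite
# populations with a known logistic-regression estimand.

#' Covariate descriptors for an archetype specification
#'
#' An archetype population is described by a list of covariates, each with a
#' marginal distribution and a log-odds coefficient in the outcome model.
#' Dependence between covariates is induced by a latent Gaussian copula
#' (see [archetype_spec()]): binary and categorical covariates are obtained by
#' thresholding the latent normal at quantile cut-points, continuous ones by
#' the probability-integral transform.
#'
#' @param name Column name.
#' @param p Success probability of a binary covariate.
#' @param beta Log-odds coefficient(s) in the outcome model. For a categorical
#'   covariate supply one coefficient per non-reference level.
#' @param interest Flag exactly one (binary) covariate as the covariate of
#'   interest; its coefficient is set by the archetype's target log odds
#'   ratio.
#' @param levels,probs Level labels and marginal probabilities of a
#'   categorical covariate.
#' @param dist Marginal family of a continuous covariate: `"normal"`,
#'   `"gamma"` or `"lognormal"`.
#' @param params Named parameters of the marginal family (`mean`/`sd`,
#'   `shape`/`rate`, `meanlog`/`sdlog`).
#' @param support Closed support `c(lower, upper)` used for boundary-corrected
#'   kernel smoothing during synthesis; defaults to the family's natural
#'   support.
#' @return A covariate descriptor (a classed list).
#' @export
covariate_binary <- function(name, p, beta = 0, interest = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop_config(sprintf("binary covariate '%s': p must lie in (0, 1)", name))
  }
  structure(
    list(name = name, kind = "binary", p = p, beta = beta,
         interest = isTRUE(interest)),
    class = "synthrep_covariate"
  )
}

#' @rdname covariate_binary
#' @export
covariate_categorical <- function(name, levels, probs, beta = NULL) {
  stopifnot(length(levels) >= 2, length(levels) == length(probs))
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-8) {
    stop_config(sprintf("categorical covariate '%s': probs must be positive and sum to 1", name))
  }
  beta <- beta %||% rep(0, length(levels) - 1)
  if (length(beta) != length(levels) - 1) {
    stop_config(sprintf("categorical covariate '%s': need one beta per non-reference level", name))
  }
  structure(
    list(name = name, kind = "categorical", levels = as.character(levels),
         probs = as.numeric(probs), beta = beta, interest = FALSE),
    class = "synthrep_covariate"
  )
}

#' @rdname covariate_binary
#' @export
covariate_continuous <- function(name, dist = c("normal", "gamma", "lognormal"),
                                 params, beta = 0, support = NULL) {
  dist <- match.arg(dist)
  needed <- switch(dist,
    normal = c("mean", "sd"),
    gamma = c("shape", "rate"),
    lognormal = c("meanlog", "sdlog")
  )
  if (!all(needed %in% names(params))) {
    stop_config(sprintf("continuous covariate '%s': params must name %s",
                        name, paste(needed, collapse = ", ")))
  }
  support <- support %||% switch(dist,
    normal = c(-Inf, Inf), gamma = c(0, Inf), lognormal = c(0, Inf))
  structure(
    list(name = name, kind = "continuous", dist = dist,
         params = as.list(params), beta = beta, support = support,
         interest = FALSE),
    class = "synthrep_covariate"
  )
}

# Quantile function of a covariate's marginal.
q_marginal <- function(cov, u) {
  switch(cov$dist,
    normal = stats::qnorm(u, cov$params$mean, cov$params$sd),
    gamma = stats::qgamma(u, shape = cov$params$shape, rate = cov$params$rate),
    lognormal = stats::qlnorm(u, cov$params$meanlog, cov$params$sdlog)
  )
}

#' Declare an archetype population specification
#'
#' An `archetype_spec` states everything needed to simulate a finite
#' population with a known logistic-regression estimand: the nominal
#' population size, the study sample size, the target outcome event rate, the
#' target log odds ratio of the covariate of interest, the covariate
#' marginals, and the latent-Gaussian dependence among covariates. The
#' intercept of the outcome model is not declared; it is solved numerically at
#' population-build time so that the population event rate matches the target
#' (see [build_population()]).
#'
#' @param name Label for the archetype.
#' @param n_pop Nominal population size (used for the membership-disclosure
#'   sampling fraction even when the realized population is capped).
#' @param study_n Study sample size drawn from the population.
#' @param target_event_rate Target outcome prevalence, in (0, 1).
#' @param target_log_or Log odds ratio of the covariate of interest; this
#'   overrides the `beta` of the covariate flagged `interest`.
#' @param covariates List of covariate descriptors (see [covariate_binary()]).
#'   Exactly one must be flagged as the covariate of interest, and it must be
#'   binary.
#' @param dependence Correlation matrix of the latent Gaussian copula
#'   (symmetric, positive definite, unit diagonal), ordered as `covariates`.
#'   Defaults to independence.
#' @return An object of class `archetype_spec`.
#' @seealso [builtin_archetypes()], [build_population()]
#' @export
archetype_spec <- function(name, n_pop, study_n, target_event_rate,
                           target_log_or, covariates, dependence = NULL) {
  stopifnot(is.list(covariates), length(covariates) >= 1)
  if (!all(vapply(covariates, inherits, logical(1), "synthrep_covariate"))) {
    stop_config("covariates must be built with the covariate_*() constructors")
  }
  if (!is.numeric(target_event_rate) || target_event_rate <= 0 || target_event_rate >= 1) {
    stop_config("target_event_rate must lie in (0, 1)")
  }
  nms <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_config("covariate names must be unique")
  if ("y" %in% nms) stop_config("'y' is reserved for the outcome column")
  interest <- vapply(covariates, function(cv) isTRUE(cv$interest), logical(1))
  if (sum(interest) != 1) {
    stop_config("exactly one covariate must be flagged as the covariate of interest")
  }
  if (covariates[[which(interest)]]$kind != "binary") {
    stop_config("the covariate of interest must be binary")
  }
  covariates[[which(interest)]]$beta <- target_log_or

  p <- length(covariates)
  dependence <- dependence %||% diag(p)
  dependence <- as.matrix(dependence)
  if (!all(dim(dependence) == c(p, p))) {
    stop_config("dependence matrix dimension must match the number of covariates")
  }
  if (!isSymmetric(unname(dependence), tol = 1e-8)) {
    stop_config("dependence matrix must be symmetric")
  }
  if (any(abs(diag(dependence) - 1) > 1e-8)) {
    stop_config("dependence matrix must have unit diagonal")
  }
  ok <- tryCatch({ chol(dependence); TRUE }, error = function(e) FALSE)
  if (!ok) stop_config("dependence matrix must be positive definite")
  dimnames(dependence) <- list(nms, nms)

  structure(
    list(name = name, n_pop = as.double(n_pop), study_n = as.integer(study_n),
         target_event_rate = target_event_rate, target_log_or = target_log_or,
         covariates = covariates, dependence = dependence,
         interest = nms[interest]),
    class = "archetype_spec"
  )
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(sprintf("<archetype_spec '%s'>\n", x$name))
  cat(sprintf("  population N = %s, study n = %d\n",
              format(x$n_pop, big.mark = ","), x$study_n))
  cat(sprintf("  target event rate = %.3f, target OR = %.3f (covariate '%s')\n",
              x$target_event_rate, exp(x$target_log_or), x$interest))
  cat(sprintf("  covariates: %s\n",
              paste(vapply(x$covariates, function(cv) sprintf("%s[%s]", cv$name, cv$kind),
                           character(1)), collapse = ", ")))
  invisible(x)
}

#' Column-kind schema of an archetype's tables
#'
#' @param spec An [archetype_spec()].
#' @return Named list, one entry per column (covariates plus outcome `y`),
#'   each with `kind` and, where relevant, `levels` or `support`.
#' @export
table_schema <- function(spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  out <- lapply(spec$covariates, function(cv) {
    switch(cv$kind,
      binary = list(kind = "binary"),
      categorical = list(kind = "categorical", levels = cv$levels),
      continuous = list(kind = "continuous", support = cv$support)
    )
  })
  names(out) <- vapply(spec$covariates, `[[`, character(1), "name")
  out$y <- list(kind = "binary")
  structure(out, class = "synthrep_schema")
}

#' Infer a column-kind schema from a rectangular table
#'
#' Used when no declared schema is available: factors and characters become
#' categorical, numeric columns taking only values 0/1 become binary, all
#' other numerics become continuous with unbounded support. A declared schema
#' (from [table_schema()]) is always preferable since it carries the support
#' bounds that drive boundary-corrected smoothing.
#'
#' @param df A data frame.
#' @return A `synthrep_schema`.
#' @export
infer_schema <- function(df) {
  out <- lapply(df, function(x) {
    if (is.factor(x)) {
      list(kind = "categorical", levels = levels(x))
    } else if (is.character(x)) {
      list(kind = "categorical", levels = sort(unique(x)))
    } else if (is.numeric(x) && all(x %in% c(0, 1))) {
      list(kind = "binary")
    } else if (is.numeric(x)) {
      list(kind = "continuous", support = c(-Inf, Inf))
    } else {
      stop_schema("unsupported column type")
    }
  })
  structure(out, class = "synthrep_schema")
}

#' Built-in archetypes emulating three heterogeneous health datasets
#'
#' Three presets reproduce the headline structure of the study datasets used
#' throughout the package: a colon-cancer trial control arm
#' (`n0147_like`: N = 1,365,135, n = 1420, event rate 0.12, OR 1.8), a
#' national community health survey (`cchs_like`: N = 35.44M, n = 903, event
#' rate 0.63, OR 1.47), and a national colorectal-surgery registry
#' (`dccg_like`: N = 30,000, n = 2625, event rate 0.16, OR 1.58). The
#' covariate mixes (5-6 mixed-type covariates each) and their dependence are
#' plausible inventions: the source datasets are access-restricted, so only
#' the sample sizes, population sizes, event rates and odds ratios are
#' matched. The `n0147_like` covariate structure is additionally calibrated so
#' that the stated sample size of 1420 delivers approximately 80% power for
#' the covariate of interest.
#'
#' @return Named list of three [archetype_spec()] objects.
#' @export
#' @examples
#' specs <- builtin_archetypes()
#' specs$n0147_like
builtin_archetypes <- function() {
  # Latent-correlation helper
  corr <- function(nms, ...) {
    R <- diag(length(nms)); dimnames(R) <- list(nms, nms)
    for (e in list(...)) { R[e[[1]], e[[2]]] <- R[e[[2]], e[[1]]] <- e[[3]] }
    R
  }

  n0147_names <- c("obstruction", "age", "sex", "stage", "nodes", "perf_status")
  n0147 <- archetype_spec(
    name = "n0147_like",
    n_pop = 1365135, study_n = 1420,
    target_event_rate = 0.12, target_log_or = log(1.8),
    covariates = list(
      covariate_binary("obstruction", p = 0.14, interest = TRUE),
      covariate_continuous("age", "normal", list(mean = 65, sd = 10), beta = 0.012),
      covariate_binary("sex", p = 0.45, beta = log(1.2)),
      covariate_categorical("stage", c("II", "IIIa", "IIIb"), c(0.25, 0.50, 0.25),
                            beta = c(log(1.4), log(1.9))),
      covariate_continuous("nodes", "gamma", list(shape = 4, rate = 0.3), beta = 0.008),
      covariate_binary("perf_status", p = 0.30, beta = log(1.3))
    ),
    dependence = corr(n0147_names,
      list("obstruction", "stage", 0.25),
      list("obstruction", "nodes", 0.10),
      list("stage", "nodes", 0.35),
      list("age", "perf_status", 0.25),
      list("age", "obstruction", 0.05))
  )

  cchs_names <- c("sex", "age", "income", "smoker", "bmi", "activity")
  cchs <- archetype_spec(
    name = "cchs_like",
    n_pop = 35440000, study_n = 903,
    target_event_rate = 0.63, target_log_or = log(1.47),
    covariates = list(
      covariate_binary("sex", p = 0.50, interest = TRUE),
      covariate_continuous("age", "normal", list(mean = 48, sd = 17), beta = 0.018),
      covariate_categorical("income", c("q1", "q2", "q3", "q4"), c(0.2, 0.3, 0.3, 0.2),
                            beta = c(-0.20, -0.35, -0.55)),
      covariate_binary("smoker", p = 0.18, beta = 0.50),
      covariate_continuous("bmi", "gamma", list(shape = 42, rate = 1.55), beta = 0.035),
      covariate_categorical("activity", c("low", "moderate", "high"), c(0.3, 0.4, 0.3),
                            beta = c(-0.30, -0.60))
    ),
    dependence = corr(cchs_names,
      list("age", "income", 0.20),
      list("age", "bmi", 0.15),
      list("smoker", "activity", -0.15),
      list("sex", "smoker", 0.10))
  )

  dccg_names <- c("sex", "age", "asa", "bmi", "comorbidity", "emergency")
  dccg <- archetype_spec(
    name = "dccg_like",
    n_pop = 30000, study_n = 2625,
    target_event_rate = 0.16, target_log_or = log(1.58),
    covariates = list(
      covariate_binary("sex", p = 0.45, interest = TRUE),
      covariate_continuous("age", "normal", list(mean = 72, sd = 11), beta = 0.02),
      covariate_categorical("asa", c("I-II", "III", "IV"), c(0.45, 0.40, 0.15),
                            beta = c(0.40, 0.85)),
      covariate_continuous("bmi", "gamma", list(shape = 38, rate = 1.5), beta = 0.015),
      covariate_binary("comorbidity", p = 0.38, beta = 0.45),
      covariate_binary("emergency", p = 0.15, beta = 0.50)
    ),
    dependence = corr(dccg_names,
      list("age", "asa", 0.35),
      list("age", "comorbidity", 0.30),
      list("asa", "comorbidity", 0.30),
      list("asa", "emergency", 0.15))
  )

  list(n0147_like = n0147, cchs_like = cchs, dccg_like = dccg)
}

# ---- YAML serialization ----------------------------------------------------

#' Read and write archetype specifications as YAML
#'
#' @param spec An [archetype_spec()].
#' @param path File path.
#' @return `read_archetype()` returns an [archetype_spec()];
#'   `write_archetype()` returns `path` invisibly.
#' @export
write_archetype <- function(spec, path) {
  stopifnot(inherits(spec, "archetype_spec"))
  covs <- lapply(spec$covariates, function(cv) {
    cv <- unclass(cv)
    cv$support <- if (!is.null(cv$support)) as.numeric(cv$support)
    cv
  })
  obj <- list(
    name = spec$name, n_pop = spec$n_pop, study_n = spec$study_n,
    target_event_rate = spec$target_event_rate,
    target_log_or = spec$target_log_or,
    covariates = covs,
    dependence = apply(unname(spec$dependence), 1, as.numeric, simplify = FALSE)
  )
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_archetype
#' @export
read_archetype <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- lapply(obj$covariates, function(cv) {
    switch(cv$kind,
      binary = covariate_binary(cv$name, cv$p, cv$beta %||% 0, isTRUE(cv$interest)),
      categorical = covariate_categorical(cv$name, cv$levels, cv$probs, unlist(cv$beta)),
      continuous = covariate_continuous(cv$name, cv$dist, cv$params, cv$beta %||% 0,
                                        if (!is.null(cv$support)) unlist(cv$support))
    )
  })
  dep <- do.call(rbind, lapply(obj$dependence, unlist))
  archetype_spec(obj$name, obj$n_pop, obj$study_n, obj$target_event_rate,
                 obj$target_log_or, covs, dep)
}

#' Write a column-kind schema sidecar as YAML
#'
#' @param schema A `synthrep_schema`.
#' @param path File path.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(lapply(unclass(schema), function(col) {
    col$support <- if (!is.null(col$support)) as.numeric(col$support)
    col
  }), path)
  invisible(path)
}
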