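# Generative models behind one interface: the sequential tree-based
# synthesizer (CART or gradient-boosted trees) and a parametric oracle
# baseline used to validate the inferential machinery.

#' Learner settings for the sequential synthesizer
#'
#' The boosted learner uses a fixed budget of 200 trees of depth 3 at
#' learning rate 0.1 — enough boosting iterations to recover weak
#' conditional effects without hyperparameter search; smaller budgets leave
#' visible shrinkage of fitted coefficients on rare binary outcomes. The CART
#' learner uses the conventional synthesis settings of deep trees with small
#' leaves (complexity parameter 1e-8, minimum bucket 5, minimum split 20),
#' which make each leaf an empirical conditional distribution; it is the fast
#' mode for scaled-down runs.
#'
#' @param learner `"boosted"` (gradient-boosted trees) or `"cart"`.
#' @param nrounds,max_depth,eta Boosted-tree budget.
#' @param cp,minbucket CART complexity and minimum leaf size.
#' @return A list of settings.
#' @export
seq_control <- function(learner = c("boosted", "cart"), nrounds = 200,
                        max_depth = 3, eta = 0.1, cp = 1e-8, minbucket = 5) {
  list(learner = match.arg(learner), nrounds = nrounds, max_depth = max_depth,
       eta = eta, cp = cp, minbucket = minbucket)
}

# ---- internal column handling ---------------------------------------------

# Per-column metadata: modeling kind, factor levels, numeric-coded flag,
# support bounds for boundary-corrected smoothing.
column_meta <- function(df, schema) {
  metas <- list()
  for (nm in names(df)) {
    sc <- schema[[nm]]
    if (is.null(sc)) stop_schema(sprintf("column '%s' missing from schema", nm))
    metas[[nm]] <- switch(sc$kind,
      binary = list(kind = "class", levels = c("0", "1"),
                    numeric_coded = is.numeric(df[[nm]])),
      categorical = list(kind = "class",
                         levels = sc$levels %||% levels(factor(df[[nm]])),
                         numeric_coded = FALSE),
      continuous = list(kind = "reg", support = sc$support %||% c(-Inf, Inf)),
      stop_schema(sprintf("unknown kind for column '%s'", nm))
    )
  }
  metas
}

as_model_frame <- function(df, metas) {
  out <- df
  for (nm in names(metas)) {
    m <- metas[[nm]]
    if (m$kind == "class") {
      out[[nm]] <- factor(as.character(df[[nm]]), levels = m$levels)
    } else {
      out[[nm]] <- as.numeric(df[[nm]])
    }
  }
  as.data.frame(out)
}

cast_back <- function(df, metas, orig_names) {
  for (nm in names(metas)) {
    m <- metas[[nm]]
    if (m$kind == "class" && isTRUE(m$numeric_coded)) {
      df[[nm]] <- as.numeric(as.character(df[[nm]]))
    }
  }
  tibble::as_tibble(df[, orig_names, drop = FALSE])
}

# One-hot design matrix with stable columns (reference level dropped).
one_hot <- function(df) {
  mats <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.factor(x)) {
      lv <- levels(x)
      if (length(lv) < 2) return(NULL)
      m <- vapply(lv[-1], function(l) as.numeric(x == l), numeric(nrow(df)))
      m <- matrix(m, nrow = nrow(df))
      colnames(m) <- paste0(nm, "=", lv[-1])
      m
    } else {
      matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, nm))
    }
  })
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0) {
    return(matrix(1, nrow = nrow(df), ncol = 1, dimnames = list(NULL, "(const)")))
  }
  do.call(cbind, mats)
}

# Mutual information between two variables after coarse discretization;
# used only to rank covariates for the "auto" synthesis order.
mutual_info <- function(x, y) {
  disc <- function(v) {
    if (is.numeric(v) && length(unique(v)) > 10) {
      br <- unique(stats::quantile(v, probs = seq(0, 1, 0.1), names = FALSE))
      if (length(br) < 2) return(factor(rep(1, length(v))))
      cut(v, breaks = br, include.lowest = TRUE)
    } else {
      factor(v)
    }
  }
  tab <- table(disc(x), disc(y))
  pxy <- tab / sum(tab)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

resolve_order <- function(df, order, outcome) {
  nms <- names(df)
  if (identical(order, "auto")) {
    if (!outcome %in% nms) return(nms)
    covs <- setdiff(nms, outcome)
    mi <- vapply(covs, function(nm) mutual_info(df[[nm]], df[[outcome]]), numeric(1))
    return(c(covs[order(-mi)], outcome))
  }
  if (!setequal(order, nms) || length(order) != length(nms)) {
    stop_config("order must be a permutation of the table's columns")
  }
  order
}

# ---- conditional models ---------------------------------------------------

fit_conditional <- function(data, target, predictors, meta, control) {
  fml <- stats::reformulate(predictors, response = target)
  if (meta$kind == "class") {
    yy <- droplevels(data[[target]])
    lev_used <- levels(yy)
    if (length(lev_used) < 2) {
      return(list(type = "const", level = lev_used[1]))
    }
    if (control$learner == "cart") {
      dd <- data[, c(target, predictors), drop = FALSE]
      dd[[target]] <- yy
      fit <- rpart::rpart(fml, data = dd, method = "class",
                          control = rpart::rpart.control(
                            cp = control$cp, minbucket = control$minbucket,
                            minsplit = max(4L * control$minbucket, 20L),
                            xval = 0, maxsurrogate = 0, maxcompete = 0))
      list(type = "class", engine = "cart", fit = fit, levels = lev_used)
    } else {
      X <- one_hot(data[, predictors, drop = FALSE])
      lab <- as.integer(yy) - 1L
      if (length(lev_used) == 2) {
        booster <- xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = control$max_depth,
                        eta = control$eta, nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = lab),
          nrounds = control$nrounds, verbose = 0)
      } else {
        booster <- xgboost::xgb.train(
          params = list(objective = "multi:softprob", num_class = length(lev_used),
                        max_depth = control$max_depth, eta = control$eta, nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = lab),
          nrounds = control$nrounds, verbose = 0)
      }
      list(type = "class", engine = "boosted", fit = booster, levels = lev_used,
           features = colnames(X))
    }
  } else {
    yv <- data[[target]]
    if (control$learner == "cart") {
      fit <- rpart::rpart(fml, data = data[, c(target, predictors), drop = FALSE],
                          method = "anova",
                          control = rpart::rpart.control(
                            cp = control$cp, minbucket = control$minbucket,
                            minsplit = max(4L * control$minbucket, 20L),
                            xval = 0, maxsurrogate = 0, maxcompete = 0))
      fitted_tr <- unname(stats::predict(fit, data))
      eng <- list(engine = "cart", fit = fit)
    } else {
      X <- one_hot(data[, predictors, drop = FALSE])
      booster <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = control$max_depth,
                      eta = control$eta, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = yv),
        nrounds = control$nrounds, verbose = 0)
      fitted_tr <- as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(X)))
      eng <- list(engine = "boosted", fit = booster, features = colnames(X))
    }
    resid_tr <- yv - fitted_tr
    breaks <- unique(stats::quantile(fitted_tr, probs = seq(0, 1, 0.1), names = FALSE))
    if (length(breaks) < 2) {
      bin_tr <- rep(1L, length(fitted_tr))
      breaks <- range(fitted_tr)
    } else {
      bin_tr <- findInterval(fitted_tr, breaks, all.inside = TRUE)
    }
    pools <- split(resid_tr, bin_tr)
    bw <- if (stats::sd(yv) > 0) stats::bw.nrd0(yv) else 0
    c(eng, list(type = "reg", breaks = breaks, pools = pools, bw = bw,
                support = meta$support))
  }
}

predict_class_probs <- function(m, newdata) {
  if (m$engine == "cart") {
    P <- stats::predict(m$fit, newdata, type = "prob")
    P <- P[, m$levels, drop = FALSE]
  } else {
    X <- one_hot(newdata)
    X <- X[, m$features, drop = FALSE]
    pr <- stats::predict(m$fit, xgboost::xgb.DMatrix(X))
    P <- if (length(m$levels) == 2) cbind(1 - pr, pr) else {
      if (is.matrix(pr)) pr else matrix(pr, ncol = length(m$levels), byrow = TRUE)
    }
    colnames(P) <- m$levels
  }
  P
}

predict_reg <- function(m, newdata) {
  if (m$engine == "cart") {
    unname(stats::predict(m$fit, newdata))
  } else {
    X <- one_hot(newdata)
    X <- X[, m$features, drop = FALSE]
    as.numeric(stats::predict(m$fit, xgboost::xgb.DMatrix(X)))
  }
}

sample_classes <- function(P, levels_) {
  k <- nrow(P)
  L <- ncol(P)
  cum <- P %*% upper.tri(diag(L), diag = TRUE)
  u <- stats::runif(k)
  idx <- pmin(rowSums(u > cum) + 1L, L)
  levels_[idx]
}

reflect_into <- function(x, support) {
  lo <- support[1]; hi <- support[2]
  for (i in 1:2) {
    if (is.finite(lo)) x <- ifelse(x < lo, 2 * lo - x, x)
    if (is.finite(hi)) x <- ifelse(x > hi, 2 * hi - x, x)
  }
  if (is.finite(lo)) x <- pmax(x, lo)
  if (is.finite(hi)) x <- pmin(x, hi)
  x
}

# ---- sequential synthesizer -----------------------------------------------

#' Fit the sequential tree-based synthesizer
#'
#' Variables are synthesized one at a time along a declared or automatically
#' chosen order. The first ordered variable's training values are stored and
#' later resampled; every subsequent variable gets a conditional tree model on
#' its predecessors — a classification tree for binary/categorical targets, a
#' regression tree for continuous ones. For a table with `p` columns this
#' yields `p - 1` conditional models.
#'
#' The `"auto"` order places the outcome last and ranks covariates by
#' descending mutual information with the outcome; any explicit permutation of
#' the columns can be supplied instead, so alternative ordering strategies
#' plug in externally.
#'
#' @param sample Training table (a study sample).
#' @param schema Optional `synthrep_schema` declaring column kinds and
#'   supports; inferred with [infer_schema()] when absent.
#' @param order `"auto"` or a character permutation of the column names.
#' @param outcome Outcome column name (used only by the `"auto"` order; the
#'   synthesizer itself treats all columns alike).
#' @param control Learner settings from [seq_control()].
#' @return A `generator_model` of class `seq_synth`.
#' @seealso [generate()], [fit_oracle()]
#' @export
fit_sequential <- function(sample, schema = NULL, order = "auto",
                           outcome = "y", control = seq_control()) {
  if (!is.data.frame(sample)) stop_schema("sample must be a data frame")
  if (nrow(sample) == 0) stop_value("cannot fit a synthesizer to an empty sample")
  schema <- schema %||% infer_schema(sample)
  metas <- column_meta(sample, schema)
  ord <- resolve_order(sample, order, outcome)
  data <- as_model_frame(sample, metas)

  models <- list()
  if (length(ord) >= 2) {
    for (j in 2:length(ord)) {
      target <- ord[j]
      predictors <- ord[seq_len(j - 1)]
      models[[target]] <- fit_conditional(data, target, predictors,
                                          metas[[target]], control)
    }
  }

  structure(
    list(kind = "sequential", variable_order = ord, orig_names = names(sample),
         first_values = data[[ord[1]]], models = models, metas = metas,
         schema = schema, n = nrow(sample), control = control),
    class = c("seq_synth", "generator_model")
  )
}

#' Generate synthetic data from a fitted generator
#'
#' For the sequential synthesizer, generation starts by bootstrap-sampling the
#' first ordered variable from its training values. Each subsequent
#' categorical variable is sampled row-wise from the conditional model's
#' predicted class probabilities. Each subsequent continuous variable takes
#' the conditional model's prediction, adds a residual drawn from training
#' residuals in the same predicted-value decile bin, and is then smoothed with
#' Gaussian kernel noise at the Silverman bandwidth of the training variable,
#' reflected at the declared support boundaries so generated values respect
#' the variable's support.
#'
#' @param model A fitted `generator_model`.
#' @param k Number of rows to generate (>= 1); `k` larger than the training
#'   size amplifies the data.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param ... Unused.
#' @return A tibble of `k` rows with the training table's columns and types.
#' @export
generate <- function(model, k, seed = NULL, ...) UseMethod("generate")

#' @rdname generate
#' @export
generate.seq_synth <- function(model, k, seed = NULL, ...) {
  if (!is.numeric(k) || k < 1) stop_value("k must be >= 1")
  k <- as.integer(k)
  with_seed(seed, {
    out <- list()
    ord <- model$variable_order
    v1 <- model$first_values
    out[[ord[1]]] <- v1[sample.int(length(v1), k, replace = TRUE)]
    for (target in names(model$models)) {
      m <- model$models[[target]]
      newdata <- as.data.frame(out, optional = TRUE)
      out[[target]] <- switch(m$type,
        const = factor(rep(m$level, k), levels = model$metas[[target]]$levels),
        class = {
          P <- predict_class_probs(m, newdata)
          factor(sample_classes(P, m$levels),
                 levels = model$metas[[target]]$levels)
        },
        reg = {
          pred <- predict_reg(m, newdata)
          bin <- if (length(m$pools) == 1) rep(1L, k) else
            findInterval(pred, m$breaks, all.inside = TRUE)
          res <- numeric(k)
          for (b in unique(bin)) {
            pool <- m$pools[[as.character(b)]] %||% unlist(m$pools)
            rows <- which(bin == b)
            res[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
          }
          val <- pred + res + stats::rnorm(k, 0, m$bw)
          reflect_into(val, m$support)
        }
      )
    }
    cast_back(as.data.frame(out, optional = TRUE), model$metas, model$orig_names)
  })
}

# ---- oracle generator -----------------------------------------------------

#' Fit the parametric oracle generator
#'
#' A validation baseline approximating an ideal synthesizer: covariate rows
#' are bootstrap-resampled from the training sample, and the outcome is
#' regenerated from the logistic model fitted to that sample. Because its
#' only error is sampling error, it isolates the behaviour of the combining
#' rules and metrics from synthesis quality.
#'
#' @inheritParams fit_sequential
#' @return A `generator_model` of class `oracle_synth`.
#' @export
fit_oracle <- function(sample, outcome = "y", schema = NULL) {
  if (!is.data.frame(sample)) stop_schema("sample must be a data frame")
  if (!outcome %in% names(sample)) stop_schema(sprintf("outcome column '%s' not found", outcome))
  fml <- stats::reformulate(setdiff(names(sample), outcome), response = outcome)
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = sample)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || any(!is.finite(stats::coef(fit)))) {
    synthrep_error("logistic fit for the oracle generator failed",
                   "synthrep_oracle_unavailable")
  }
  structure(
    list(kind = "oracle", covariates = sample[, setdiff(names(sample), outcome), drop = FALSE],
         fit = fit, outcome = outcome, orig_names = names(sample),
         variable_order = names(sample), schema = schema, n = nrow(sample)),
    class = c("oracle_synth", "generator_model")
  )
}

#' @rdname generate
#' @export
generate.oracle_synth <- function(model, k, seed = NULL, ...) {
  if (!is.numeric(k) || k < 1) stop_value("k must be >= 1")
  k <- as.integer(k)
  with_seed(seed, {
    idx <- sample.int(nrow(model$covariates), k, replace = TRUE)
    X <- model$covariates[idx, , drop = FALSE]
    p <- stats::predict(model$fit, newdata = X, type = "response")
    X[[model$outcome]] <- stats::rbinom(k, 1L, p)
    tibble::as_tibble(X[, model$orig_names, drop = FALSE])
  })
}
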