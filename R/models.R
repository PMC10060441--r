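# The two classifiers compared in the temporal analysis: elastic-net
# penalized logistic regression (ENR) and a 100-tree Gini random forest
# (RF), each with a 3x3 hyperparameter grid.

#' One model configuration
#'
#' A configuration is one cell of the 2 outcomes x 2 algorithms x 2
#' predictor sets space (8 models in total).
#'
#' @param outcome `"depression"` or `"si"`.
#' @param algorithm `"ENR"` (elastic-net logistic regression) or `"RF"`
#'   (random forest).
#' @param predictor_set `"mood_only"` or `"mood_plus_wearable"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(outcome = c("depression", "si"),
                         algorithm = c("ENR", "RF"),
                         predictor_set = c("mood_only", "mood_plus_wearable")) {
  structure(
    list(outcome = match.arg(outcome), algorithm = match.arg(algorithm),
         predictor_set = match.arg(predictor_set)),
    class = "model_config"
  )
}

#' The full 8-member model configuration space
#'
#' @return A list of 8 [model_config()] objects (2 outcomes x 2 algorithms
#'   x 2 predictor sets).
#' @export
model_configs <- function() {
  grid <- expand.grid(outcome = c("depression", "si"),
                      algorithm = c("ENR", "RF"),
                      predictor_set = c("mood_only", "mood_plus_wearable"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    model_config(grid$outcome[i], grid$algorithm[i], grid$predictor_set[i])
  })
}

#' Short label for a model configuration
#' @param config A `model_config`.
#' @return A string such as `"depression_ENR_mood_only"`.
#' @export
config_label <- function(config) {
  paste(config$outcome, config$algorithm, config$predictor_set, sep = "_")
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:", config_label(x), "\n")
  invisible(x)
}

#' Hyperparameter grid candidates for one algorithm
#'
#' Returns the 3 x 3 grid searched in the inner tuning loop. For ENR the
#' grid crosses the penalty magnitude (3 log-uniform levels over
#' \[1e-10, 1\]) with the L1 proportion (0, 0.5, 1). For RF it crosses
#' `mtry` (3 evenly spaced integers over \[1, n_predictors\]) with the
#' minimum node size required to split (2, 21, 40); the number of trees is
#' fixed at 100.
#'
#' Note on naming: the source literature for this design labels the ENR
#' penalty "alpha" and the mixture "lambda", the reverse of the common
#' glmnet convention; this package uses the unambiguous names `penalty`
#' and `mixture` everywhere.
#'
#' @param algorithm `"ENR"` or `"RF"`.
#' @param n_predictors Number of predictor columns (needed for the RF
#'   `mtry` range).
#' @return A data.frame of exactly 9 hyperparameter settings.
#' @export
grid_candidates <- function(algorithm = c("ENR", "RF"), n_predictors = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "ENR") {
    grid <- expand.grid(penalty = 10^seq(-10, 0, length.out = 3),
                        mixture = c(0, 0.5, 1))
  } else {
    if (is.null(n_predictors) || n_predictors < 1) {
      stop("grid_candidates: n_predictors >= 1 required for RF", call. = FALSE)
    }
    mtry <- as.integer(round(seq(1, n_predictors, length.out = 3)))
    grid <- expand.grid(mtry = mtry, min_node = c(2L, 21L, 40L))
    grid$n_trees <- 100L
  }
  grid
}

assert_model_inputs <- function(X, y) {
  if (anyNA(X)) {
    stop("model fit: feature matrix contains unavailable entries; ",
         "apply imputation first", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop_fit_degenerate("single-class outcome in training data")
  }
  invisible(TRUE)
}

all_columns_constant <- function(X) {
  all(col_vars(X) == 0)
}

# column variances without an extra dependency
col_vars <- function(X) {
  mu <- colMeans(X)
  colSums(sweep(X, 2, mu)^2) / max(1, nrow(X) - 1)
}

# binomial glmnet with its small-class-count advisory muffled (expected on
# small inner folds of a low-prevalence outcome; the fit is still valid)
glmnet_quietly <- function(X, y, alpha, lambda, thresh = 1e-10) {
  withCallingHandlers(
    glmnet::glmnet(X, y, family = "binomial", alpha = alpha, lambda = lambda,
                   standardize = TRUE, thresh = thresh, maxit = 1e6),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

stop_fit_degenerate <- function(msg) {
  stop(structure(class = c("moodcast_degenerate_fit", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Fit an elastic-net logistic regression
#'
#' Minimizes the penalized negative binomial log-likelihood with penalty
#' `penalty * (mixture * ||b||_1 + (1 - mixture) / 2 * ||b||_2^2)`.
#' Features are standardized to zero mean / unit variance using training
#' statistics before fitting (glmnet's internal standardization);
#' probabilities are returned on the original scale.
#'
#' @param X Numeric matrix (rows = participants), fully imputed.
#' @param y Binary 0/1 vector with both classes present.
#' @param penalty Overall regularization magnitude (> 0).
#' @param mixture L1 proportion in \[0, 1\].
#' @param thresh Coordinate-descent convergence threshold passed to glmnet.
#' @return A fitted classifier of class `moodcast_enr`; use `predict()` to
#'   obtain class-1 probabilities.
#' @export
fit_enr <- function(X, y, penalty, mixture, thresh = 1e-10) {
  X <- as.matrix(X)
  assert_model_inputs(X, y)
  stopifnot(penalty > 0, mixture >= 0, mixture <= 1)
  # fit along a short descending path ending at the requested penalty:
  # warm starts make the solution at `penalty` accurate and cheap
  path <- sort(unique(penalty * c(1000, 100, 10, 1)), decreasing = TRUE)
  if (all_columns_constant(X)) {
    # nothing to discriminate on (e.g. a subgroup where every feature is
    # constant): intercept-only model, probability = training proportion
    return(structure(list(intercept = qlogis(clamp01(mean(y))),
                          beta = rep(0, ncol(X)),
                          penalty = penalty, mixture = mixture,
                          p1_train = mean(y)),
                     class = "moodcast_enr"))
  }
  fit <- glmnet_quietly(X, y, alpha = mixture, lambda = path, thresh = thresh)
  # the requested penalty is the last path entry unless glmnet stopped the
  # path early; then the nearest (smallest) fitted lambda stands in
  i <- which.min(abs(log(fit$lambda) - log(penalty)))
  structure(list(intercept = as.numeric(fit$a0[i]),
                 beta = as.numeric(fit$beta[, i]),
                 penalty = penalty, mixture = mixture,
                 p1_train = mean(y)),
            class = "moodcast_enr")
}

#' @export
predict.moodcast_enr <- function(object, newdata, ...) {
  eta <- as.matrix(newdata) %*% object$beta + object$intercept
  as.vector(plogis(eta))
}

# evaluate all (penalty, mixture) grid cells for one inner train/validation
# split with one glmnet path fit per mixture (identical objective to
# fit_enr, warm-started along the shared descending penalty path)
enr_grid_validation_auc <- function(X_fit, y_fit, X_val, y_val, grid) {
  out <- numeric(nrow(grid))
  if (all_columns_constant(X_fit)) {
    # every setting collapses to the intercept-only model: all-tied scores
    return(rep(0.5, nrow(grid)))
  }
  for (m in unique(grid$mixture)) {
    rows <- which(grid$mixture == m)
    pens <- grid$penalty[rows]
    path <- sort(unique(c(pens, max(pens) * c(1000, 100, 10))),
                 decreasing = TRUE)
    fit <- glmnet_quietly(X_fit, y_fit, alpha = m, lambda = path)
    # glmnet may stop the path early (saturated deviance); index by the
    # lambdas actually fitted and fall back to the nearest fitted one
    lam <- fit$lambda
    eta <- as.matrix(X_val %*% fit$beta) +
      matrix(fit$a0, nrow(X_val), length(lam), byrow = TRUE)
    for (j in seq_along(rows)) {
      k <- which.min(abs(log(lam) - log(pens[j])))
      out[rows[j]] <- auc(eta[, k], y_val)
    }
  }
  out
}

#' Fit a 100-tree Gini random forest
#'
#' Bootstrap-resampled probability forest with Gini-impurity splits;
#' predicted probabilities are averaged leaf class proportions over trees.
#' Every fit receives an explicit seed from the orchestration layer so the
#' full sweep is exactly reproducible.
#'
#' @param X Numeric matrix, fully imputed.
#' @param y Binary 0/1 vector with both classes present.
#' @param mtry Variables tried per split (clamped to the column count).
#' @param min_node Minimum observations for a node to be split further.
#' @param n_trees Ensemble size (default 100).
#' @param seed Integer seed for the forest.
#' @return A fitted classifier of class `moodcast_rf`.
#' @export
fit_rf <- function(X, y, mtry, min_node, n_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  assert_model_inputs(X, y)
  df <- as.data.frame(X)
  df$.outcome <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    probability = TRUE, num.trees = n_trees,
    mtry = min(as.integer(mtry), ncol(X)),
    min.node.size = as.integer(min_node),
    splitrule = "gini", seed = as.integer(seed), num.threads = 1
  )
  structure(list(fit = fit, cols = colnames(df)[colnames(df) != ".outcome"]),
            class = "moodcast_rf")
}

#' @export
predict.moodcast_rf <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  colnames(df) <- object$cols
  p <- predict(object$fit, data = df, num.threads = 1)$predictions
  as.vector(p[, "1"])
}

# fit one (algorithm, hyperparameter-row) setting; seed only used by RF
fit_classifier <- function(algorithm, X, y, hp, seed = 1L) {
  if (algorithm == "ENR") {
    fit_enr(X, y, penalty = hp$penalty, mixture = hp$mixture)
  } else {
    fit_rf(X, y, mtry = hp$mtry, min_node = hp$min_node,
           n_trees = hp$n_trees, seed = seed)
  }
}
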