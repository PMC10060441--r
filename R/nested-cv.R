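# Nested cross-validation for one (day, model configuration) cell:
# 3-fold inner hyperparameter tuning, 3x5 repeated outer validation,
# 15 AUC estimates, conservative standard error (sample SD / sqrt(k)).

# deterministic 32-bit seed derived from a stream of small integers
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 0
  for (p in parts) h <- (h * 69069 + p * 2654435 + 1) %% 2147483647
  as.integer(h)
}

# stratified assignment of indices to k folds: within each class, shuffled
# members are dealt round-robin over a shuffled fold order, so each fold's
# class count differs from exact proportionality by at most 1
stratified_fold_ids <- function(labels, k) {
  n <- length(labels)
  fold_of <- integer(n)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep(sample.int(k), length.out = length(idx))
  }
  fold_of
}

#' Build a nested fold plan
#'
#' Partitions participants into `repeats` independent stratified k-fold
#' splits (the outer loop), and within each outer training set into
#' `inner_k` stratified folds (the inner tuning loop). Stratification is by
#' outcome label so each fold's case count differs from proportionality by
#' at most 1 — important because suicidal-ideation prevalence (~7%) makes
#' unstratified folds frequently single-class.
#'
#' @param labels Binary 0/1 outcome vector, one entry per participant.
#' @param k Outer folds per repeat (default 5).
#' @param repeats Outer repeats (default 3).
#' @param inner_k Inner folds (default 3).
#' @param seed Integer seed; the plan is a pure function of
#'   `(labels, k, repeats, inner_k, seed)`.
#' @return An object of class `fold_plan`: `outer[[r]][[f]]` holds the
#'   test indices of fold f in repeat r; `inner[[r]][[f]][[g]]` holds the
#'   inner-validation indices (subsets of the outer training set) used when
#'   tuning for that outer fold.
#' @export
make_fold_plan <- function(labels, k = 5L, repeats = 3L, inner_k = 3L, seed = 1L) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  if (n < 2 * k) {
    stop("make_fold_plan: need at least 2k participants (n = ", n, ", k = ",
         k, ")", call. = FALSE)
  }
  if (n_pos < k) {
    stop("make_fold_plan: only ", n_pos, " cases for ", k, " folds; ",
         "use a larger cohort or fewer folds", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  outer_folds <- vector("list", repeats)
  inner_folds <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of <- stratified_fold_ids(labels, k)
    outer_folds[[r]] <- lapply(seq_len(k), function(f) which(fold_of == f))
    inner_folds[[r]] <- vector("list", k)
    for (f in seq_len(k)) {
      train_idx <- which(fold_of != f)
      inner_of <- stratified_fold_ids(labels[train_idx], inner_k)
      inner_folds[[r]][[f]] <- lapply(seq_len(inner_k), function(g) {
        train_idx[inner_of == g]
      })
    }
  }
  structure(list(outer = outer_folds, inner = inner_folds, n = n,
                 k = as.integer(k), repeats = as.integer(repeats),
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_case > score_control) + 0.5 * P(tie)` over all case-control
#' pairs, computed via mid-ranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return The AUC, in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("auc: undefined for single-class labels", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# order grid rows from most to least regularized, used for tie-breaking
regularization_order <- function(algorithm, grid) {
  if (algorithm == "ENR") {
    order(-grid$penalty, -grid$mixture)
  } else {
    order(-grid$min_node, grid$mtry)
  }
}

#' Tune hyperparameters on a training set via inner cross-validation
#'
#' Evaluates every grid setting on the inner folds (fitting the imputation
#' model inside each inner-training split, so no information leaks from
#' inner-validation rows) and returns the setting maximizing the mean
#' inner-fold AUC. Exact ties are broken toward stronger regularization:
#' larger penalty then larger mixture for ENR; larger minimum node size
#' then smaller mtry for RF.
#'
#' @param features Feature data.frame for the outer training set's cohort
#'   (all participants; indices below select rows).
#' @param y Full outcome vector aligned with `features` rows.
#' @param train_idx Row indices of the outer training set.
#' @param inner_folds List of inner-validation index vectors (subsets of
#'   `train_idx`).
#' @param algorithm `"ENR"` or `"RF"`.
#' @param grid Hyperparameter grid (default [grid_candidates()]).
#' @param seed Base seed for stochastic fits.
#' @return A list: `best` (one-row data.frame of the chosen setting) and
#'   `mean_auc` per grid row.
#' @export
inner_tune <- function(features, y, train_idx, inner_folds, algorithm,
                       grid = NULL, seed = 1L) {
  n_pred <- ncol(feature_matrix_values(features))
  if (is.null(grid)) grid <- grid_candidates(algorithm, n_pred)
  fold_auc <- matrix(NA_real_, nrow = nrow(grid), ncol = length(inner_folds))
  for (g in seq_along(inner_folds)) {
    val_idx <- inner_folds[[g]]
    fit_idx <- setdiff(train_idx, val_idx)
    if (length(unique(y[val_idx])) < 2L || length(unique(y[fit_idx])) < 2L) next
    imp <- fit_imputation(features[fit_idx, , drop = FALSE])
    X_fit <- feature_matrix_values(apply_imputation(imp, features[fit_idx, , drop = FALSE]))
    X_val <- feature_matrix_values(apply_imputation(imp, features[val_idx, , drop = FALSE]))
    if (algorithm == "ENR" && all(c("penalty", "mixture") %in% names(grid))) {
      # warm-started path fit per mixture: same objective, one glmnet call
      # per mixture level instead of one per grid row
      fold_auc[, g] <- enr_grid_validation_auc(X_fit, y[fit_idx], X_val,
                                               y[val_idx], grid)
    } else {
      for (j in seq_len(nrow(grid))) {
        fit <- fit_classifier(algorithm, X_fit, y[fit_idx], grid[j, , drop = FALSE],
                              seed = derive_seed(seed, g, j))
        fold_auc[j, g] <- auc(predict(fit, X_val), y[val_idx])
      }
    }
  }
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  if (all(is.nan(mean_auc))) {
    stop("inner_tune: all inner folds degenerate", call. = FALSE)
  }
  ord <- regularization_order(algorithm, grid)
  best_val <- max(mean_auc[ord], na.rm = TRUE)
  best_row <- ord[which(mean_auc[ord] >= best_val - 1e-12)[1]]
  list(best = grid[best_row, , drop = FALSE], mean_auc = mean_auc,
       fold_auc = fold_auc)
}

#' Nested-CV performance for one (day, configuration) cell
#'
#' Builds the day-t feature matrix, then for each of the 15 outer
#' train/test splits: fits the imputation model on the outer training set,
#' tunes hyperparameters via the inner folds, refits on the full outer
#' training set with the chosen setting, scores the outer test fold, and
#' computes its AUC. Returns the 15 estimates with their mean and the
#' conservative standard error `sd(estimates) / sqrt(k)` (not `sqrt(k *
#' repeats)`, which would be optimistically biased because the repeats
#' reuse the same participants).
#'
#' Degenerate outer test folds (single class) are dropped with a warning,
#' so fewer than 15 estimates may be returned; the count is recorded.
#'
#' @param cohort A `cohort`.
#' @param day As-of day t.
#' @param config A [model_config()].
#' @param plan A [make_fold_plan()] for this cohort's participants (ordered
#'   by participant id).
#' @param grid Optional hyperparameter grid override.
#' @param seed Base seed for stochastic fits (RF).
#' @return An object of class `day_performance`: list with `day`, `config`,
#'   `auc_estimates` (data.frame: repeat, fold, auc, plus the chosen
#'   hyperparameters), `mean_auc`, `se_auc`, `n_estimates`, `n_dropped`.
#' @export
evaluate_day <- function(cohort, day, config, plan, grid = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "model_config"),
            inherits(plan, "fold_plan"))
  features <- build_feature_matrix(cohort, day, config$predictor_set)
  outcomes <- cohort$outcomes[order(cohort$outcomes$participant_id), , drop = FALSE]
  stopifnot(identical(outcomes$participant_id, features$participant_id))
  y <- outcomes[[config$outcome]]
  if (plan$n != length(y)) {
    stop("evaluate_day: fold plan built for ", plan$n,
         " participants, cohort has ", length(y), call. = FALSE)
  }
  rows <- list()
  n_dropped <- 0L
  for (r in seq_len(plan$repeats)) {
    for (f in seq_len(plan$k)) {
      test_idx <- plan$outer[[r]][[f]]
      train_idx <- setdiff(seq_along(y), test_idx)
      if (length(unique(y[test_idx])) < 2L || length(unique(y[train_idx])) < 2L) {
        warning("evaluate_day: dropping degenerate outer fold (repeat ", r,
                ", fold ", f, ") on day ", day, call. = FALSE)
        n_dropped <- n_dropped + 1L
        next
      }
      tuned <- inner_tune(features, y, train_idx, plan$inner[[r]][[f]],
                          config$algorithm, grid = grid,
                          seed = derive_seed(seed, day, r, f))
      imp <- fit_imputation(features[train_idx, , drop = FALSE])
      X_train <- feature_matrix_values(apply_imputation(imp, features[train_idx, , drop = FALSE]))
      X_test <- feature_matrix_values(apply_imputation(imp, features[test_idx, , drop = FALSE]))
      fit <- fit_classifier(config$algorithm, X_train, y[train_idx],
                            tuned$best,
                            seed = derive_seed(seed, day, r, f, 999))
      est <- auc(predict(fit, X_test), y[test_idx])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(repeat_ = r, fold = f, auc = est), tuned$best
      )
    }
  }
  estimates <- do.call(rbind, rows)
  aucs <- estimates$auc
  structure(
    list(day = as.integer(day), config = config, auc_estimates = estimates,
         mean_auc = mean(aucs),
         se_auc = if (length(aucs) > 1) sd(aucs) / sqrt(plan$k) else NA_real_,
         n_estimates = length(aucs), n_dropped = n_dropped),
    class = "day_performance"
  )
}

#' @export
print.day_performance <- function(x, ...) {
  cat(sprintf("day %d  %s: mean AUC %.3f (SE %.3f, %d estimates)\n",
              x$day, config_label(x$config), x$mean_auc, x$se_auc,
              x$n_estimates))
  invisible(x)
}
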