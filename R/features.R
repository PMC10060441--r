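# Day-1..t summary features: mean, standard deviation and percent missing
# per daily variable, with minimum-observation rules and training-median
# imputation.

#' Summarize one daily variable over days 1..t
#'
#' Computes the three accumulating summary statistics for a single
#' participant-variable series: the mean over observed values (available
#' only with at least two observations), the sample standard deviation
#' (n - 1 denominator, at least three observations), and the percent of
#' missing days, which is always computable as `100 * missing / t`.
#'
#' @param values Numeric vector of length t (the series for days 1..t),
#'   with `NA` marking missing days.
#' @return A list with elements `mean`, `sd` (each `NA` when unavailable)
#'   and `pct_missing`.
#' @export
summarize_variable <- function(values) {
  if (length(values) == 0L) {
    stop("summarize_variable: empty series", call. = FALSE)
  }
  obs <- values[!is.na(values)]
  n_obs <- length(obs)
  list(
    mean = if (n_obs >= 2L) mean(obs) else NA_real_,
    sd = if (n_obs >= 3L) sd(obs) else NA_real_,
    pct_missing = 100 * (length(values) - n_obs) / length(values)
  )
}

#' Feature column names for a predictor set
#'
#' @param predictor_set `"mood_only"` (3 features) or
#'   `"mood_plus_wearable"` (33 features: 3 statistics x 11 variables).
#' @return Character vector of feature names, mood first, statistics in
#'   mean / sd / pct_missing order within each variable.
#' @export
feature_names <- function(predictor_set = c("mood_plus_wearable", "mood_only")) {
  predictor_set <- match.arg(predictor_set)
  vars <- if (predictor_set == "mood_only") "mood" else daily_variables()
  as.vector(t(outer(vars, c("mean", "sd", "pct_missing"), paste, sep = "_")))
}

#' Build the day-t feature matrix for a cohort
#'
#' One row per participant; columns are the accumulating summary features
#' computed from days 1..t only (no lookahead). Unavailable statistics
#' (too few observations) are carried as `NA` and left for train-fold
#' median imputation inside the cross-validation loop — they are never
#' imputed globally.
#'
#' @param cohort A `cohort`.
#' @param t As-of day, in 1..horizon_days.
#' @param predictor_set `"mood_only"` or `"mood_plus_wearable"`.
#' @return A data.frame with `participant_id`, `as_of_day`, and 3 or 33
#'   feature columns, ordered by participant id.
#' @export
build_feature_matrix <- function(cohort, t,
                                 predictor_set = c("mood_plus_wearable", "mood_only")) {
  stopifnot(inherits(cohort, "cohort"))
  predictor_set <- match.arg(predictor_set)
  t <- as.integer(t)
  if (t < 1L || t > cohort$horizon_days) {
    stop("build_feature_matrix: t must lie in 1..", cohort$horizon_days,
         call. = FALSE)
  }
  ids <- sort(unique(cohort$daily$participant_id))
  n <- length(ids)
  daily <- cohort$daily[cohort$daily$day <= t, , drop = FALSE]
  daily <- daily[order(daily$participant_id, daily$day), , drop = FALSE]
  vars <- if (predictor_set == "mood_only") "mood" else daily_variables()

  out <- data.frame(participant_id = ids, as_of_day = t,
                    stringsAsFactors = FALSE)
  for (v in vars) {
    x <- matrix(as.numeric(daily[[v]]), nrow = t, ncol = n)
    n_obs <- colSums(!is.na(x))
    mu <- colMeans(x, na.rm = TRUE)
    centered <- sweep(x, 2, mu, "-")
    ss <- colSums(centered^2, na.rm = TRUE)
    sdv <- sqrt(ss / pmax(n_obs - 1, 1))
    mu[n_obs < 2] <- NA_real_
    sdv[n_obs < 3] <- NA_real_
    out[[paste0(v, "_mean")]] <- mu
    out[[paste0(v, "_sd")]] <- sdv
    out[[paste0(v, "_pct_missing")]] <- 100 * (t - n_obs) / t
  }
  out
}

# midpoints of plausible variable ranges, used only as a last-resort
# fallback when a mean feature has no available training value at all
mean_fallbacks <- function() {
  wp <- wearable_params()
  mids <- vapply(wp, function(p) (p$lo + p$hi) / 2, numeric(1))
  c(mood = 5.5, mids)
}

#' Fit a training-median imputation model
#'
#' Computes, per feature column, the median of the available training-fold
#' values. Features with no available training value fall back to a
#' documented constant (0 for SD features, the variable-range midpoint for
#' mean features) with a warning. Percent-missing features are always
#' available and never require imputation.
#'
#' @param train_rows A feature data.frame (as from
#'   [build_feature_matrix()]) restricted to training-fold rows.
#' @return An object of class `imputation_model`: named numeric vector of
#'   fill values per feature column.
#' @export
fit_imputation <- function(train_rows) {
  cols <- setdiff(names(train_rows), c("participant_id", "as_of_day"))
  if (nrow(train_rows) == 0L) {
    stop("fit_imputation: empty training set", call. = FALSE)
  }
  fb <- mean_fallbacks()
  med <- vapply(cols, function(cl) {
    v <- train_rows[[cl]]
    v <- v[!is.na(v)]
    if (length(v)) return(median(v))
    # no available training value for this feature
    if (grepl("_sd$", cl)) {
      warning("fit_imputation: no available training values for '", cl,
              "'; falling back to 0", call. = FALSE)
      0
    } else {
      var <- sub("_(mean|pct_missing)$", "", cl)
      fallback <- if (var %in% names(fb)) fb[[var]] else 0
      warning("fit_imputation: no available training values for '", cl,
              "'; falling back to ", fallback, call. = FALSE)
      fallback
    }
  }, numeric(1))
  structure(med, class = "imputation_model")
}

#' Apply a training-median imputation model
#'
#' Replaces unavailable (`NA`) feature entries with the training medians;
#' available entries are never altered.
#'
#' @param model An `imputation_model` from [fit_imputation()].
#' @param rows A feature data.frame.
#' @return `rows` with `NA` feature entries filled in.
#' @export
apply_imputation <- function(model, rows) {
  stopifnot(inherits(model, "imputation_model"))
  for (cl in names(model)) {
    if (!cl %in% names(rows)) next
    idx <- is.na(rows[[cl]])
    if (any(idx)) rows[[cl]][idx] <- model[[cl]]
  }
  rows
}

# numeric feature matrix (participants x features) from a feature data.frame
feature_matrix_values <- function(rows) {
  cols <- setdiff(names(rows), c("participant_id", "as_of_day"))
  as.matrix(rows[, cols, drop = FALSE])
}
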