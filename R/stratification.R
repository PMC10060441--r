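# Adherence-defined subgroup analysis: missingness groups are recomputed
# each day from the proportion of missing daily mood observations up to
# that day, and the best-performing configuration (ENR, mood-only
# predictors, missingness included) is rerun within each subgroup.

#' Missingness group specification
#'
#' For depression, three groups on the proportion of missing daily mood
#' observations: low `[0, 1/3)`, medium `[1/3, 2/3]`, high `(2/3, 1]`.
#' For suicidal ideation (lower prevalence, less power), two groups:
#' high `>= 1/2` missing, low `< 1/2`. Boundaries are exact thirds/halves
#' and half-open so the groups partition `[0, 1]` deterministically.
#'
#' @param outcome `"depression"` or `"si"`.
#' @return An object of class `missingness_spec` with the group labels,
#'   break points, and completion-rate aliases (completion = 1 -
#'   missingness) for unambiguous reporting.
#' @export
missingness_group_spec <- function(outcome = c("depression", "si")) {
  outcome <- match.arg(outcome)
  if (outcome == "depression") {
    spec <- list(outcome = outcome,
                 groups = c("low", "medium", "high"),
                 breaks = c(1 / 3, 2 / 3),
                 aliases = c(low = "completion > 2/3",
                             medium = "completion 1/3-2/3",
                             high = "completion < 1/3"))
  } else {
    spec <- list(outcome = outcome,
                 groups = c("low", "high"),
                 breaks = 1 / 2,
                 aliases = c(low = "completion > 1/2",
                             high = "completion <= 1/2"))
  }
  structure(spec, class = "missingness_spec")
}

#' Assign participants to missingness groups as of day t
#'
#' Group membership is recomputed independently per day from the mood
#' missingness proportion over days 1..t, so a participant can move
#' between groups across the quarter. Depression groups: low missingness
#' `< 1/3`, medium `[1/3, 2/3]`, high `> 2/3`. SI groups: high `>= 1/2`
#' missing (boundary cases go to high), low otherwise.
#'
#' @param cohort A `cohort`.
#' @param t As-of day.
#' @param spec A [missingness_group_spec()].
#' @return A factor of group labels, named by participant id, with levels
#'   `spec$groups`.
#' @export
assign_groups <- function(cohort, t, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "missingness_spec"))
  feats <- build_feature_matrix(cohort, t, "mood_only")
  # integer missing-day counts so exact-thirds/halves boundaries resolve
  # deterministically (pct_missing is 100 * m / t by construction)
  m <- as.integer(round(feats$mood_pct_missing * t / 100))
  if (spec$outcome == "depression") {
    grp <- ifelse(3L * m < t, "low",
                  ifelse(3L * m <= 2L * t, "medium", "high"))
  } else {
    grp <- ifelse(2L * m >= t, "high", "low")
  }
  factor(grp, levels = spec$groups) |>
    stats::setNames(feats$participant_id)
}

#' Per-group temporal sweep (Table-2-style analysis)
#'
#' For each evaluated day, reassigns missingness groups from the mood
#' response rates up to that day and runs the nested-CV evaluation of the
#' ENR mood-only configuration (missingness features included — they stay
#' informative within groups because the grouping is coarse) within each
#' subgroup. Day-group cells whose subsample cannot support the fold
#' scheme (too few participants or cases) are marked unavailable with a
#' warning rather than failing the sweep.
#'
#' @param cohort A `cohort`.
#' @param spec A [missingness_group_spec()].
#' @param days Integer vector of days to evaluate.
#' @param master_seed Master seed.
#' @param k,repeats,inner_k Fold scheme (defaults 5, 3, 3).
#' @param grid Optional hyperparameter grid override.
#' @return A named list of `performance_curve`s, one per group (days whose
#'   cell was skipped carry `NA` mean/se).
#' @export
run_stratified_sweep <- function(cohort, spec, days, master_seed = 1L,
                                 k = 5L, repeats = 3L, inner_k = 3L,
                                 grid = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "missingness_spec"))
  days <- sort(unique(as.integer(days)))
  config <- model_config(spec$outcome, "ENR", "mood_only")
  outcomes <- cohort$outcomes[order(cohort$outcomes$participant_id), , drop = FALSE]

  curves <- lapply(spec$groups, function(g) NULL)
  names(curves) <- spec$groups
  pts <- lapply(spec$groups, function(g) vector("list", length(days)))
  names(pts) <- spec$groups

  for (i in seq_along(days)) {
    d <- days[i]
    grp <- assign_groups(cohort, d, spec)
    for (g in spec$groups) {
      ids <- names(grp)[grp == g]
      na_point <- data.frame(day = d, mean_auc = NA_real_, se_auc = NA_real_,
                             n_estimates = 0L, n_participants = length(ids))
      y_g <- outcomes[[spec$outcome]][outcomes$participant_id %in% ids]
      if (length(ids) < 2 * k || sum(y_g == 1) < k || sum(y_g == 0) < k) {
        warning("run_stratified_sweep: day ", d, " group '", g,
                "' too small for the fold scheme (n = ", length(ids),
                ", cases = ", sum(y_g == 1), "); point marked unavailable",
                call. = FALSE)
        pts[[g]][[i]] <- na_point
        next
      }
      sub <- subset_cohort(cohort, ids)
      plan <- make_fold_plan(y_g, k, repeats, inner_k,
                             seed = derive_seed(master_seed, d, match(g, spec$groups)))
      perf <- evaluate_day(sub, d, config, plan, grid = grid,
                           seed = derive_seed(master_seed, 1))
      pts[[g]][[i]] <- data.frame(day = d, mean_auc = perf$mean_auc,
                                  se_auc = perf$se_auc,
                                  n_estimates = perf$n_estimates,
                                  n_participants = length(ids))
    }
  }
  for (g in spec$groups) {
    curve <- do.call(rbind, pts[[g]])
    attr(curve, "config") <- config
    attr(curve, "group") <- g
    attr(curve, "group_alias") <- unname(spec$aliases[g])
    class(curve) <- c("performance_curve", "data.frame")
    curves[[g]] <- curve
  }
  curves
}

#' Convergence summaries for a stratified sweep
#'
#' @param curves Result of [run_stratified_sweep()].
#' @param threshold Acceptability threshold (default 0.70).
#' @return A data.frame with one row per group, including the
#'   completion-rate alias for each missingness label.
#' @export
stratified_summary <- function(curves, threshold = 0.70) {
  do.call(rbind, lapply(names(curves), function(g) {
    cv <- curves[[g]]
    if (all(is.na(cv$mean_auc))) {
      return(NULL)
    }
    s <- convergence_summary(cv, threshold)
    cbind(data.frame(missingness_group = g,
                     group_alias = attr(cv, "group_alias"),
                     stringsAsFactors = FALSE), s)
  }))
}
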