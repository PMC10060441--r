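# Temporal sweep over days and the two day-finding rules: first day within
# one standard error of the final day's mean AUC, and last day below the
# acceptability threshold (AUC 0.70).

#' Sweep a set of days for one or more model configurations
#'
#' Runs [evaluate_day()] for every (configuration, day) cell. Each day's
#' fold plan is regenerated from `(master_seed, day)`, i.e. the days are
#' treated as independent analyses; set `shared_folds = TRUE` to reuse one
#' plan across all days (lower curve noise, same participants per fold on
#' every day). Per-day results can be cached to `cache_dir` and reused on
#' restart if the run settings are unchanged.
#'
#' @param cohort A `cohort`.
#' @param configs A [model_config()] or list of them (default: the full
#'   8-member space).
#' @param days Integer vector of days to evaluate (subset of 1..horizon).
#' @param master_seed Master seed; every stochastic step derives its seed
#'   from it.
#' @param k,repeats,inner_k Fold scheme (defaults 5, 3, 3).
#' @param grid Optional hyperparameter grid override.
#' @param shared_folds Reuse one fold plan across days (default FALSE).
#' @param cache_dir Optional directory for resumable per-day caching.
#' @return A named list of `performance_curve` objects (one per
#'   configuration): data.frames with columns `day`, `mean_auc`, `se_auc`,
#'   `n_estimates`, carrying the config as an attribute, plus the tidy
#'   per-fold estimates in the `estimates` attribute.
#' @export
run_temporal_sweep <- function(cohort, configs = model_configs(), days,
                               master_seed = 1L, k = 5L, repeats = 3L,
                               inner_k = 3L, grid = NULL,
                               shared_folds = FALSE, cache_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (inherits(configs, "model_config")) configs <- list(configs)
  days <- sort(unique(as.integer(days)))
  if (length(days) == 0L) stop("run_temporal_sweep: empty day grid", call. = FALSE)
  if (any(days < 1L | days > cohort$horizon_days)) {
    stop("run_temporal_sweep: days must lie in 1..", cohort$horizon_days,
         call. = FALSE)
  }
  if (!is.null(cache_dir)) {
    check_cache_meta(cache_dir, cohort, master_seed, k, repeats, inner_k, grid,
                     shared_folds)
  }
  outcomes <- cohort$outcomes[order(cohort$outcomes$participant_id), , drop = FALSE]
  shared_plans <- NULL
  if (shared_folds) {
    shared_plans <- lapply(c(depression = "depression", si = "si"), function(oc) {
      make_fold_plan(outcomes[[oc]], k, repeats, inner_k,
                     seed = derive_seed(master_seed, 0))
    })
  }
  curves <- list()
  for (config in configs) {
    label <- config_label(config)
    pts <- vector("list", length(days))
    est <- vector("list", length(days))
    for (i in seq_along(days)) {
      d <- days[i]
      cached <- if (!is.null(cache_dir)) read_day_cache(cache_dir, label, d) else NULL
      if (!is.null(cached)) {
        perf <- cached
      } else {
        plan <- if (shared_folds) {
          shared_plans[[config$outcome]]
        } else {
          make_fold_plan(outcomes[[config$outcome]], k, repeats, inner_k,
                         seed = derive_seed(master_seed, d))
        }
        perf <- evaluate_day(cohort, d, config, plan, grid = grid,
                             seed = derive_seed(master_seed, 1))
        if (!is.null(cache_dir)) write_day_cache(cache_dir, label, perf)
      }
      pts[[i]] <- data.frame(day = perf$day, mean_auc = perf$mean_auc,
                             se_auc = perf$se_auc,
                             n_estimates = perf$n_estimates)
      e <- perf$auc_estimates
      e$day <- perf$day
      est[[i]] <- e
    }
    curve <- do.call(rbind, pts)
    attr(curve, "config") <- config
    attr(curve, "estimates") <- do.call(rbind, lapply(est, function(e) {
      e[, c("day", "repeat_", "fold", "auc")]
    }))
    class(curve) <- c("performance_curve", "data.frame")
    curves[[label]] <- curve
  }
  curves
}

# ---- per-day result caching -------------------------------------------

cache_meta <- function(cohort, master_seed, k, repeats, inner_k, grid,
                       shared_folds) {
  list(n_participants = nrow(cohort$outcomes),
       horizon_days = cohort$horizon_days,
       cohort_config = if (!is.null(cohort$config)) unclass(cohort$config) else NULL,
       master_seed = master_seed, k = k, repeats = repeats,
       inner_k = inner_k, grid = grid, shared_folds = shared_folds,
       package_version = as.character(utils::packageVersion("moodcast")))
}

check_cache_meta <- function(cache_dir, cohort, master_seed, k, repeats,
                             inner_k, grid, shared_folds) {
  meta <- cache_meta(cohort, master_seed, k, repeats, inner_k, grid,
                     shared_folds)
  meta_json <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  meta_file <- file.path(cache_dir, "run-meta.json")
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  if (file.exists(meta_file)) {
    old <- paste(readLines(meta_file, warn = FALSE), collapse = "\n")
    if (old != as.character(meta_json)) {
      stop("run_temporal_sweep: cache directory '", cache_dir, "' was ",
           "written under different run settings (cohort, seeds, folds or ",
           "grids changed); refusing to resume. Use a fresh cache_dir.",
           call. = FALSE)
    }
  } else {
    writeLines(as.character(meta_json), meta_file)
  }
  invisible(TRUE)
}

day_cache_file <- function(cache_dir, label, day) {
  file.path(cache_dir, sprintf("%s_day%03d.csv", label, day))
}

write_day_cache <- function(cache_dir, label, perf) {
  write.csv(perf$auc_estimates, day_cache_file(cache_dir, label, perf$day),
            row.names = FALSE)
}

read_day_cache <- function(cache_dir, label, day) {
  f <- day_cache_file(cache_dir, label, day)
  if (!file.exists(f)) return(NULL)
  est <- read.csv(f, stringsAsFactors = FALSE)
  cfg <- strsplit(label, "_")[[1]]
  k <- max(est$fold)
  structure(
    list(day = as.integer(day),
         config = model_config(cfg[1], cfg[2],
                               paste(cfg[-(1:2)], collapse = "_")),
         auc_estimates = est, mean_auc = mean(est$auc),
         se_auc = sd(est$auc) / sqrt(k),
         n_estimates = nrow(est), n_dropped = NA_integer_),
    class = "day_performance"
  )
}

# ---- convergence rules -------------------------------------------------

curve_points <- function(curve) {
  pts <- curve[!is.na(curve$mean_auc), c("day", "mean_auc", "se_auc"), drop = FALSE]
  pts[order(pts$day), , drop = FALSE]
}

#' First day within one standard error of the final day's mean AUC
#'
#' The one-standard-error rule used to declare that a model trained on the
#' data available to date approximates the final-day model: the smallest
#' evaluated day d with `mean_auc(d) >= mean_auc(final) - band`, where the
#' band is the final day's SE (`band = "final"`, the default, a literal
#' reading of the rule) or the candidate day's own SE
#' (`band = "candidate"`). With `sustained = TRUE` the rule must hold on
#' every evaluated day from d onwards, guarding against single-day noise
#' crossings.
#'
#' @param curve A `performance_curve` (or data.frame with `day`,
#'   `mean_auc`, `se_auc`).
#' @param band `"final"` or `"candidate"`.
#' @param sustained Require the rule to hold for all subsequent days.
#' @return The day (integer); the final evaluated day always qualifies, so
#'   a day is always returned for a non-empty curve.
#' @export
first_day_within_one_se <- function(curve, band = c("final", "candidate"),
                                    sustained = FALSE) {
  band <- match.arg(band)
  pts <- curve_points(curve)
  if (nrow(pts) == 0L) return(NA_integer_)
  final <- pts[nrow(pts), ]
  margin <- if (band == "final") rep(final$se_auc, nrow(pts)) else pts$se_auc
  ok <- pts$mean_auc >= final$mean_auc - margin
  ok[nrow(pts)] <- TRUE  # the final day trivially qualifies under "final"
  if (sustained) {
    qualifies <- rev(cumprod(rev(ok))) > 0  # ok from here to the end
  } else {
    qualifies <- ok
  }
  pts$day[which(qualifies)[1]]
}

#' Last day with mean AUC below a threshold
#'
#' Identifies the last evaluated day on which the model had not yet
#' reached acceptable accuracy (default threshold AUC 0.70): the largest
#' day d with `mean_auc(d) < threshold`.
#'
#' @param curve A `performance_curve`.
#' @param threshold Acceptability threshold (default 0.70).
#' @return The day, or `NA` if every evaluated day is at or above the
#'   threshold. If no day reaches the threshold this is the final day.
#' @export
last_day_below_threshold <- function(curve, threshold = 0.70) {
  pts <- curve_points(curve)
  below <- pts$day[pts$mean_auc < threshold]
  if (length(below) == 0L) return(NA_integer_)
  max(below)
}

#' Convergence summary for one performance curve
#'
#' A one-row table mirroring the per-model summaries of the temporal
#' analysis: the final day's mean AUC, the first day within one standard
#' error of it (both final-day-SE and candidate-day-SE variants, plus the
#' sustained variant), and the last day below the acceptability threshold.
#'
#' @param curve A `performance_curve`.
#' @param threshold Acceptability threshold (default 0.70).
#' @return A one-row data.frame.
#' @export
convergence_summary <- function(curve, threshold = 0.70) {
  config <- attr(curve, "config")
  pts <- curve_points(curve)
  final <- pts[nrow(pts), ]
  data.frame(
    outcome = if (!is.null(config)) config$outcome else NA_character_,
    algorithm = if (!is.null(config)) config$algorithm else NA_character_,
    predictor_set = if (!is.null(config)) config$predictor_set else NA_character_,
    final_day = final$day,
    final_mean_auc = final$mean_auc,
    final_se_auc = final$se_auc,
    first_day_within_one_se = first_day_within_one_se(curve, band = "final"),
    first_day_within_one_se_candidate =
      first_day_within_one_se(curve, band = "candidate"),
    first_day_within_one_se_sustained =
      first_day_within_one_se(curve, band = "final", sustained = TRUE),
    last_day_below_threshold = last_day_below_threshold(curve, threshold),
    threshold = threshold,
    stringsAsFactors = FALSE
  )
}

#' Tidy table of per-day summaries for a list of curves
#' @param curves Named list of `performance_curve`s.
#' @return A data.frame with config columns plus day, mean_auc, se_auc,
#'   n_estimates.
#' @export
curve_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    config <- attr(cv, "config")
    cbind(data.frame(outcome = config$outcome, algorithm = config$algorithm,
                     predictor_set = config$predictor_set,
                     stringsAsFactors = FALSE),
          as.data.frame(cv))
  }))
}

#' Tidy per-fold AUC estimates for a list of curves
#' @param curves Named list of `performance_curve`s.
#' @return A data.frame: config columns, day, repeat, fold, auc.
#' @export
estimates_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    config <- attr(cv, "config")
    est <- attr(cv, "estimates")
    cbind(data.frame(outcome = config$outcome, algorithm = config$algorithm,
                     predictor_set = config$predictor_set,
                     stringsAsFactors = FALSE),
          est)
  }))
}
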