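# Result serialization, provenance and human-readable reporting for the
# analysis drivers.

#' Write sweep outputs as tidy CSV files
#'
#' Produces the three standard result files: per-fold AUC estimates
#' (`estimates.csv`: config, day, repeat, fold, auc), per-day summaries
#' (`per_day.csv`: config, day, mean_auc, se_auc, n_estimates), and the
#' per-configuration convergence table (`convergence.csv`).
#'
#' @param curves Named list of `performance_curve`s from
#'   [run_temporal_sweep()].
#' @param dir Output directory (created if needed).
#' @param threshold Acceptability threshold for the convergence table.
#' @return `dir`, invisibly.
#' @export
write_sweep_results <- function(curves, dir, threshold = 0.70) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(estimates_table(curves), file.path(dir, "estimates.csv"),
            row.names = FALSE)
  write.csv(curve_table(curves), file.path(dir, "per_day.csv"),
            row.names = FALSE)
  conv <- do.call(rbind, lapply(curves, convergence_summary,
                                threshold = threshold))
  write.csv(conv, file.path(dir, "convergence.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a provenance JSON next to analysis outputs
#'
#' Records the master seed, generator configuration, fold scheme, package
#' version and timestamp so a run can be reproduced exactly.
#'
#' @param path File to write (e.g. `results/provenance.json`).
#' @param master_seed Master seed of the run.
#' @param config Optional [synthetic_config()] used for the cohort.
#' @param extra Optional named list of further settings to record.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, master_seed, config = NULL, extra = NULL) {
  prov <- c(list(master_seed = master_seed,
                 package = "moodcast",
                 package_version = as.character(utils::packageVersion("moodcast")),
                 r_version = as.character(getRversion()),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 cohort_config = if (!is.null(config)) unclass(config)),
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Render a plain-text report of convergence findings
#'
#' Summarizes, per configuration or group: the final mean AUC with its
#' standard error, the first day within one standard error of the final
#' day, and the last day below the acceptability threshold (AUC 0.70 by
#' default). Days that never reached the threshold are reported as such.
#'
#' @param summaries A data.frame from [convergence_summary()] /
#'   [stratified_summary()] rows.
#' @return A character vector of report lines.
#' @export
render_report <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  lines <- c("Temporal prediction of end-of-quarter outcomes",
             sprintf("Acceptable-accuracy threshold: AUC > %.2f",
                     summaries$threshold[1]), "")
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    label <- paste(s$outcome, s$algorithm, s$predictor_set)
    if ("missingness_group" %in% names(s)) {
      label <- paste0(label, " [", s$missingness_group, " missingness, ",
                      s$group_alias, "]")
    }
    thresh_line <- if (is.na(s$last_day_below_threshold)) {
      "at or above threshold on every evaluated day"
    } else if (s$last_day_below_threshold >= s$final_day) {
      "did not meet the threshold during the study period"
    } else {
      sprintf("last day below threshold: day %d", s$last_day_below_threshold)
    }
    lines <- c(lines,
               sprintf("%s", label),
               sprintf("  final day %d mean AUC %.3f (SE %.3f)",
                       s$final_day, s$final_mean_auc, s$final_se_auc),
               sprintf("  first day within 1 SE of final: day %d (sustained: day %d)",
                       s$first_day_within_one_se,
                       s$first_day_within_one_se_sustained),
               sprintf("  %s", thresh_line), "")
  }
  lines
}

#' Plot performance curves with one-standard-error ribbons
#'
#' Mean AUC per day with a +/- 1 SE ribbon per configuration or group.
#' Requires ggplot2.
#'
#' @param curves Named list of `performance_curve`s.
#' @param threshold Horizontal reference line (default 0.70); `NULL` to
#'   omit.
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, threshold = 0.70) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_curves requires ggplot2", call. = FALSE)
  }
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- as.data.frame(curves[[nm]])
    cv$series <- nm
    cv[!is.na(cv$mean_auc), , drop = FALSE]
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$mean_auc,
                                        colour = .data$series,
                                        fill = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_auc - .data$se_auc,
                                      ymax = .data$mean_auc + .data$se_auc),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of quarter", y = "Mean AUC (nested CV)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
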