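#!/usr/bin/env Rscript
# Stage 3: convergence findings for the full-sample curves.
#
# Applies the two day-finding rules to every configuration's AUC curve:
# the one-standard-error rule (first day whose mean AUC is within 1 SE of
# the final day's mean; candidate-band and sustained variants reported
# alongside) and the acceptability rule (last day with mean AUC < 0.70).
# Writes the per-model summary table and a plain-text report, plus curve
# figures when ggplot2 is available.
#
# Usage: Rscript analysis/03_convergence.R

suppressMessages(library(moodcast))

per_day <- read.csv("results/full_sample/per_day.csv")
curves <- lapply(split(per_day, paste(per_day$outcome, per_day$algorithm,
                                      per_day$predictor_set, sep = "_")),
                 function(df) {
                   cv <- df[order(df$day), c("day", "mean_auc", "se_auc",
                                             "n_estimates")]
                   attr(cv, "config") <- model_config(df$outcome[1],
                                                      df$algorithm[1],
                                                      df$predictor_set[1])
                   class(cv) <- c("performance_curve", "data.frame")
                   cv
                 })

summary_tab <- do.call(rbind, lapply(curves, convergence_summary))
write.csv(summary_tab, "results/full_sample/convergence.csv",
          row.names = FALSE)

report <- render_report(summary_tab)
writeLines(report, "results/full_sample/report.txt")
cat(report, sep = "\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  for (oc in c("depression", "si")) {
    sel <- curves[grepl(paste0("^", oc, "_"), names(curves))]
    p <- plot_curves(sel)
    ggplot2::ggsave(sprintf("results/full_sample/curves_%s.pdf", oc), p,
                    width = 8, height = 5)
  }
  message("curve figures written to results/full_sample/")
}
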