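#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a synthetic quarter of daily mood-diary and wearable data for a
# cohort of first-year training physicians: a latent severity trait drives
# lower and more volatile daily mood, heavier missingness (which also decays
# with time in the quarter), and the two end-of-quarter outcomes, calibrated
# to 18.5% depression and 6.8% suicidal-ideation prevalence. Writes the
# cohort as long-format CSVs plus a provenance JSON.
#
# Usage: Rscript analysis/01_simulate.R [n_participants] [master_seed]

suppressMessages(library(moodcast))

argv <- commandArgs(trailingOnly = TRUE)
n <- if (length(argv) >= 1) as.integer(argv[1]) else 600L
master_seed <- if (length(argv) >= 2) as.integer(argv[2]) else 20260920L

# n is scaled to desk runtime; the full-cohort analogue would use 2459
config <- synthetic_config(n_participants = n, seed = master_seed)
cohort <- generate_cohort(config)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
write_provenance("results/cohort/provenance.json", master_seed, config)

message(sprintf("simulated %d participants x %d days -> results/cohort/", n,
                cohort$horizon_days))
message(sprintf("  depression prevalence: %.1f%% (target 18.5%%)",
                100 * mean(cohort$outcomes$depression)))
message(sprintf("  SI prevalence:         %.1f%% (target 6.8%%)",
                100 * mean(cohort$outcomes$si)))
message(sprintf("  day-1 mood missingness %.1f%%, day-%d %.1f%%",
                100 * mean(is.na(cohort$daily$mood[cohort$daily$day == 1])),
                cohort$horizon_days,
                100 * mean(is.na(cohort$daily$mood[cohort$daily$day ==
                                                     cohort$horizon_days]))))
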