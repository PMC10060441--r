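# Shared fixtures, generated in code at test time.

# small default cohort for structural tests
small_cohort <- function(n = 80, horizon = 20, seed = 42, ...) {
  generate_cohort(synthetic_config(n_participants = n, horizon_days = horizon,
                                   seed = seed, ...))
}

# cohort with no severity signal anywhere (effects all zero)
null_cohort <- function(n = 500, horizon = 92, seed = 1) {
  generate_cohort(synthetic_config(
    n_participants = n, horizon_days = horizon,
    mood_effect = 0, mood_volatility_effect = 0,
    missingness_severity_link = 0, outcome_effect = 0,
    adherence_decay = 0, seed = seed
  ))
}

# strong mood signal, wearables pure noise
signal_cohort <- function(n = 800, horizon = 92, seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_participants = n, horizon_days = horizon,
    mood_effect = 1.5, mood_volatility_effect = 0.3,
    outcome_effect = 2.0, wearable_signal = FALSE, seed = seed, ...
  ))
}

# strong-signal cohort whose mood signal is fully expressed by day dstar:
# observed moods after dstar are redrawn from a severity-independent
# distribution (missingness pattern preserved), so the AUC curve plateaus
plateau_cohort <- function(n = 500, seed = 1, dstar = 10, horizon = 30) {
  co <- generate_cohort(synthetic_config(
    n_participants = n, horizon_days = horizon,
    mood_effect = 1.5, mood_volatility_effect = 0,
    missingness_severity_link = 0, outcome_effect = 2.0, seed = seed
  ))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed + 500000)
  obs_late <- co$daily$day > dstar & !is.na(co$daily$mood)
  co$daily$mood[obs_late] <-
    pmin(10L, pmax(1L, as.integer(round(rnorm(sum(obs_late), 7, 1.3)))))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  co
}

# one nested-CV cell with the per-day fold-plan seeding of the sweep
run_cell <- function(cohort, day, config, master_seed) {
  y <- cohort$outcomes[[config$outcome]][order(cohort$outcomes$participant_id)]
  plan <- make_fold_plan(y, seed = moodcast:::derive_seed(master_seed, day))
  suppressWarnings(evaluate_day(cohort, day, config, plan,
                                seed = moodcast:::derive_seed(master_seed, 1)))
}

# hand-built cohort from an explicit mood matrix (days x participants);
# wearables constant and fully observed, outcomes supplied
manual_cohort <- function(mood, depression, si = depression) {
  t_max <- nrow(mood); n <- ncol(mood)
  ids <- sprintf("P%04d", seq_len(n))
  daily <- data.frame(participant_id = rep(ids, each = t_max),
                      day = rep(seq_len(t_max), times = n),
                      mood = as.vector(mood), stringsAsFactors = FALSE)
  for (v in wearable_variables()) daily[[v]] <- 1
  outcomes <- data.frame(participant_id = ids,
                         depression = depression, si = si,
                         latent_severity = 0, stringsAsFactors = FALSE)
  moodcast:::new_cohort(daily, outcomes, t_max)
}

# outcome vector aligned with feature-matrix row order
cohort_labels <- function(cohort, outcome = "depression") {
  oc <- cohort$outcomes[order(cohort$outcomes$participant_id), , drop = FALSE]
  oc[[outcome]]
}
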