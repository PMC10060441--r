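# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: exhaustive pair counting for AUC, per-participant
# loops for summary features, quadrature for the prevalence calibration.

# AUC by exhaustive enumeration of all case-control pairs (ties count 1/2)
brute_force_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) {
    for (b in controls) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(cases) * length(controls))
}

# day-t summary features recomputed one participant-variable at a time
brute_force_features <- function(cohort, t, vars = daily_variables()) {
  ids <- sort(unique(cohort$daily$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (v in vars) {
    m <- s <- pm <- numeric(length(ids))
    for (i in seq_along(ids)) {
      rows <- cohort$daily$participant_id == ids[i] & cohort$daily$day <= t
      vals <- cohort$daily[[v]][rows]
      obs <- vals[!is.na(vals)]
      m[i] <- if (length(obs) >= 2) mean(obs) else NA_real_
      s[i] <- if (length(obs) >= 3) sd(obs) else NA_real_
      pm[i] <- 100 * sum(is.na(vals)) / t
    }
    out[[paste0(v, "_mean")]] <- m
    out[[paste0(v, "_sd")]] <- s
    out[[paste0(v, "_pct_missing")]] <- pm
  }
  out
}

# E[plogis(a + b * U)] for standard-normal U by Gauss-Hermite quadrature
gh_marginal_prevalence <- function(a, b, n_nodes = 80) {
  gh <- pracma::gaussHermite(n_nodes)
  sum(gh$w * plogis(a + b * sqrt(2) * gh$x)) / sqrt(pi)
}

# linear scan implementation of the one-SE rule (final-day band)
scan_first_day_within_one_se <- function(days, means, ses) {
  target <- means[length(means)] - ses[length(ses)]
  for (i in seq_along(days)) {
    if (means[i] >= target) return(days[i])
  }
  days[length(days)]
}

scan_last_day_below <- function(days, means, threshold) {
  hit <- NA_integer_
  for (i in seq_along(days)) {
    if (means[i] < threshold) hit <- days[i]
  }
  hit
}
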