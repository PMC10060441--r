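# Synthetic cohort generator: daily mood + wearable streams with latent
# severity, informative time-decaying missingness, and calibrated binary
# outcome prevalences.

#' Names of the ten daily wearable variables
#'
#' Daily Fitbit-style metrics: total sleep (minutes), sleep start and end
#' times (minutes from midnight), sleep efficiency (percent), total steps,
#' four activity-intensity minute counts, and resting heart rate (bpm).
#'
#' @return Character vector of length 10.
#' @export
wearable_variables <- function() {
  c("total_sleep", "sleep_start", "sleep_end", "sleep_efficiency",
    "total_steps", "sedentary_min", "lightly_active_min",
    "fairly_active_min", "very_active_min", "resting_hr")
}

#' All daily variables (mood first, then wearables)
#' @return Character vector of length 11.
#' @export
daily_variables <- function() c("mood", wearable_variables())

# Plausible population-level parameters for each wearable stream:
# person-level mean, between-person SD, within-person day SD, hard range,
# and the shift (in variable units per SD of latent severity) applied in
# informative mode. Sleep times are minutes from midnight (sleep_start of
# 1410 = 23:30 the previous evening is encoded as 1410, i.e. not wrapped).
wearable_params <- function() {
  list(
    total_sleep        = list(mu = 420,  bsd = 45,  wsd = 55,  lo = 0,   hi = 960,  shift = -20),
    sleep_start        = list(mu = 1410, bsd = 50,  wsd = 45,  lo = 0,   hi = 1900, shift = 15),
    sleep_end          = list(mu = 390,  bsd = 40,  wsd = 40,  lo = 0,   hi = 900,  shift = 10),
    sleep_efficiency   = list(mu = 92,   bsd = 3,   wsd = 3,   lo = 0,   hi = 100,  shift = -1.5),
    total_steps        = list(mu = 8000, bsd = 2200, wsd = 2600, lo = 0, hi = 40000, shift = -800),
    sedentary_min      = list(mu = 600,  bsd = 90,  wsd = 80,  lo = 0,   hi = 1440, shift = 40),
    lightly_active_min = list(mu = 180,  bsd = 45,  wsd = 45,  lo = 0,   hi = 900,  shift = -15),
    fairly_active_min  = list(mu = 30,   bsd = 12,  wsd = 14,  lo = 0,   hi = 400,  shift = -4),
    very_active_min    = list(mu = 25,   bsd = 12,  wsd = 13,  lo = 0,   hi = 400,  shift = -4),
    resting_hr         = list(mu = 65,   bsd = 6,   wsd = 2.5, lo = 30,  hi = 140,  shift = 1.5)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for a cohort of participants observed daily
#' over a quarter. A standard-normal latent severity `u` per person drives
#' (i) lower mean daily mood (`mood_effect`, in mood points per SD of
#' severity), (ii) larger day-to-day mood variability
#' (`mood_volatility_effect`, log-SD units per SD), (iii) higher missingness
#' (`missingness_severity_link`, log-odds per SD), and (iv) higher outcome
#' risk (`outcome_effect`, log-odds per SD). Missingness also rises over
#' time by `adherence_decay` log-odds per day, emulating adherence decay.
#' Outcome intercepts are calibrated with [calibrate_prevalence()] so that
#' marginal prevalences hit the targets (defaults 18.5% depression, 6.8%
#' suicidal ideation, the follow-up rates observed in cohorts of first-year
#' training physicians).
#'
#' @param n_participants Number of participants.
#' @param horizon_days Days in the observation window (default 92, one
#'   quarter).
#' @param mood_effect Drop in mean daily mood per SD of latent severity.
#' @param mood_volatility_effect Increase in log within-person mood SD per
#'   SD of severity.
#' @param mood_baseline_mean,mood_baseline_sd Population mean and SD of the
#'   person-level mood baseline (1-10 scale).
#' @param mood_day_sd Within-person daily mood noise SD at severity 0.
#' @param missingness_base Day-1 mood missingness probability at severity 0.
#' @param wearable_missingness_base As above for each wearable variable
#'   (device non-wear / sync failure); shares the person/day propensity
#'   terms with mood but has its own base rate.
#' @param adherence_decay Per-day increase in missingness log-odds (>= 0).
#' @param missingness_severity_link Missingness log-odds per SD of severity.
#' @param depression_prevalence_target,si_prevalence_target Target marginal
#'   outcome prevalences, strictly inside (0, 1).
#' @param outcome_effect Outcome log-odds per SD of latent severity (applies
#'   to both outcomes).
#' @param wearable_signal If `TRUE`, wearable person-level means shift with
#'   severity; if `FALSE` (default) the wearable streams are pure noise with
#'   respect to the outcomes, matching the finding that passive-sensing
#'   features added noise rather than signal.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   cohort.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_participants = 2459,
                             horizon_days = 92,
                             mood_effect = 0.9,
                             mood_volatility_effect = 0.25,
                             mood_baseline_mean = 7,
                             mood_baseline_sd = 0.9,
                             mood_day_sd = 1.3,
                             missingness_base = 0.15,
                             wearable_missingness_base = 0.25,
                             adherence_decay = 0.02,
                             missingness_severity_link = 0.35,
                             depression_prevalence_target = 0.185,
                             si_prevalence_target = 0.068,
                             outcome_effect = 1.2,
                             wearable_signal = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    horizon_days = as.integer(horizon_days),
    mood_effect = mood_effect,
    mood_volatility_effect = mood_volatility_effect,
    mood_baseline_mean = mood_baseline_mean,
    mood_baseline_sd = mood_baseline_sd,
    mood_day_sd = mood_day_sd,
    missingness_base = missingness_base,
    wearable_missingness_base = wearable_missingness_base,
    adherence_decay = adherence_decay,
    missingness_severity_link = missingness_severity_link,
    depression_prevalence_target = depression_prevalence_target,
    si_prevalence_target = si_prevalence_target,
    outcome_effect = outcome_effect,
    wearable_signal = isTRUE(wearable_signal),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  num_fields <- c("mood_effect", "mood_volatility_effect",
                  "mood_baseline_mean", "mood_baseline_sd", "mood_day_sd",
                  "missingness_base", "wearable_missingness_base",
                  "adherence_decay", "missingness_severity_link",
                  "depression_prevalence_target", "si_prevalence_target",
                  "outcome_effect")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("synthetic_config: field '", f, "' must be a finite number",
           call. = FALSE)
    }
  }
  if (cfg$n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  if (cfg$horizon_days < 1L) stop("horizon_days must be >= 1", call. = FALSE)
  for (f in c("missingness_base", "wearable_missingness_base")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("synthetic_config: field '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$adherence_decay < 0) stop("adherence_decay must be >= 0", call. = FALSE)
  for (f in c("depression_prevalence_target", "si_prevalence_target")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) {
      stop("synthetic_config: field '", f,
           "' must lie strictly inside (0, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Calibrate an outcome intercept to a target marginal prevalence
#'
#' Finds the intercept `a` such that `E[plogis(a + b * U)] = target` for
#' standard-normal `U`, by numerical integration of the logistic-normal
#' marginal and root bracketing. Used so the generator's Bernoulli outcomes
#' hit their target prevalences regardless of the severity effect size.
#'
#' @param target Target prevalence, strictly inside (0, 1).
#' @param severity_effect Outcome log-odds per SD of latent severity (`b`).
#' @param tol Accuracy of the calibrated marginal prevalence (default 1e-6).
#' @return The intercept (a single number). With `severity_effect = 0` this
#'   is exactly `qlogis(target)`.
#' @export
calibrate_prevalence <- function(target, severity_effect, tol = 1e-6) {
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0 || target >= 1) {
    stop("calibrate_prevalence: target must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (!is.finite(severity_effect)) {
    stop("calibrate_prevalence: severity_effect must be finite", call. = FALSE)
  }
  if (severity_effect == 0) return(qlogis(target))
  marginal <- function(a) {
    integrate(function(u) plogis(a + severity_effect * u) * stats::dnorm(u),
              lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }
  # the marginal is strictly increasing in a; bracket widely
  lo <- qlogis(target) - abs(severity_effect) * 8 - 2
  hi <- qlogis(target) + abs(severity_effect) * 8 + 2
  root <- uniroot(function(a) marginal(a) - target, lower = lo, upper = hi,
                  tol = 1e-10, maxiter = 200)
  a <- root$root
  if (abs(marginal(a) - target) > max(tol, 1e-4)) {
    stop("calibrate_prevalence: failed to reach target within tolerance",
         call. = FALSE)
  }
  a
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from the generative model described in
#' [synthetic_config()]. The result holds a long-format daily table (one
#' row per participant-day, `NA` = missing observation), an outcomes table
#' with the two binary labels and the latent severity truth channel
#' (retained for recovery tests only, never entering any feature path),
#' and the generating configuration.
#'
#' Wearable streams are person-level means plus AR(1) daily deviations
#' (autocorrelation 0.3), clamped to plausible ranges; in informative mode
#' the person-level means shift linearly with latent severity.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `cohort`: a list with elements `daily`
#'   (data.frame: participant_id, day, mood, ten wearable columns),
#'   `outcomes` (data.frame: participant_id, depression, si,
#'   latent_severity), `horizon_days`, and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  n <- config$n_participants
  t_max <- config$horizon_days

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  u <- rnorm(n)
  ids <- sprintf("P%04d", seq_len(n))

  # daily mood: person baseline minus severity effect, noise SD increasing
  # in severity, rounded and clamped to the 1-10 integer scale
  baseline <- rnorm(n, config$mood_baseline_mean, config$mood_baseline_sd)
  mood_mu <- baseline - config$mood_effect * u
  mood_sd <- config$mood_day_sd * exp(config$mood_volatility_effect * u)
  mood <- matrix(rnorm(n * t_max, mean = rep(mood_mu, each = t_max),
                       sd = rep(mood_sd, each = t_max)),
                 nrow = t_max, ncol = n)
  mood <- pmin(10L, pmax(1L, as.integer(round(mood))))

  # missingness: logistic in day (adherence decay) and severity, applied
  # independently per variable-day; mood and wearables share the person and
  # day terms but have separate base rates
  day_term <- config$adherence_decay * (seq_len(t_max) - 1)
  sev_term <- config$missingness_severity_link * u
  lin <- outer(day_term, sev_term, "+")  # t_max x n
  p_miss_mood <- plogis(qlogis(clamp01(config$missingness_base)) + lin)
  p_miss_wear <- plogis(qlogis(clamp01(config$wearable_missingness_base)) + lin)
  mood[matrix(stats::runif(n * t_max), t_max, n) < p_miss_mood] <- NA

  wp <- wearable_params()
  wear <- vector("list", length(wp))
  names(wear) <- names(wp)
  phi <- 0.3  # daily AR(1) autocorrelation, shared across streams
  for (v in names(wp)) {
    p <- wp[[v]]
    pm <- p$mu + p$bsd * rnorm(n)
    if (config$wearable_signal) pm <- pm + p$shift * u
    innov <- matrix(rnorm(n * t_max), t_max, n)
    dev <- matrix(0, t_max, n)
    dev[1, ] <- innov[1, ]
    for (d in seq_len(t_max)[-1]) {
      dev[d, ] <- phi * dev[d - 1, ] + sqrt(1 - phi^2) * innov[d, ]
    }
    x <- sweep(dev * p$wsd, 2, pm, "+")
    x <- pmin(p$hi, pmax(p$lo, x))
    x[matrix(stats::runif(n * t_max), t_max, n) < p_miss_wear] <- NA
    wear[[v]] <- x
  }

  a_dep <- calibrate_prevalence(config$depression_prevalence_target,
                                config$outcome_effect)
  a_si <- calibrate_prevalence(config$si_prevalence_target,
                               config$outcome_effect)
  depression <- rbinom(n, 1L, plogis(a_dep + config$outcome_effect * u))
  si <- rbinom(n, 1L, plogis(a_si + config$outcome_effect * u))

  daily <- data.frame(
    participant_id = rep(ids, each = t_max),
    day = rep(seq_len(t_max), times = n),
    mood = as.vector(mood),
    stringsAsFactors = FALSE
  )
  for (v in names(wear)) daily[[v]] <- as.vector(wear[[v]])

  outcomes <- data.frame(
    participant_id = ids,
    depression = as.integer(depression),
    si = as.integer(si),
    latent_severity = u,
    stringsAsFactors = FALSE
  )

  new_cohort(daily, outcomes, t_max, config)
}

clamp01 <- function(p) min(1 - 1e-12, max(1e-12, p))

new_cohort <- function(daily, outcomes, horizon_days, config = NULL) {
  structure(
    list(daily = daily, outcomes = outcomes,
         horizon_days = as.integer(horizon_days), config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$outcomes)
  cat("Synthetic daily-diary cohort\n")
  cat("  participants:", n, " horizon:", x$horizon_days, "days\n")
  cat(sprintf("  depression prevalence: %.3f   SI prevalence: %.3f\n",
              mean(x$outcomes$depression), mean(x$outcomes$si)))
  cat(sprintf("  overall mood missingness: %.1f%%\n",
              100 * mean(is.na(x$daily$mood))))
  invisible(x)
}

#' Restrict a cohort to a subset of participants
#'
#' @param cohort A `cohort`.
#' @param ids Character vector of participant ids to keep.
#' @return A `cohort` containing only those participants.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"))
  keep <- cohort$outcomes$participant_id %in% ids
  if (!any(keep)) stop("subset_cohort: no matching participants", call. = FALSE)
  new_cohort(
    daily = cohort$daily[cohort$daily$participant_id %in% ids, , drop = FALSE],
    outcomes = cohort$outcomes[keep, , drop = FALSE],
    horizon_days = cohort$horizon_days,
    config = cohort$config
  )
}

#' Write a cohort to plain-text files
#'
#' Writes `daily.csv` (long format, one row per participant-day, empty
#' field = missing) and `outcomes.csv` (one row per participant) into a
#' directory. Numeric values are written with 17 significant digits so that
#' a read/write round trip is exact.
#'
#' @param cohort A `cohort`.
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  fmt <- function(df) {
    for (cl in names(df)) {
      if (is.double(df[[cl]])) {
        x <- formatC(df[[cl]], format = "g", digits = 17)
        x[is.na(df[[cl]])] <- NA
        df[[cl]] <- x
      }
    }
    df
  }
  write.csv(fmt(cohort$daily), file.path(path, "daily.csv"),
            row.names = FALSE, na = "")
  out <- cohort$outcomes
  write.csv(fmt(out), file.path(path, "outcomes.csv"),
            row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from plain-text files
#'
#' Counterpart of [write_cohort()]. Validates the long table: every
#' participant must have exactly one row per day 1..horizon, days in range,
#' no duplicate participant-day keys; offending rows are named in errors.
#'
#' @param path Directory containing `daily.csv` and `outcomes.csv`.
#' @return A `cohort`.
#' @export
read_cohort <- function(path) {
  daily_file <- file.path(path, "daily.csv")
  out_file <- file.path(path, "outcomes.csv")
  for (f in c(daily_file, out_file)) {
    if (!file.exists(f)) stop("read_cohort: missing file ", f, call. = FALSE)
  }
  daily <- read.csv(daily_file, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
  outcomes <- read.csv(out_file, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  need <- c("participant_id", "day", daily_variables())
  missing_cols <- setdiff(need, names(daily))
  if (length(missing_cols)) {
    stop("read_cohort: daily.csv lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  horizon <- max(daily$day)
  bad <- which(daily$day < 1 | daily$day > horizon | daily$day != round(daily$day))
  if (length(bad)) {
    stop("read_cohort: day out of range at daily.csv row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(daily$participant_id, daily$day)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("read_cohort: duplicate participant-day key at daily.csv row(s) ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  counts <- table(daily$participant_id)
  if (any(counts != horizon)) {
    off <- names(counts)[counts != horizon][1]
    stop("read_cohort: participant ", off, " has ", counts[[off]],
         " rows, expected ", horizon, call. = FALSE)
  }
  if (!setequal(outcomes$participant_id, unique(daily$participant_id))) {
    stop("read_cohort: outcomes.csv and daily.csv participant sets differ",
         call. = FALSE)
  }
  daily <- daily[order(daily$participant_id, daily$day), , drop = FALSE]
  outcomes <- outcomes[order(outcomes$participant_id), , drop = FALSE]
  rownames(daily) <- NULL
  rownames(outcomes) <- NULL
  new_cohort(daily, outcomes, horizon)
}
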