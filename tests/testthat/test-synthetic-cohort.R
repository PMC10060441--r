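# Synthetic cohort generator: calibration, determinism, missingness
# structure, outcome prevalences, and plain-text round trips.

test_that("prevalence calibration matches quadrature and closed forms", {
  # no severity effect: closed-form logit
  expect_equal(calibrate_prevalence(0.5, 0), 0)
  expect_equal(calibrate_prevalence(0.068, 0), qlogis(0.068))

  # with severity effect: marginal prevalence must hit the target;
  # cross-checked against an independent Gauss-Hermite quadrature oracle
  skip_if_not_installed("pracma")
  for (case in list(c(0.185, 1), c(0.068, 1.2), c(0.5, 2), c(0.9, 0.7))) {
    a <- calibrate_prevalence(case[1], case[2])
    expect_equal(gh_marginal_prevalence(a, case[2]), case[1],
                 tolerance = 1e-4)
  }
  # intercept itself matches root-finding against the quadrature oracle
  a_impl <- calibrate_prevalence(0.185, 1)
  a_oracle <- uniroot(function(a) gh_marginal_prevalence(a, 1) - 0.185,
                      c(-10, 10), tol = 1e-12)$root
  expect_equal(a_impl, a_oracle, tolerance = 1e-4)
})

test_that("calibration rejects degenerate targets and non-finite effects", {
  expect_error(calibrate_prevalence(0, 1), "strictly inside")
  expect_error(calibrate_prevalence(1, 1), "strictly inside")
  expect_error(calibrate_prevalence(0.2, NaN), "finite")
  expect_error(synthetic_config(depression_prevalence_target = 0),
               "strictly inside")
  expect_error(synthetic_config(mood_effect = Inf), "finite")
  expect_error(synthetic_config(missingness_base = 1.2), "\\[0, 1\\]")
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- synthetic_config(n_participants = 40, horizon_days = 15, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$daily, c2$daily)
  expect_identical(c1$outcomes, c2$outcomes)
  # a different seed changes the draw
  c3 <- generate_cohort(synthetic_config(n_participants = 40,
                                         horizon_days = 15, seed = 100))
  expect_false(identical(c1$daily, c3$daily))
})

test_that("cohort has the contracted shape and value ranges", {
  co <- small_cohort(n = 50, horizon = 30)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$daily), 50 * 30)
  expect_equal(sort(unique(co$daily$day)), 1:30)
  expect_equal(length(unique(co$daily$participant_id)), 50)
  # every participant has exactly one row per day
  expect_true(all(table(co$daily$participant_id) == 30))
  m <- co$daily$mood[!is.na(co$daily$mood)]
  expect_true(all(m == round(m) & m >= 1 & m <= 10))
  eff <- co$daily$sleep_efficiency
  expect_true(all(eff[!is.na(eff)] >= 0 & eff[!is.na(eff)] <= 100))
  for (v in wearable_variables()) {
    expect_true(all(co$daily[[v]][!is.na(co$daily[[v]])] >= 0), info = v)
  }
  expect_setequal(names(co$outcomes),
                  c("participant_id", "depression", "si", "latent_severity"))
  expect_true(all(co$outcomes$depression %in% 0:1))
  expect_true(all(co$outcomes$si %in% 0:1))
})

test_that("empirical prevalences hit their calibrated targets", {
  co <- generate_cohort(synthetic_config(n_participants = 5000, seed = 11))
  expect_equal(mean(co$outcomes$depression), 0.185, tolerance = 0.02 / 0.185)
  expect_equal(mean(co$outcomes$si), 0.068, tolerance = 0.02 / 0.068)
})

test_that("with all effects zero, person-mean mood is uncorrelated with outcomes", {
  co <- null_cohort(n = 2000, horizon = 30, seed = 5)
  f <- build_feature_matrix(co, 30, "mood_only")
  y <- cohort_labels(co, "depression")
  ok <- !is.na(f$mood_mean)
  r <- cor(f$mood_mean[ok], y[ok])
  expect_lt(abs(r), 0.06)  # ~2.7 SDs of the null correlation at this n
})

test_that("missingness rate is non-decreasing in day under adherence decay", {
  co <- generate_cohort(synthetic_config(n_participants = 2000,
                                         horizon_days = 60,
                                         adherence_decay = 0.03, seed = 8))
  rate <- tapply(is.na(co$daily$mood), co$daily$day, mean)
  # compare weekly bins to absorb Monte-Carlo noise
  bins <- tapply(rate, rep(1:10, each = 6), mean)
  expect_true(all(diff(bins) > -0.01))
  expect_gt(bins[10], bins[1])
})

test_that("cases miss more mood prompts than non-cases when severity drives both", {
  co <- generate_cohort(synthetic_config(n_participants = 2000,
                                         missingness_severity_link = 0.5,
                                         outcome_effect = 1.5, seed = 13))
  f <- build_feature_matrix(co, co$horizon_days, "mood_only")
  y <- cohort_labels(co, "depression")
  expect_gt(mean(f$mood_pct_missing[y == 1]), mean(f$mood_pct_missing[y == 0]))
})

test_that("latent severity drives mood level and volatility in the stated directions", {
  co <- generate_cohort(synthetic_config(n_participants = 1500,
                                         mood_effect = 1,
                                         mood_volatility_effect = 0.4,
                                         missingness_base = 0, adherence_decay = 0,
                                         missingness_severity_link = 0, seed = 21))
  f <- build_feature_matrix(co, co$horizon_days, "mood_only")
  u <- co$outcomes$latent_severity[order(co$outcomes$participant_id)]
  expect_lt(cor(f$mood_mean, u), -0.5)   # higher severity -> lower mood
  expect_gt(cor(f$mood_sd, u), 0.3)      # higher severity -> more volatile
})

test_that("wearable streams track severity only in informative mode", {
  base <- list(n_participants = 1200, horizon_days = 30,
               wearable_missingness_base = 0, adherence_decay = 0,
               missingness_severity_link = 0)
  for (sig in c(FALSE, TRUE)) {
    co <- generate_cohort(do.call(synthetic_config,
                                  c(base, list(wearable_signal = sig, seed = 3))))
    f <- build_feature_matrix(co, 30)
    u <- co$outcomes$latent_severity[order(co$outcomes$participant_id)]
    r <- cor(f$total_sleep_mean, u)
    if (sig) expect_lt(r, -0.2) else expect_lt(abs(r), 0.08)
  }
})

test_that("cohorts round-trip exactly through the plain-text format", {
  co <- small_cohort(n = 15, horizon = 8, seed = 77)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$daily$mood, co$daily$mood)
  expect_equal(back$daily, co$daily, tolerance = 0)
  expect_equal(back$outcomes, co$outcomes, tolerance = 0)
  expect_identical(back$horizon_days, co$horizon_days)
})

test_that("malformed cohort files are rejected with named rows", {
  co <- small_cohort(n = 6, horizon = 5, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  daily <- read.csv(file.path(dir, "daily.csv"),
                    colClasses = c(participant_id = "character"))

  dup <- rbind(daily, daily[3, ])
  write.csv(dup, file.path(dir, "daily.csv"), row.names = FALSE, na = "")
  expect_error(read_cohort(dir), "duplicate participant-day")

  bad <- daily
  bad$day[4] <- -2
  write.csv(bad, file.path(dir, "daily.csv"), row.names = FALSE, na = "")
  expect_error(read_cohort(dir), "day out of range")

  short <- daily[-1, ]
  write.csv(short, file.path(dir, "daily.csv"), row.names = FALSE, na = "")
  expect_error(read_cohort(dir), "expected 5")
})
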