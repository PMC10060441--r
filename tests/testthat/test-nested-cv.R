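# Nested cross-validation: fold plans, the Mann-Whitney AUC, inner tuning
# tie-breaks, the 15-estimate contract with its conservative standard
# error, and leakage checks.

test_that("AUC matches exhaustive pair counting on random vectors", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.3, 0.7, 0.5, 0.6), c(0, 1, 0, 1)),
               brute_force_auc(c(0.3, 0.7, 0.5, 0.6), c(0, 1, 0, 1)))
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    scores <- sample(round(runif(n), 2))  # rounded to force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auc(scores, labels), brute_force_auc(scores, labels))
  }
  expect_error(auc(1:4, rep(1, 4)), "single-class")
})

test_that("fold plans stratify, partition, and are reproducible", {
  labels <- rep(c(1, 0), c(20, 80))
  plan <- make_fold_plan(labels, k = 5, repeats = 3, inner_k = 3, seed = 12)
  for (r in 1:3) {
    folds <- plan$outer[[r]]
    expect_equal(sort(unlist(folds)), 1:100)           # partition law
    expect_equal(lengths(folds), rep(20L, 5))          # balanced sizes
    expect_equal(vapply(folds, function(f) sum(labels[f]), numeric(1)),
                 rep(4, 5))                            # perfect stratification
    for (f in 1:5) {
      inner <- plan$inner[[r]][[f]]
      # inner folds cover exactly the outer training set, disjointly
      expect_equal(sort(unlist(inner)), sort(setdiff(1:100, folds[[f]])))
    }
  }
  expect_identical(make_fold_plan(labels, seed = 12), plan)
  expect_false(identical(make_fold_plan(labels, seed = 13)$outer, plan$outer))
})

test_that("fold stratification keeps case counts within 1 of proportional", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.08, 0.4))
    if (sum(labels) < 5) next
    plan <- make_fold_plan(labels, seed = i)
    for (r in 1:3) {
      cases <- vapply(plan$outer[[r]], function(f) sum(labels[f]), numeric(1))
      expect_lte(max(cases) - min(cases), 1)
    }
  }
})

test_that("undersized or case-poor cohorts are rejected with advice", {
  expect_error(make_fold_plan(rep(c(1, 0), c(3, 60))), "cases")
  expect_error(make_fold_plan(rep(c(1, 0), 4), k = 5), "2k")
})

test_that("inner tuning returns the singleton and breaks ties toward regularization", {
  co <- small_cohort(n = 100, horizon = 10, seed = 15)
  features <- build_feature_matrix(co, 8, "mood_only")
  y <- cohort_labels(co)
  plan <- make_fold_plan(y, seed = 2)
  inner <- plan$inner[[1]][[1]]
  train_idx <- sort(unlist(inner))

  single <- data.frame(penalty = 0.3, mixture = 0.5)
  got <- inner_tune(features, y, train_idx, inner, "ENR", grid = single)
  expect_equal(got$best, single)

  # two settings shrinking everything to zero give identical (tied) inner
  # AUCs; the larger penalty must win
  tied <- data.frame(penalty = c(1e3, 1e4), mixture = 1)
  got <- inner_tune(features, y, train_idx, inner, "ENR", grid = tied)
  expect_equal(got$mean_auc[1], got$mean_auc[2])
  expect_equal(got$best$penalty, 1e4)
})

test_that("a planted signal makes the low-penalty setting win the grid", {
  # one strongly informative feature; a penalty large enough to zero it
  # must lose the inner tournament to the permissive setting
  set.seed(18)
  n <- 150
  mood <- matrix(round(pmin(10, pmax(1, 6 - 3 * rep(rbinom(n, 1, 0.5), each = 10) +
                                       rnorm(10 * n, sd = 0.4)))), nrow = 10)
  y <- as.integer(mood[1, ] < 4)
  co <- manual_cohort(mood, depression = y)
  features <- build_feature_matrix(co, 10, "mood_only")
  plan <- make_fold_plan(y, seed = 3)
  inner <- plan$inner[[1]][[1]]
  train_idx <- sort(unlist(inner))
  grid <- data.frame(penalty = c(1e-5, 1e3), mixture = 1)
  got <- inner_tune(features, y, train_idx, inner, "ENR", grid = grid)
  expect_gt(got$mean_auc[1], got$mean_auc[2])
  expect_equal(got$best$penalty, 1e-5)
})

test_that("evaluate_day returns 15 estimates with the conservative SE", {
  co <- small_cohort(n = 120, horizon = 15, seed = 19)
  y <- cohort_labels(co)
  plan <- make_fold_plan(y, seed = 4)
  perf <- evaluate_day(co, 10, model_config("depression", "ENR", "mood_only"),
                       plan)
  expect_s3_class(perf, "day_performance")
  expect_equal(perf$n_estimates, 15)
  expect_equal(nrow(perf$auc_estimates), 15)
  expect_true(all(perf$auc_estimates$auc >= 0 & perf$auc_estimates$auc <= 1))
  # SE contract: sample SD of the estimates over sqrt(k = 5), not sqrt(15)
  expect_equal(perf$se_auc, sd(perf$auc_estimates$auc) / sqrt(5),
               tolerance = 1e-12)
  expect_equal(perf$mean_auc, mean(perf$auc_estimates$auc), tolerance = 1e-12)
})

test_that("evaluate_day is deterministic for both algorithms", {
  co <- small_cohort(n = 90, horizon = 8, seed = 23)
  y <- cohort_labels(co)
  plan <- make_fold_plan(y, seed = 5)
  for (alg in c("ENR", "RF")) {
    cfg <- model_config("depression", alg, "mood_only")
    p1 <- evaluate_day(co, 6, cfg, plan, seed = 7)
    p2 <- evaluate_day(co, 6, cfg, plan, seed = 7)
    expect_identical(p1$auc_estimates, p2$auc_estimates, label = alg)
  }
})

test_that("no participant is in both train and test, and test rows cannot leak", {
  co <- small_cohort(n = 100, horizon = 10, seed = 29)
  y <- cohort_labels(co)
  plan <- make_fold_plan(y, seed = 6)
  for (r in 1:3) {
    for (f in 1:5) {
      test_idx <- plan$outer[[r]][[f]]
      inner <- unlist(plan$inner[[r]][[f]])
      expect_length(intersect(test_idx, inner), 0)
    }
  }

  # perturbing outer-test rows must not change the fitted imputation
  # medians or the tuned hyperparameters for that split
  features <- build_feature_matrix(co, 8, "mood_only")
  test_idx <- plan$outer[[1]][[1]]
  train_idx <- setdiff(seq_along(y), test_idx)
  tampered <- features
  tampered[test_idx, c("mood_mean", "mood_sd")] <- 99

  imp1 <- fit_imputation(features[train_idx, , drop = FALSE])
  imp2 <- fit_imputation(tampered[train_idx, , drop = FALSE])
  expect_identical(imp1, imp2)

  tune1 <- inner_tune(features, y, train_idx, plan$inner[[1]][[1]], "ENR")
  tune2 <- inner_tune(tampered, y, train_idx, plan$inner[[1]][[1]], "ENR")
  expect_identical(tune1$best, tune2$best)
  expect_identical(tune1$mean_auc, tune2$mean_auc)
})

test_that("degenerate outer test folds are dropped and counted", {
  # 5 cases in 60: with k = 5 each fold gets exactly 1 case, so forcing one
  # fold single-class requires a tampered plan
  co <- small_cohort(n = 60, horizon = 8, seed = 31)
  y <- cohort_labels(co)
  plan <- make_fold_plan(y, seed = 8)
  # move all cases out of repeat 1 fold 1's test set
  f1 <- plan$outer[[1]][[1]]
  cases_in_f1 <- f1[y[f1] == 1]
  f2 <- plan$outer[[1]][[2]]
  controls_in_f2 <- f2[y[f2] == 0][seq_along(cases_in_f1)]
  plan$outer[[1]][[1]] <- sort(c(setdiff(f1, cases_in_f1), controls_in_f2))
  plan$outer[[1]][[2]] <- sort(c(setdiff(f2, controls_in_f2), cases_in_f1))
  expect_warning(
    perf <- evaluate_day(co, 6, model_config("depression", "ENR", "mood_only"),
                         plan),
    "degenerate"
  )
  expect_equal(perf$n_estimates, 14)
  expect_equal(perf$n_dropped, 1L)
})
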