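---
title: "How soon can daily diaries predict quarter-end depression? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How soon can daily diaries predict quarter-end depression? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcast)
```

## The question and the procedure

Intensive longitudinal studies collect a daily self-report (here a single
1–10 mood item) and passive wearable streams (sleep, activity, resting
heart rate) for months, then relate them to a distal outcome — here binary
depression (PHQ-9 ≥ 10) and suicidal ideation (any endorsement of PHQ-9
item 9) at the end of a 92-day quarter. Longer collection means better
features but heavier participant burden and more drop-out, so the central
question is temporal: *on what day t does a model trained on days 1..t
become as accurate as the model trained on the full quarter?*

The pipeline answers it by brute force. For every evaluated day t:

1. **Accumulate features.** For each of the 11 daily variables (mood plus
   10 wearable metrics), compute the mean, sample standard deviation and
   percent missing over days 1..t — 33 features in the full set, 3 in the
   mood-only set. A mean requires at least 2 observed days and an SD at
   least 3; below that the statistic is carried as an explicit
   not-available sentinel. Percent missing is always computable and is
   itself a predictor: adherence carries signal.
2. **Estimate out-of-sample AUC by nested cross-validation.** The outer
   loop is 3 independent stratified 5-fold splits (15 train/test cells).
   Inside each outer training set, a 3-fold inner loop tunes the
   hyperparameters over a 3×3 grid; the winning setting is refit on the
   full outer training set and scored on the held-out fold. Not-available
   features are imputed with the *training-fold* median at every level of
   the nest, so no information flows from validation or test rows.
3. **Summarize.** The 15 outer AUCs give the day's mean and a standard
   error computed as `sd(estimates)/sqrt(5)`. Using k = 5 rather than the
   15 total estimates in the denominator is deliberate conservatism:
   repeats reuse the same participants, so the 15 estimates are far from
   independent.

Two day-finding rules are then applied to each per-day curve. The
**one-standard-error rule** reports the first day whose mean AUC is within
one SE of the final day's mean; the **acceptability rule** reports the last
day whose mean AUC sits below 0.70, the conventional floor for acceptable
discrimination. Finally, because adherence varies enormously across
people, the whole analysis is repeated within missingness strata that are
recomputed every day from each participant's mood response rate to date.

## The classifiers and their grids

Two algorithms are compared deliberately at the ends of the complexity
spectrum:

* **ENR** — logistic regression with the elastic-net penalty
  `penalty · (mixture·‖β‖₁ + (1−mixture)/2·‖β‖₂²)`, fit by glmnet with
  features standardized to training mean/variance. The grid crosses
  penalty ∈ {1e−10, 1e−5, 1} (three log-uniform levels spanning
  effectively-unpenalized to fully-shrunk) with mixture ∈ {0, ½, 1}
  (ridge, even blend, lasso).
* **RF** — a 100-tree probability forest with Gini-impurity splits
  (ranger). The grid crosses `mtry` (three evenly spaced integers over
  [1, p], so {1, 2, 3} for the mood-only set and {1, 17, 33} for the full
  set) with minimum node size {2, 21, 40}.

Inner-loop ties are broken toward the stronger regularization (larger
penalty, then larger mixture; larger node size, then smaller `mtry`):
when two settings cannot be distinguished on tuning AUC, the simpler
model is preferred. A note on naming: part of the literature for this
design swaps the Greek letters for the two ENR hyperparameters relative
to the glmnet convention, so this package avoids both and says `penalty`
and `mixture` throughout.

## The synthetic cohort generator

No public dataset pairs daily mood diaries, consumer-wearable streams and
quarter-end PHQ-9 outcomes at cohort scale, so the package ships a
generator whose defaults encode the study conditions the pipeline is
designed for, and every claim the test suite makes is a claim about these
synthetic cohorts.

A standard-normal latent severity `u` per person is the single source of
signal. It drives:

* **mood level**: daily mood is `round(clamp(baseline − mood_effect·u +
  noise))` on the 1–10 integer scale, with person baselines ~ N(7, 0.9)
  and day noise SD `1.3 · exp(mood_volatility_effect · u)` — severer
  people report lower *and more volatile* mood;
* **missingness**: each variable-day is masked independently with
  probability `logistic(logit(base) + adherence_decay·(day−1) +
  missingness_severity_link·u)`. Defaults (base 0.15 for mood, 0.25 for
  wearables; decay 0.02/day; severity link 0.35) give the qualitative
  pattern reported across EMA studies — adherence decays over the quarter
  and drop-out is heavier among the more symptomatic;
* **outcomes**: Bernoulli with logit `a + outcome_effect·u`, where the
  intercept `a` is calibrated by numerically solving
  `E[logistic(a + b·U)] = target` so the marginal prevalences hit their
  targets (defaults 18.5% depression, 6.8% SI — the follow-up rates in
  large cohorts of first-year physicians) for any effect size;
* **wearables**: person-level means plus AR(1) daily deviations
  (autocorrelation 0.3) within plausible fixed ranges (e.g. total sleep
  centred on 420 min, resting HR on 65 bpm). By default the wearable
  means do *not* depend on `u`: the streams are pure noise with respect
  to the outcomes, matching the empirical finding that these features
  added noise rather than predictive signal. `wearable_signal = TRUE`
  shifts the means with severity for sensitivity analyses.

Latent severity is retained in the output as a truth channel for recovery
tests only; no feature path reads it.

What the generator does **not** emulate: within-quarter symptom growth
(outcomes are fixed end-of-quarter labels and severity is static, whereas
real prevalences roughly double over the first quarter); weekly and
rotation-schedule structure in mood or sleep; institution/specialty
nesting; device-specific artifacts (sync gaps vs non-wear are
indistinguishable here, and both are treated simply as missing). Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
well calibrated, not that any particular real-data AUC is reproducible.

## Numerical and design choices

* **Sample vs population SD**: summary features use the n−1 denominator,
  the convention of the statistical environments this design comes from.
* **Percent-missing base**: missing days / t over all scheduled days to
  date — every variable is defined daily for every participant.
* **Imputation fallback**: a feature with no available training values at
  all (e.g. any SD feature at t = 2) falls back to 0 for SD features and
  the variable-range midpoint for means, with a warning. This occurs only
  on the first few days, where the feature is uninformative anyway.
* **Degenerate folds**: an outer test fold containing a single class has
  no defined AUC; the estimate is dropped, counted and flagged rather
  than imputed. Stratified fold assignment makes this rare even at SI
  prevalence, which is why stratification is the default.
* **Intercept-only degeneracy**: if every feature in a training set is
  constant (possible in a high-missingness stratum early in the quarter),
  ENR falls back to the intercept-only model rather than failing; all
  validation scores tie and the cell contributes a 0.5 AUC.
* **One-SE band**: the rule compares each day against the *final day's*
  mean minus the *final day's* SE — the literal reading of the
  convergence criterion. Because a single noisy day can cross that band
  spuriously, a sustained variant (the first day from which every later
  evaluated day stays in the band) and a candidate-day-SE variant are
  computed alongside and reported in the same summary table.
* **Fold plans per day**: each day's fold plan is regenerated from
  `(master seed, day)`, treating days as independent analyses, which is
  the plainest reading of "estimated iteratively". A `shared_folds` flag
  reuses one plan across days for smoother curves.
* **Missingness boundaries**: the depression strata use exact thirds on
  the missing proportion — low [0, 1/3), medium [1/3, 2/3], high
  (2/3, 1] — and SI uses halves with ≥ 1/2 missing going to the high
  group. Boundary membership is computed in integer arithmetic
  (`3·missing_days` vs `t`), so exact thirds never fall on the wrong side
  of a floating-point comparison. Group labels are stated as
  *missingness* levels, with completion-rate aliases attached to outputs
  because completion-rate phrasings of the same groups are ambiguous.
* **ENR at vanishing penalty**: glmnet is warm-started down a short
  descending path ending at the requested penalty; at penalty 1e−10 the
  coefficients agree with an unpenalized `glm` fit to 1e−4, which the
  test suite asserts.
* **Determinism**: every stochastic step — cohort draw, fold plans, RF
  fits — derives its seed from a master seed through a small integer
  hash, and the generator restores the global RNG state, so sweeps are
  bit-reproducible and per-day cells are independent of evaluation order.

## Problem sizes

The shipped analysis scripts and the test suite run at desk scale, chosen
so a full pass stays in minutes on one core: cohorts of 500–800
participants for calibration and recovery experiments (2000–5000 where
only the generator is exercised), day grids of 9 points across the
quarter for the 8-configuration sweep and all 30 days for plateau
detection. The full-resolution analogue — 2459 participants, all 92 days,
all 8 configurations — is the same code with larger arguments.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(synthetic_config(n_participants = 800,
                                       mood_effect = 1.5,
                                       outcome_effect = 2, seed = 1))
curves <- run_temporal_sweep(co, model_config("depression", "ENR", "mood_only"),
                             days = c(3, 7, 14, 30, 60, 92), master_seed = 1)
convergence_summary(curves[[1]])
```

## Known limitations

Beyond the generator's simplifications listed above: no formal inference
is attached to cross-day AUC comparisons (the estimates are autocorrelated
across days and no accepted test exists for that setting — the one-SE rule
is a heuristic); the comparison covers exactly two algorithms; and RF
probabilities are averaged leaf class proportions, one of two common
conventions.
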