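# moodcast

How many days of daily mood diaries and wearable data do you need before
you can predict end-of-quarter depression or suicidal ideation as well as
you ever will?

`moodcast` is an R package plus analysis workflow for that temporal
question in intensive longitudinal mental-health studies. It targets the
design used in large cohorts of first-year training physicians: a single
daily mood item ("on a scale of 1–10, how was your mood today?"), ten
daily Fitbit-style metrics (total sleep, sleep start/end, sleep
efficiency, steps, four activity-minute bands, resting heart rate), and
two binary outcomes at the end of a 92-day quarter — depression (PHQ-9
≥ 10) and suicidal ideation (any endorsement of the PHQ-9 suicidality
item). Because no such dataset is public, the package ships a seeded
synthetic-cohort generator with the same statistical structure
(person-level heterogeneity, informative and time-decaying missingness,
calibrated outcome prevalences of 18.5% / 6.8%), and every result it
reports is computed on those synthetic cohorts.

## The method

For each day t in the quarter, each daily variable v is summarized over
days 1..t by three accumulating statistics

* mean_v (needs ≥ 2 observed days),
* sd_v — sample SD, n−1 denominator (needs ≥ 3),
* %missing_v = 100 · (missing days) / t (always defined),

giving 33 features for the full predictor set (3 × 11 variables) or 3 for
the mood-only set. Eight model configurations — {depression, SI} ×
{elastic-net logistic regression (ENR), 100-tree Gini random forest (RF)}
× {mood-only, mood + wearables} — are evaluated per day with nested
cross-validation: a 3-fold inner loop tunes each algorithm's 3 × 3
hyperparameter grid (ENR: penalty × L1-mixture; RF: mtry × minimum node
size), and a 3 × 5 repeated outer loop yields 15 out-of-sample AUC
estimates, summarized as mean ± SE with the conservative
`sd(estimates)/√5` standard error. Unavailable features are imputed with
training-fold medians at every level of the nest. Two rules are read off
each per-day AUC curve:

* **one-SE convergence day** — first day with mean AUC ≥ (final-day mean
  − final-day SE);
* **acceptability day** — last day with mean AUC < 0.70.

The same machinery reruns within adherence strata recomputed daily from
each participant's mood response rate (three missingness groups for
depression, two for SI).

## Worked example

```r
library(moodcast)

co <- generate_cohort(synthetic_config(n_participants = 800,
                                       mood_effect = 1.5,
                                       outcome_effect = 2, seed = 1))
curves <- run_temporal_sweep(co,
                             model_config("depression", "ENR", "mood_only"),
                             days = c(3, 7, 14, 30, 60, 92),
                             master_seed = 1)
print(as.data.frame(curves[[1]]))
#>   day  mean_auc     se_auc n_estimates
#> 1   3 0.7602967 0.02640064          15
#> 2   7 0.7969727 0.01466750          15
#> 3  14 0.8247384 0.01381324          15
#> 4  30 0.8346211 0.01576730          15
#> 5  60 0.8454162 0.02076853          15
#> 6  92 0.8507614 0.01508977          15
convergence_summary(curves[[1]])[, c("final_mean_auc",
                                     "first_day_within_one_se",
                                     "last_day_below_threshold")]
#>   final_mean_auc first_day_within_one_se last_day_below_threshold
#> 1      0.8507614                      60                       NA
```

Read: on this strong-signal synthetic cohort the mood-only ENR reaches a
final (day 92) mean AUC of 0.851; day 60 is the first evaluated day whose
mean AUC is within one SE of that on this sparse 6-day grid (a denser
grid locates the crossing earlier — the curve is essentially flat after
day 30); and no evaluated day fell below the 0.70 acceptability floor
(`last_day_below_threshold = NA`).

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic
cohort and write tidy CSVs under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort -> results/cohort/
Rscript analysis/02_full_sweep.R      # 8 configs x day grid -> results/full_sample/
Rscript analysis/03_convergence.R     # convergence tables + report + figures
Rscript analysis/04_missingness.R     # adherence-stratified sweep -> results/missingness/
```

Stage 2 caches each (configuration, day) cell under `results/cache/` and
resumes an interrupted sweep; changing seeds, folds or grids invalidates
the cache explicitly. Every stage is deterministic given its master seed.

## Vignette

`vignettes/temporal-auc-methods.Rmd` documents the model, the synthetic
generator and its realism limits, the numerical choices (tie-breaks,
imputation fallbacks, degenerate folds, one-SE band variants) and the
desk-scale problem sizes used throughout.
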