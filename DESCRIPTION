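Package: moodcast
Title: Temporal Prediction of Depression and Suicidal Ideation from Daily
    Mood Diaries and Wearable Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how quickly intensive longitudinal data can
    predict end-of-quarter mental health outcomes. Simulates cohorts of
    daily mood-diary ratings and wearable (sleep, activity, resting heart
    rate) streams with informative, time-decaying missingness; accumulates
    day 1..t summary features (mean, standard deviation, percent missing);
    trains elastic-net logistic regression and random forest classifiers
    under nested cross-validation (3-fold inner tuning, 3x5 repeated outer
    validation); traces per-day AUC curves for binary depression and
    suicidal-ideation outcomes; and locates the day at which accuracy
    converges (one-standard-error rule) or becomes acceptable (AUC > 0.70),
    overall and within adherence-defined subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    ggplot2
Config/testthat/edition: 3
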