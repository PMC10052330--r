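Package: asvrf
Title: Feature-Weighted Random Forests for E-Health Patient Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classification stack for continuous patient-monitoring data
    (e.g. glucose readings from diabetic cohorts): leakage-safe min-max
    normalization with median imputation, linear discriminant analysis by the
    between/within scatter generalized eigenproblem, a random-forest variant
    whose per-tree feature subsets are drawn with probability proportional to
    chi-squared feature-class association over a pre-selected top-ranked
    feature set (C4.5 gain-ratio base trees, probability-averaged voting),
    particle swarm optimization with linearly decaying inertia for
    hyperparameter tuning, a confusion-matrix metric suite (accuracy,
    sensitivity, specificity, precision, F1, Cohen's kappa, MAE, RMSE), and a
    seeded synthetic cohort generator with planted informative features,
    correlated noise and missing-completely-at-random gaps for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
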