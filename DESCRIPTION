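Package: microdiab
Title: Microarray Diabetes Classification with Metaheuristic Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-class (diabetic versus non-diabetic)
    classification of microarray gene-expression cohorts. Provides per-sample
    log10 standardization, block-wise dimensionality reduction by detrended
    fluctuation analysis, a chi-square block statistic, and Firefly or Cuckoo
    swarm-weighted projections; wrapper feature selection by particle swarm
    optimization or harmony search; seven classifiers (non-linear, linear and
    logistic regression, Gaussian mixtures, Bayesian linear discriminant,
    softmax discriminant, RBF support vector machine) trained against mapped
    class targets; stratified k-fold evaluation with a confusion-matrix metric
    suite (accuracy, recall, precision, F1, MCC, error rate, Jaccard, Cohen's
    kappa); and a seeded synthetic cohort generator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    e1071,
    jsonlite,
    mclust,
    withr
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
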