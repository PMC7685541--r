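Package: powerforest
Title: Stable Random-Forest Feature Selection and Simulation-Based Power
    Analysis for Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-module framework for biomarker discovery in tabular omics
    data. Module one runs repeated random-forest feature selection (Boruta
    shadow-variable testing, outcome-permutation significance testing with and
    without Benjamini-Hochberg correction, and recursive feature elimination)
    inside a nested cross-validation loop and reports low- and high-stringency
    stable feature sets with held-out validation performance. Module two fits a
    multivariate log-normal model that preserves the correlation structure of
    the input data, groups highly correlated variables, estimates per-variable
    effect sizes (Pearson correlation or Cohen's d), and runs Monte-Carlo power
    calculations over a sample-size grid to recommend sample sizes for future
    studies. Includes a simulation module that generates benchmark datasets
    with six correlated predictor groups and a known nonlinear outcome model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
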