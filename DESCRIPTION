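Package: afexplain
Title: Interpretable RR-Interval Feature Models for Heart-Rhythm
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for interpretable, hand-crafted-feature classification
    of short single-lead heart-rhythm recordings into normal sinus rhythm,
    atrial fibrillation, other rhythms, and noise.  Provides a seeded
    synthetic generator of labelled RR-interval data, the standard
    rhythm-irregularity feature set (HRV statistics, heart-rate
    fragmentation, Lorenz-plot evidence scores, coefficient of sample
    entropy), native decision-tree ensembles and logistic models exposing
    the node-level structure needed for impurity-based importance, four
    global feature-importance methods (coefficient-, Gini-, permutation-
    and Shapley-based), exact and sampled Shapley attributions with
    executable axiom checks, LIME-style local surrogate explanations, and
    a repeated stratified cross-validation harness with micro/macro
    F-scores and rank-based incremental feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
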