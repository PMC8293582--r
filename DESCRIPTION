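Package: bfsmr
Title: Bagging-Based Ensemble Feature Selection with Chunked MapReduce-Style Execution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble feature selection for large tabular cohort data that
    cannot be loaded in memory at once. Records are streamed in fixed-size
    chunks, split into train/test partitions, and bootstrapped samples tagged
    with set identifiers are merged across chunks and routed to five distinct
    feature-selection methods (mutual-information filter, SVM-RFE, lasso,
    ridge, and random-forest permutation importance). The per-method top-K
    ranked lists are fused by a weighted voting scheme combining per-rank
    feature weights with per-method performance-tier weights, yielding a
    single interpretable feature ranking. A synthetic cohort generator with
    an age/sex-stratified BMI-percentile outcome, planted effects, and
    configurable block missingness makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    generics,
    glmnet,
    e1071,
    ranger,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
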