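---
title: "Methods: bagging-based ensemble feature selection with chunked execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bagging-based ensemble feature selection with chunked execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfsmr)
```

## The model

`bfsmr` fuses the rankings of several feature-selection methods into one
interpretable feature ranking, under the constraint that the cohort file
cannot be loaded in memory at once. The design is a split–apply–combine
plan married to bagging:

* **Split.** The file is streamed in fixed-size chunks. A first pass
  accumulates per-(age, sex)-stratum BMI values and the observed levels of
  every categorical variable; the outcome threshold for each stratum is
  the nearest-rank 90th percentile of BMI, and a record is labelled
  overweight when its BMI is *strictly* above its stratum threshold.
* **Map.** Each chunk is split at random into a train partition (80%) and
  a test partition (20%). From the train partition, `M` with-replacement
  samples of 10% of its size are drawn, tagged with set IDs 1..M; the test
  partition is tagged 0 and is never touched by any training step.
* **Shuffle/Reduce.** Samples sharing a set ID are pooled across chunks.
  Set `i` feeds selector `i`; every selector emits its top-`K` features
  with importances and effect signs, and its predictor is scored on the
  pooled sid-0 test set, so all methods are compared on identical data.
* **Merge.** Each ranked-list entry casts a weighted vote for its feature
  in the canonical union space. Writing `w1[k]` for the weight of rank `k`
  and `w2[j]` for the weight of selector `j`, the three strategies score a
  feature by the sum over its supporting entries of 1 (`voting1`),
  `w1[k]` (`voting2`), or `w1[k] * w2[j]` (`voting3`).

The key assumptions are that visit records can be treated as exchangeable
rows (repeated records of one child are not modelled longitudinally), that
a union of per-method top-K lists is a fair canonical space for voting,
and that per-chunk random splits approximate a global split well when
chunks are large relative to the outcome prevalence.

## The selector bank

Five methods spanning the filter, wrapper, and embedded families:

| selector | importance | key defaults |
|---|---|---|
| `filter_mi` | kNN mutual information with the outcome | 3 neighbours |
| `svm_rfe` | absolute linear-SVM weight, recursive elimination | step 1, cost 1 |
| `lasso` | absolute coefficient at CV-chosen penalty | CV over the path, 5 folds |
| `ridge` | absolute coefficient at CV-chosen penalty | grid 10^4..10^-2, 5 folds |
| `random_forest` | permutation importance on a held-out split | 50 Gini trees, 5 repeats |

Notes on the choices that were genuinely open:

* **Mutual information.** No installed R package provides the
  continuous-feature / discrete-label kNN estimator, so it is implemented
  here: per point, the distance to its k-th nearest neighbour *within its
  label class* sets a radius, and the count of points of any class inside
  that radius enters a digamma average. In one dimension the k nearest
  neighbours of a sorted sample lie in a contiguous window, giving an
  O(n log n) implementation. Dummy columns are jittered by 1e-10 of their
  scale (seeded) to break ties; constant features score 0.
* **Penalized regressions.** Lasso and ridge are fitted as regularized
  *least squares* on the 0/1 outcome, with the penalty chosen by
  cross-validation along the path — the penalty value is a data-dependent
  outcome of the procedure, not an input. Logistic variants sit behind the
  `logistic` hyperparameter. If the chosen penalty zeroes every lasso
  coefficient, ranking falls back to path entry order, with a warning.
* **SVM-RFE.** Features are standardized, one feature is dropped per
  iteration (the smallest absolute weight; ties take the earlier column),
  and the `K` survivors are ranked by the final fit's absolute weights.
  The weight vector is oriented so a positive coefficient pushes towards
  the positive class, making signs comparable across selectors.
* **Random forest.** Permutation importance is computed on an internal
  80/20 validation split of the selector's own set rather than on its
  training rows, which reduces the optimistic bias of training-set
  permutation scores. Negative mean drops are clipped to 0 in the report.
* **Performance.** Regression-type predictors are thresholded at 0.5;
  accuracy and the F-score of the positive class are reported. The filter
  selects without a learning algorithm, so its carried predictor is an
  ordinary least-squares fit on its selected features. The positive class
  defaults to the overweight label but is configurable, since with a ~10%
  prevalence the F-score changes drastically with that convention.

## The voting layer

* **Rank weights.** The default is linear, `w1[k] = K + 1 - k` (rank 1
  gets K, rank K gets 1). This is exposed as a plain numeric vector;
  `rank_weights_borda()` gives the 1/k alternative.
* **Model weights.** An explicit tier map takes precedence over raw test
  scores, because model weights encode judgement about model properties as
  well as performance (a filter may be demoted for ignoring interactions
  despite good metrics). `default_tier_weights()` carries the standard
  three-tier ladder for the five-method bank: lasso/ridge 1, filter and
  SVM-RFE 0.5, random forest 0.2. `"auto"` mode tiers selectors by the
  mean of accuracy and F-score with a 0.02 tolerance.
* **Aliases.** Complementary dummy encodings of one variable (an
  "adequate" column that is the negatively-signed mirror of an
  "inadequate" column) can be folded together before voting;
  `default_alias_map()` encodes the single merge needed by the packaged
  example lists. If folding makes two entries of one list share a name,
  both keep their rank weights.
* **Ties.** Final ordering breaks score ties by the number of supporting
  lists (descending) then feature name (ascending) — deterministic and
  favouring consensus. Scores are exact sums of rational weights
  internally and rounded to one decimal only in exports.
* Signs do not enter the vote arithmetic; they are carried for reporting.

## The synthetic cohort generator

The generator emulates the statistical shape of a primary-care cohort
export: one row per visit, several visits per child across ages 1–18, a
panel of numeric vitals with near-zero missingness, lifestyle variables
with 30–70% missingness, a rare form above 80%, and a BMI built as

```
BMI = 14.5 + 0.25 * age + 0.3 * (sex == "M") + sum(beta_f * x_f) + N(0, 2)
```

so that thresholding at the stratum 90th percentile yields an outcome of
known association and sign with the planted features `f`. Missingness is
missing-completely-at-random per cell (real visit-motivation-driven
missingness is closer to MNAR, but no generative mechanism for it is
defensible here; MCAR is the testable default and rates are per-feature
hooks). Outcome prevalence is controlled by the percentile knob rather
than fixed. Everything derives from one master seed, with per-stage and
per-chunk derived seeds so results are independent of processing order.

The recovery experiment used by the tests (`recovery_cohort_config()`)
plants three effects worth twice the BMI noise SD per standard deviation
of the observed feature: SystolicPressure +4 and Birthweight −4 (numeric,
SD 1) and Tobacco_lv2 +8 (binary indicator, SD 0.5, so the raw
coefficient is doubled to carry the same per-SD signal). Test cohorts use
30,000 records from 12,000 children — large enough for ~1,000-record
strata and stable selector behaviour, small enough for a desk run.

What passing these tests shows — and does not. Recovery of planted linear
effects under MCAR missingness demonstrates the plumbing end to end:
labels, encoding, bootstrap routing, each selector's ranking behaviour,
and the vote fusion. It does not certify behaviour under informative
missingness, correlated feature blocks, nonlinear effects, or
within-child dependence, none of which the generator produces.

## Numerical conventions

* Percentiles use the nearest-rank definition (smallest order statistic at
  or above the target rank): deterministic and tie-robust. Strata with
  fewer than 10 records fall back to the pooled threshold with a warning.
  An externally supplied threshold table can replace the empirical pass.
* Overweight is `BMI > threshold`, strictly.
* Test partition size is `round((1 - split_ratio) * n)`; bootstrap size is
  `floor(frac * train size)` — stated so the size laws are exact.
* Numeric missing values are imputed by the per-chunk median (no second
  pass; bounded memory); missing or unseen categorical values encode as
  all-zero dummy rows. Records missing BMI, age or sex cannot be labelled
  and are dropped, with counts in the manifest (rows in = labelled +
  dropped, always).
* Bootstrap sampling is uniform over rows; a stratified variant is out of
  scope for now.
* Chunks with fewer than `M + 1` rows are skipped with a warning.

## Problem sizes in the test-suite

Unit tests run on 10^2–10^4-row constructions; the chunk-accounting test
streams a 148,857-row file at chunk size 10,000; the recovery experiment
runs the full pipeline on ten seeds at 30,000 records each; the voting
arithmetic is checked against a brute-force double sum on 1,000 random
small instances. Every expected number in the suite is either computed by
an independent oracle in the test itself or a closed-form constant.

## Limitations

* Selection is correlation-based and diagnostic; no causal reading.
* Single-host execution: sid groups and chunks are contracts of
  independence (identical results regardless of order), not a distributed
  runtime.
* The least-squares selectors thresholded at 0.5 are conservative
  classifiers at 10% prevalence; their test accuracies sit close to the
  majority-class rate, which is why model weights accept an explicit tier
  map rather than trusting small metric differences.
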