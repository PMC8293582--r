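# Selector bank: the kNN MI estimator against a closed-form oracle, the
# ranking/sign behaviour of each method, shared invariants, and the
# confusion-matrix arithmetic of the performance evaluator.

test_that("kNN MI matches the plug-in MI of a known 2x2 contingency table", {
  n <- 4000
  # joint counts: (0,0)=1500 (0,1)=500 (1,0)=500 (1,1)=1500
  x <- rep(c(0, 0, 1, 1), c(1500, 500, 500, 1500))
  y <- rep(c(0, 1, 0, 1), c(1500, 500, 500, 1500))
  p <- c(1500, 500, 500, 1500) / n
  marg <- c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5)
  exact <- sum(p * log(p / marg))
  set.seed(1)
  est <- mutual_info_knn(x + 1e-10 * rnorm(n), y, k = 3)
  expect_lt(abs(est - exact), 0.03)  # discrete-mass bias at this n
})

test_that("kNN MI hits its independence and identity limits", {
  set.seed(2)
  y <- rbinom(10000, 1, 0.5)
  expect_lt(mutual_info_knn(rnorm(10000), y, 3), 0.02)
  # feature equal to the label: MI = H(y) = log 2
  est <- mutual_info_knn(y + 1e-10 * rnorm(10000), y, 3)
  expect_lt(abs(est - log(2)), 0.02)
  expect_equal(mutual_info_knn(rep(1, 100), rbinom(100, 1, 0.5), 3), 0)
})

test_that("the MI filter ranks a label-identical feature first", {
  set.seed(3)
  n <- 2000
  y <- rbinom(n, 1, 0.3)
  x <- cbind(copy = y, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  fit <- select_filter_mi(x, y, selector_spec("filter_mi", K = 3), seed = 1)
  expect_equal(fit$ranking$feature[1], "copy")
  expect_equal(fit$ranking$sign[1], "+")
  # the carried OLS predictor reproduces the label from its own features
  perf <- evaluate_performance(fit, x, y)
  expect_equal(perf$accuracy, 1)
})

test_that("SVM-RFE keeps a separating feature at rank 1 with the right sign", {
  set.seed(4)
  n <- 400
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n), f4 = rnorm(n))
  y <- as.integer(x[, "f1"] > 0)
  fit <- select_svm_rfe(x, y, selector_spec("svm_rfe", K = 2), seed = 1)
  expect_equal(fit$ranking$feature[1], "f1")
  expect_equal(fit$ranking$sign[1], "+")
  # negative association carries a negative sign
  y2 <- as.integer(x[, "f2"] < 0)
  fit2 <- select_svm_rfe(x, y2, selector_spec("svm_rfe", K = 2), seed = 1)
  expect_equal(fit2$ranking$feature[1], "f2")
  expect_equal(fit2$ranking$sign[1], "-")
  # boundary: n_features = K means no elimination, single-fit ranking
  fit3 <- select_svm_rfe(x, y, selector_spec("svm_rfe", K = 4), seed = 1)
  expect_equal(nrow(fit3$ranking), 4)
  expect_equal(fit3$ranking$feature[1], "f1")
  expect_error(select_svm_rfe(x, rep(1L, n), selector_spec("svm_rfe", K = 2)),
               "single-class")
})

test_that("lasso and ridge recover planted effects with matching signs", {
  set.seed(5)
  n <- 20000
  p <- 20
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
  lp <- 2 * x[, "f3"] - 1.5 * x[, "f7"] + 1 * x[, "f11"]
  y <- as.integer(lp + rnorm(n) > quantile(lp + rnorm(n), 0.9))
  for (id in c("lasso", "ridge")) {
    fit <- run_selector(x, y, selector_spec(id, K = 10), seed = 2)
    top <- fit$ranking
    expect_true(all(c("f3", "f7", "f11") %in% top$feature[1:10]))
    expect_equal(top$sign[top$feature == "f3"], "+")
    expect_equal(top$sign[top$feature == "f7"], "-")
  }
})

test_that("a saturating penalty grid zeroes the lasso with a path-order fallback", {
  set.seed(6)
  x <- matrix(rnorm(500 * 4), 500, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  spec <- selector_spec("lasso", K = 4, lambda_grid = c(1e6, 9e5))
  expect_warning(fit <- select_lasso(x, y, spec, seed = 1), "zero")
  expect_equal(nrow(fit$ranking), 4)
})

test_that("random forest permutation importance is maximal for the label feature", {
  set.seed(7)
  n <- 1500
  y <- rbinom(n, 1, 0.4)
  x <- cbind(copy = y + 0.01 * rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  fit <- select_random_forest(x, y, selector_spec("random_forest", K = 3), seed = 3)
  expect_equal(fit$ranking$feature[1], "copy")
  # features the forest cannot use have near-zero permutation importance
  noise_imp <- fit$ranking$importance[fit$ranking$feature != "copy"]
  expect_true(all(noise_imp < 0.02))
})

test_that("rescaling a feature leaves standardizing selectors unchanged", {
  set.seed(8)
  n <- 800
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- as.integer(x[, "f1"] + 0.5 * x[, "f2"] + rnorm(n) > 1)
  x_scaled <- x
  x_scaled[, "f2"] <- x[, "f2"] * 1000
  for (id in c("svm_rfe", "lasso", "ridge")) {
    a <- run_selector(x, y, selector_spec(id, K = 3), seed = 4)$ranking
    b <- run_selector(x_scaled, y, selector_spec(id, K = 3), seed = 4)$ranking
    expect_equal(a$feature, b$feature)
    expect_equal(a$importance, b$importance, tolerance = 1e-6)
  }
})

test_that("every selector returns a valid, deterministic ranked list", {
  set.seed(9)
  n <- 1200
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] - x[, 2] + rnorm(n) > 1)
  for (id in c("filter_mi", "svm_rfe", "lasso", "ridge", "random_forest")) {
    spec <- selector_spec(id, K = 4)
    fit <- run_selector(x, y, spec, seed = 11)
    r <- fit$ranking
    expect_equal(r$rank, 1:4)
    expect_true(all(diff(r$importance) <= 1e-12))  # non-increasing
    expect_true(all(r$importance >= 0))
    expect_true(all(r$feature %in% colnames(x)))
    expect_true(all(r$sign %in% c("+", "-")))
    again <- run_selector(x, y, spec, seed = 11)
    expect_identical(r, again$ranking)
  }
})

test_that("selectors agree on the sign of a monotone planted effect", {
  cfg <- recovery_cohort_config(master_seed = 4, n_records = 8000,
                                n_children = 3200)
  res <- suppressWarnings(run_bfsmr(bfsmr_config(cfg, chunk_size = 4000,
                                                 master_seed = 4)))
  r <- res$rankings
  for (f in c("SystolicPressure", "Birthweight")) {
    signs <- unique(r$sign[r$feature == f])
    expect_length(signs, 1)
  }
  expect_true(all(r$sign[r$feature == "SystolicPressure"] == "+"))
  expect_true(all(r$sign[r$feature == "Birthweight"] == "-"))
})

test_that("accuracy and F-score follow the confusion-matrix formulas", {
  # TP=8, FP=2, FN=2, TN=8
  pred <- rep(c(1, 1, 0, 0), c(8, 2, 2, 8))
  truth <- rep(c(1, 0, 1, 0), c(8, 2, 2, 8))
  perf <- classification_performance(pred, truth)
  expect_equal(perf$accuracy, 0.8)
  expect_equal(perf$f_score, 0.8)

  # an all-positive predictor on 843/1000 positives
  perf2 <- classification_performance(rep(1, 1000),
                                      rep(c(1, 0), c(843, 157)))
  expect_equal(perf2$accuracy, 0.843)
  expect_equal(perf2$f_score, 2 * 0.843 / 1.843, tolerance = 1e-12)

  # no predicted positives: undefined precision reported as F = 0
  expect_warning(perf3 <- classification_performance(rep(0, 10),
                                                     rep(c(1, 0), 5)),
                 "no predicted positives")
  expect_equal(perf3$f_score, 0)
  expect_equal(perf3$accuracy, 0.5)

  # the positive class is configurable
  perf4 <- classification_performance(rep(0, 10), rep(c(1, 0), 5), positive = 0)
  expect_equal(perf4$f_score, 2 * 0.5 / 1.5, tolerance = 1e-12)
})
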