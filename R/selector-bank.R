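# Selector bank (Reduce stage) ------------------------------------------
#
# Five feature-selection methods spanning the filter / wrapper / embedded
# families. Each consumes the merged bootstrap set routed to it by set ID,
# emits a ranked top-K feature list with signed effects, and carries a
# fitted predictor so all methods can be scored on the shared sid-0 test
# pool.

#' Specify one feature-selection method
#'
#' @param selector One of `"filter_mi"`, `"svm_rfe"`, `"lasso"`, `"ridge"`,
#'   `"random_forest"`.
#' @param K Number of features to select.
#' @param ... Hyperparameters: `k_neighbors` (filter_mi, default 3),
#'   `cost` (svm_rfe, default 1), `lambda_grid` (lasso/ridge; `NULL` lets
#'   the path be data-derived), `n_folds` (lasso/ridge CV, default 5),
#'   `n_trees` (random_forest, default 50), `n_permutation_repeats`
#'   (random_forest, default 5), `logistic` (lasso/ridge; fit the binomial
#'   variant instead of least squares on the 0/1 outcome, default FALSE).
#' @return An object of class `selector_spec`.
#' @export
selector_spec <- function(selector = c("filter_mi", "svm_rfe", "lasso", "ridge",
                                       "random_forest"),
                          K = 10L, ...) {
  selector <- match.arg(selector)
  stopifnot(K >= 1)
  hp <- list(...)
  defaults <- switch(selector,
    filter_mi = list(k_neighbors = 3L),
    svm_rfe = list(cost = 1),
    lasso = list(lambda_grid = NULL, n_folds = 5L, logistic = FALSE),
    ridge = list(lambda_grid = 10 ^ seq(4, -2, length.out = 100), n_folds = 5L,
                 logistic = FALSE),
    random_forest = list(n_trees = 50L, n_permutation_repeats = 5L)
  )
  for (nm in names(defaults)) if (is.null(hp[[nm]])) hp[[nm]] <- defaults[[nm]]
  structure(list(selector = selector, K = as.integer(K), hyperparameters = hp),
            class = "selector_spec")
}

#' The default bank of five selectors
#'
#' @param K Top-K size shared by all selectors (default 10).
#' @return Named list of [selector_spec()] objects in set-ID order
#'   (sid 1 = filter_mi, ..., sid 5 = random_forest).
#' @export
default_selector_specs <- function(K = 10L) {
  ids <- c("filter_mi", "svm_rfe", "lasso", "ridge", "random_forest")
  setNames(lapply(ids, selector_spec, K = K), ids)
}

# Mutual information ----------------------------------------------------

#' k-nearest-neighbour mutual information between a numeric feature and a
#' discrete label
#'
#' Mixed-type MI estimator: for each point, the distance to its k-th
#' nearest neighbour among points sharing its label sets a radius, and the
#' number of points of any label inside that radius enters a digamma
#' average (Ross-type estimator). Classes with fewer than 2 points are
#' dropped; per-class k is capped at the class size minus one. Callers
#' should jitter discrete-valued features to break ties (see
#' [select_filter_mi()]).
#'
#' @param x Numeric vector.
#' @param y Integer/character label vector of the same length.
#' @param k Number of neighbours, default 3.
#' @return Estimated MI in nats, clipped below at 0.
#' @export
mutual_info_knn <- function(x, y, k = 3L) {
  stopifnot(length(x) == length(y), k >= 1)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- as.character(y[keep])
  counts <- table(y)
  ok_class <- names(counts)[counts >= 2]
  use <- y %in% ok_class
  x <- x[use]; y <- y[use]
  n <- length(x)
  if (n < 3 || length(unique(y)) < 2 || length(unique(x)) == 1) return(0)

  radius <- numeric(n)
  kvec <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    m <- length(idx)
    kc <- min(k, m - 1L)
    ord <- order(x[idx])
    v <- x[idx][ord]
    r <- rep(Inf, m)
    # k nearest neighbours in 1-D sorted data lie in a contiguous window
    for (t in 0:kc) {
      hi <- seq_len(m) + t
      lo <- seq_len(m) + t - kc
      dhi <- ifelse(hi <= m, v[pmin(hi, m)] - v, Inf)
      dlo <- ifelse(lo >= 1, v - v[pmax(lo, 1)], Inf)
      r <- pmin(r, pmax(dhi, dlo))
    }
    radius[idx[ord]] <- r
    kvec[idx] <- kc
  }

  s <- sort(x)
  m_i <- findInterval(x + radius, s, left.open = TRUE) -
    findInterval(x - radius, s)
  m_i[m_i < 1] <- 1L
  label_n <- as.numeric(table(y)[y])
  mi <- digamma(n) - mean(digamma(label_n)) + mean(digamma(kvec)) -
    mean(digamma(m_i))
  max(0, mi)
}

# Selector implementations ----------------------------------------------

#' @noRd
sign_from_cor <- function(x, y) {
  s <- suppressWarnings(cor(x, y))
  ifelse(is.na(s) | s >= 0, "+", "-")
}

#' @noRd
ranked_tibble <- function(selector, features, importance, sign, K) {
  ord <- order(-importance)    # stable: ties keep column order
  take <- head(ord, K)
  tibble(
    selector = selector,
    rank = seq_along(take),
    feature = unname(features[take]),
    importance = unname(pmax(importance[take], 0)),
    sign = unname(sign[take])
  )
}

#' Mutual-information filter selection
#'
#' Ranks features by their k-nearest-neighbour MI with the binary outcome
#' ([mutual_info_knn()]). A tiny seeded jitter (1e-10 of the feature scale)
#' breaks duplicate-value degeneracy in dummy columns. Signs come from the
#' point-biserial correlation with the outcome. Because the filter involves
#' no learning algorithm, its carried predictor is an ordinary least-squares
#' regression of the outcome on the selected features, fitted on the same
#' set.
#'
#' @param x Numeric feature matrix with column names.
#' @param y Integer 0/1 outcome.
#' @param spec A [selector_spec()] with selector `"filter_mi"`.
#' @param seed Integer seed for the jitter.
#' @return An object of class `selector_fit`: list with `ranking` (tibble:
#'   selector, rank, feature, importance, sign), `predict(newx)` and
#'   `predict_type` (`"score"` or `"class"`).
#' @export
select_filter_mi <- function(x, y, spec, seed = 1L) {
  stopifnot(spec$selector == "filter_mi")
  k <- spec$hyperparameters$k_neighbors
  xj <- with_seed(seed, {
    jit <- matrix(rnorm(length(x)), nrow = nrow(x))
    x + 1e-10 * pmax(1, rep(colMeans(abs(x)), each = nrow(x))) * jit
  })
  mi <- vapply(seq_len(ncol(x)), function(j) mutual_info_knn(xj[, j], y, k),
               numeric(1))
  ranking <- ranked_tibble("filter_mi", colnames(x), mi,
                           sign_from_cor(x, y), spec$K)
  sel <- ranking$feature
  xs <- cbind(1, x[, sel, drop = FALSE])
  beta <- qr.coef(qr(xs), y)
  beta[is.na(beta)] <- 0
  structure(list(
    ranking = ranking,
    predict = function(newx) drop(cbind(1, newx[, sel, drop = FALSE]) %*% beta),
    predict_type = "score"
  ), class = "selector_fit")
}

#' Linear SVM recursive feature elimination
#'
#' Features are standardized, a linear support-vector classifier is fitted,
#' and the feature with the smallest absolute weight is dropped — one per
#' iteration (step 1) — until K remain. The K survivors are ranked by the
#' absolute weights of the final fit; signs are the final coefficient
#' signs (positive = pushes towards the positive class). Ties take the
#' earlier column.
#'
#' @inheritParams select_filter_mi
#' @param spec A [selector_spec()] with selector `"svm_rfe"`.
#' @export
select_svm_rfe <- function(x, y, spec, seed = 1L) {
  stopifnot(spec$selector == "svm_rfe")
  if (length(unique(y)) < 2) abort("svm_rfe: training labels are single-class")
  xs <- standardize_matrix(x)
  ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
  yf <- factor(y, levels = c(1L, 0L))  # first level drives decision sign
  cost <- spec$hyperparameters$cost

  remaining <- seq_len(ncol(xs))
  fit <- NULL
  w <- NULL
  repeat {
    fit <- with_seed(seed, e1071::svm(
      x = xs[, remaining, drop = FALSE], y = yf, kernel = "linear",
      cost = cost, scale = FALSE
    ))
    w <- drop(crossprod(fit$coefs, fit$SV))
    # orient w so positive weights push towards the positive class
    d <- xs[, remaining, drop = FALSE] %*% w - fit$rho
    pred1 <- predict(fit, xs[, remaining, drop = FALSE]) == "1"
    if (any(pred1) && any(!pred1) && mean(d[pred1]) < mean(d[!pred1])) w <- -w
    if (length(remaining) <= spec$K) break
    remaining <- remaining[-which.min(abs(w))]
  }
  imp <- abs(w)
  ranking <- ranked_tibble("svm_rfe", colnames(xs)[remaining], imp,
                           ifelse(w >= 0, "+", "-"), spec$K)
  sel_idx <- remaining
  structure(list(
    ranking = ranking,
    predict = function(newx) {
      nz <- scale(newx, center = ctr, scale = scl)[, sel_idx, drop = FALSE]
      as.integer(as.character(predict(fit, nz)))
    },
    predict_type = "class"
  ), class = "selector_fit")
}

#' @noRd
select_glmnet <- function(x, y, spec, seed, alpha) {
  id <- spec$selector
  xs <- standardize_matrix(x)
  ctr <- attr(xs, "scaled:center"); scl <- attr(xs, "scaled:scale")
  hp <- spec$hyperparameters
  fam <- if (isTRUE(hp$logistic)) "binomial" else "gaussian"
  cvfit <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(hp$n_folds), length(y)))
    glmnet::cv.glmnet(xs, y, alpha = alpha, lambda = hp$lambda_grid,
                      family = fam, standardize = FALSE, foldid = foldid)
  })
  beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  imp <- abs(beta)
  sgn <- ifelse(beta > 0, "+", ifelse(beta < 0, "-", sign_from_cor(x, y)))
  if (all(imp == 0) && alpha > 0) {
    warn(sprintf("%s: all coefficients zero at the selected lambda; ranking by path entry order", id))
    entry <- apply(as.matrix(cvfit$glmnet.fit$beta) != 0, 1,
                   function(r) if (any(r)) which(r)[1] else Inf)
    imp <- 1 / (1 + entry)   # earlier entry -> larger pseudo-importance
  }
  ranking <- ranked_tibble(id, colnames(xs), imp, sgn, spec$K)
  structure(list(
    ranking = ranking,
    lambda = cvfit$lambda.min,
    predict = function(newx) {
      nz <- scale(newx, center = ctr, scale = scl)
      drop(predict(cvfit, newx = nz, s = "lambda.min",
                   type = if (fam == "binomial") "response" else "link"))
    },
    predict_type = "score"
  ), class = "selector_fit")
}

#' L1-regularized (lasso) selection
#'
#' Least-squares regression of the 0/1 outcome on standardized features
#' with an L1 penalty; the penalty is chosen by cross-validation along the
#' regularization path. Importance is the absolute coefficient at the
#' chosen penalty, sign its sign. If everything is shrunk to zero the
#' ranking falls back to path entry order with a warning. A logistic
#' variant is available via the `logistic` hyperparameter.
#'
#' @inheritParams select_filter_mi
#' @param spec A [selector_spec()] with selector `"lasso"`.
#' @export
select_lasso <- function(x, y, spec, seed = 1L) {
  stopifnot(spec$selector == "lasso")
  select_glmnet(x, y, spec, seed, alpha = 1)
}

#' L2-regularized (ridge) selection
#'
#' As [select_lasso()] with an L2 penalty: no exact zeros, so the ranking
#' is always total.
#'
#' @inheritParams select_filter_mi
#' @param spec A [selector_spec()] with selector `"ridge"`.
#' @export
select_ridge <- function(x, y, spec, seed = 1L) {
  stopifnot(spec$selector == "ridge")
  select_glmnet(x, y, spec, seed, alpha = 0)
}

#' Random-forest permutation-importance selection
#'
#' A Gini-split forest is trained on an internal 80% split of the set; the
#' importance of a feature is the mean decrease in accuracy on the held-out
#' 20% over repeated permutations of that feature's column. Scoring
#' importance on held-out rows reduces the training-set bias that impurity
#' importances suffer from. Signs come from the point-biserial correlation.
#'
#' @inheritParams select_filter_mi
#' @param spec A [selector_spec()] with selector `"random_forest"`.
#' @export
select_random_forest <- function(x, y, spec, seed = 1L) {
  stopifnot(spec$selector == "random_forest")
  if (length(unique(y)) < 2) abort("random_forest: training labels are single-class")
  hp <- spec$hyperparameters
  n <- nrow(x)
  idx <- with_seed(seed, sample.int(n, floor(0.8 * n)))
  xt <- x[idx, , drop = FALSE]; yt <- y[idx]
  xv <- x[-idx, , drop = FALSE]; yv <- y[-idx]
  fit <- ranger::ranger(
    x = as.data.frame(xt), y = factor(yt, levels = c(0L, 1L)),
    num.trees = hp$n_trees, splitrule = "gini", seed = seed,
    num.threads = 1
  )
  base_acc <- mean(predict(fit, as.data.frame(xv),
                           num.threads = 1)$predictions == yv)
  imp <- with_seed(derive_seed(seed, 97L), {
    vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(hp$n_permutation_repeats), function(r) {
        xp <- xv
        xp[, j] <- xp[sample.int(nrow(xv)), j]
        base_acc - mean(predict(fit, as.data.frame(xp),
                                num.threads = 1)$predictions == yv)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  ranking <- ranked_tibble("random_forest", colnames(x), imp,
                           sign_from_cor(x, y), spec$K)
  structure(list(
    ranking = ranking,
    predict = function(newx) {
      as.integer(as.character(predict(fit, as.data.frame(newx),
                                      num.threads = 1)$predictions))
    },
    predict_type = "class"
  ), class = "selector_fit")
}

#' Run one selector on its merged set
#'
#' @param x,y Merged set feature matrix and labels.
#' @param spec A [selector_spec()].
#' @param seed Integer seed.
#' @return A `selector_fit`.
#' @export
run_selector <- function(x, y, spec, seed = 1L) {
  switch(spec$selector,
    filter_mi = select_filter_mi(x, y, spec, seed),
    svm_rfe = select_svm_rfe(x, y, spec, seed),
    lasso = select_lasso(x, y, spec, seed),
    ridge = select_ridge(x, y, spec, seed),
    random_forest = select_random_forest(x, y, spec, seed)
  )
}

# Performance -----------------------------------------------------------

#' Accuracy and F-score of predicted against true labels
#'
#' F-score is the harmonic mean of precision and recall for the configured
#' positive class. If nothing is predicted positive, precision is
#' undefined and the F-score is reported as 0 with a warning.
#'
#' @param pred Predicted 0/1 labels.
#' @param truth True 0/1 labels.
#' @param positive The class treated as positive (default 1, overweight).
#' @return Tibble with `accuracy`, `f_score`, `n`.
#' @export
classification_performance <- function(pred, truth, positive = 1L) {
  stopifnot(length(pred) == length(truth))
  acc <- mean(pred == truth)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp + fp == 0) {
    warn("no predicted positives: F-score reported as 0")
    f <- 0
  } else if (tp == 0) {
    f <- 0
  } else {
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    f <- 2 * prec * rec / (prec + rec)
  }
  tibble(accuracy = acc, f_score = f, n = length(truth))
}

#' Evaluate a fitted selector on the shared test pool
#'
#' Regression-type predictors are thresholded at 0.5; classifier-type
#' predictors are used as-is. All selectors of a run are scored on the same
#' sid-0 set.
#'
#' @param fit A `selector_fit`.
#' @param x,y Test feature matrix and labels (the merged sid-0 set).
#' @param positive Positive class for the F-score (default 1).
#' @return Tibble with `selector`, `accuracy`, `f_score`, `n_test`.
#' @export
evaluate_performance <- function(fit, x, y, positive = 1L) {
  stopifnot(inherits(fit, "selector_fit"))
  if (length(y) == 0) abort("empty test set")
  raw <- fit$predict(x)
  pred <- if (fit$predict_type == "score") as.integer(raw >= 0.5) else as.integer(raw)
  perf <- classification_performance(pred, y, positive)
  tibble(selector = fit$ranking$selector[1],
         accuracy = perf$accuracy, f_score = perf$f_score,
         n_test = perf$n)
}

#' Run the whole selector bank on merged sets
#'
#' Selector i consumes the merged set with sid i (in the order of `specs`)
#' and is evaluated on the shared sid-0 pool.
#'
#' @param merged A `merged_sets` from [shuffle_merge()].
#' @param specs Named list of [selector_spec()]s (default the five-method
#'   bank).
#' @param master_seed Run master seed; selector i derives seed i.
#' @param positive Positive class for F-scores.
#' @return List with `rankings` (bound tibble over selectors),
#'   `performance` (tibble), and `fits`.
#' @export
run_selector_bank <- function(merged, specs = default_selector_specs(),
                              master_seed = 1L, positive = 1L) {
  stopifnot(inherits(merged, "merged_sets"))
  M <- length(specs)
  stopifnot(length(merged$sets) >= M + 1)
  test <- merged$sets$sid0
  fits <- vector("list", M)
  perf <- vector("list", M)
  for (i in seq_len(M)) {
    set_i <- merged$sets[[paste0("sid", i)]]
    fits[[i]] <- run_selector(set_i$x, set_i$y, specs[[i]],
                              seed = derive_seed(master_seed, 1000L + i))
    perf[[i]] <- evaluate_performance(fits[[i]], test$x, test$y, positive)
  }
  names(fits) <- vapply(specs, `[[`, "", "selector")
  list(
    rankings = bind_rows(lapply(fits, `[[`, "ranking")),
    performance = bind_rows(perf),
    fits = fits
  )
}
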