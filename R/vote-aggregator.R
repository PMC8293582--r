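# Weighted rank-vote aggregation ----------------------------------------
#
# The merge stage: the M ranked top-K lists are mapped onto a canonical
# feature space (after alias folding, e.g. a negatively-signed "adequate"
# dummy folded into its "inadequate" counterpart), and each list entry
# casts a vote. Three strategies: equal votes (voting1), per-rank feature
# weights w1 (voting2), and the joint weight w1[rank] * w2[selector]
# (voting3). The final ranking is the top-K features by total score.

#' Alias map folding encoded feature names into canonical names
#'
#' @param pairs Named character vector: `c(alias = "canonical")`. Canonical
#'   names must be fixed points (no chains).
#' @return An object of class `alias_map`.
#' @export
alias_map <- function(pairs = character()) {
  if (length(pairs) > 0) {
    stopifnot(!is.null(names(pairs)))
    chained <- intersect(unname(pairs), names(pairs))
    if (length(chained) > 0) {
      abort(paste("alias chains not allowed; canonical names must be fixed points:",
                  paste(chained, collapse = ", ")))
    }
  }
  structure(list(pairs = pairs), class = "alias_map")
}

#' Default alias map of the bundled example lists
#'
#' Folds the negatively-signed `PE_Adequate` dummy into its complementary
#' `PE_Inadequate` dummy — two encodings of the same physical-exercise
#' adequacy variable with opposite sign conventions.
#' @return An [alias_map()].
#' @export
default_alias_map <- function() alias_map(c(PE_Adequate = "PE_Inadequate"))

#' Canonicalize ranked lists and form the union feature space
#'
#' Feature names are mapped through the alias map; the canonical feature
#' space F is the sorted union of the resulting names. Per-list ranks are
#' unchanged; if aliasing makes two entries of one list share a canonical
#' name, both entries are kept and each contributes its own rank weight.
#'
#' @param lists Tibble of ranked-list entries with columns `selector`,
#'   `rank`, `feature` (and optionally `sign`, `importance`).
#' @param aliases An [alias_map()], or `NULL` for the identity.
#' @return List with `lists` (canonicalized tibble) and `feature_space`
#'   (sorted character vector F).
#' @export
canonicalize <- function(lists, aliases = NULL) {
  lists <- as_tibble(lists)
  stopifnot(nrow(lists) > 0, all(c("selector", "rank", "feature") %in% names(lists)))
  if (!is.null(aliases)) {
    stopifnot(inherits(aliases, "alias_map"))
    hit <- match(lists$feature, names(aliases$pairs))
    lists$feature <- ifelse(is.na(hit), lists$feature,
                            unname(aliases$pairs)[hit])
  }
  list(lists = lists, feature_space = sort(unique(lists$feature)))
}

#' Per-rank feature weights, linearly decreasing
#'
#' Rank k of a top-K list receives weight `K + 1 - k` (rank 1 gets K, rank
#' K gets 1). This is the package's default w1 scheme; Borda-style `1/k`
#' weights are available via [rank_weights_borda()] or any user-supplied
#' vector.
#'
#' @param K Top-K size.
#' @return Numeric vector of length K, `w1[k]` for rank k.
#' @export
rank_weights_linear <- function(K) K + 1 - seq_len(K)

#' @rdname rank_weights_linear
#' @export
rank_weights_borda <- function(K) 1 / seq_len(K)

#' Assign model (tier) weights from selector performance
#'
#' An explicit tier map takes precedence: model weights express judgement
#' about model properties as well as raw scores (e.g. a filter method may
#' be demoted for ignoring variable interactions despite good test
#' metrics). In `"auto"` mode selectors are ordered by the mean of
#' accuracy and F-score and grouped into tiers: a new tier starts whenever
#' the score drops more than `tol` below the current tier's best. Tier t
#' receives `ladder[t]` (last rung reused if there are more tiers than
#' rungs).
#'
#' @param performances Tibble with columns `selector`, `accuracy`,
#'   `f_score` (one row per selector); may be `NULL` when `tiers` is
#'   explicit.
#' @param tiers `"auto"`, or a named integer vector mapping selector to
#'   tier number (1 = best).
#' @param ladder Weights per tier, default `c(1, 0.5, 0.2)`.
#' @param tol Score tolerance for `"auto"` tiering, default 0.02.
#' @return Named numeric vector w2 (selector -> model weight).
#' @export
assign_model_weights <- function(performances = NULL, tiers = "auto",
                                 ladder = c(1, 0.5, 0.2), tol = 0.02) {
  stopifnot(all(ladder > 0))
  if (!identical(tiers, "auto")) {
    stopifnot(is.numeric(tiers), !is.null(names(tiers)))
    if (!is.null(performances)) {
      unknown <- setdiff(names(tiers), performances$selector)
      if (length(unknown) > 0) {
        abort(paste("tier map names unknown selector(s):",
                    paste(unknown, collapse = ", ")))
      }
    }
    t <- pmin(as.integer(tiers), length(ladder))
    return(setNames(ladder[t], names(tiers)))
  }
  stopifnot(is.data.frame(performances))
  score <- (performances$accuracy + performances$f_score) / 2
  ord <- order(-score)
  tier <- integer(length(score))
  cur <- 1L; best <- score[ord[1]]
  for (i in ord) {
    if (best - score[i] > tol) {
      cur <- cur + 1L
      best <- score[i]
    }
    tier[i] <- cur
  }
  setNames(ladder[pmin(tier, length(ladder))], performances$selector)
}

#' The published three-tier model weights for the five-method bank
#'
#' Lasso and ridge at weight 1, the MI filter and SVM-RFE at 0.5, and the
#' random forest at 0.2.
#' @return Named numeric vector w2.
#' @export
default_tier_weights <- function() {
  c(lasso = 1, ridge = 1, filter_mi = 0.5, svm_rfe = 0.5, random_forest = 0.2)
}

#' Tally weighted votes over canonicalized ranked lists
#'
#' Every list entry casts one vote for its canonical feature:
#' \describe{
#'   \item{voting1}{each entry contributes 1;}
#'   \item{voting2}{an entry of rank k contributes `w1[k]`;}
#'   \item{voting3}{an entry of rank k in selector j's list contributes
#'     `w1[k] * w2[j]`.}
#' }
#' Scores are summed per canonical feature over all lists. Signs do not
#' enter the arithmetic; they are carried for reporting only.
#'
#' @param canon Output of [canonicalize()] (or a plain ranked-list tibble,
#'   canonicalized with the identity map).
#' @param strategy `"voting1"`, `"voting2"` or `"voting3"`.
#' @param w1 Rank-weight vector (`w1[k]` for rank k); default
#'   [rank_weights_linear()] of the largest rank present. Unused by
#'   voting1.
#' @param w2 Named model-weight vector; required for voting3.
#' @return An object of class `vote_tally`: tibble with `feature`, `score`,
#'   `n_lists` (number of distinct supporting selectors), sorted by
#'   descending score then the tie-break of [select_top_k()]; attributes
#'   `strategy` and `feature_space`.
#' @export
tally_votes <- function(canon, strategy = c("voting3", "voting2", "voting1"),
                        w1 = NULL, w2 = NULL) {
  strategy <- match.arg(strategy)
  if (is.data.frame(canon)) canon <- canonicalize(canon)
  lists <- canon$lists
  K <- max(lists$rank)
  if (is.null(w1)) w1 <- rank_weights_linear(K)
  if (max(lists$rank) > length(w1)) abort("w1 does not cover every rank present")
  if (strategy == "voting3") {
    if (is.null(w2)) abort("voting3 needs model weights w2")
    missing_w2 <- setdiff(unique(lists$selector), names(w2))
    if (length(missing_w2) > 0) {
      abort(paste("w2 missing selector(s):", paste(missing_w2, collapse = ", ")))
    }
  }
  weight <- switch(strategy,
    voting1 = rep(1, nrow(lists)),
    voting2 = w1[lists$rank],
    voting3 = w1[lists$rank] * unname(w2[lists$selector])
  )
  tallied <- lists %>%
    mutate(.w = weight) %>%
    group_by(.data$feature) %>%
    summarise(score = sum(.data$.w),
              n_lists = dplyr::n_distinct(.data$selector),
              .groups = "drop") %>%
    arrange(desc(.data$score), desc(.data$n_lists), .data$feature)
  structure(tallied, class = c("vote_tally", class(tallied)),
            strategy = strategy, feature_space = canon$feature_space)
}

#' Extract the final top-K features from a tally
#'
#' Features are ordered by score descending; ties are broken by the number
#' of supporting lists (descending) then canonical name (ascending). If K
#' exceeds the feature space, all features are returned with a warning.
#'
#' @param tally A `vote_tally`.
#' @param K Number of features to return.
#' @return Tibble with `rank`, `feature`, `score`, `n_lists`.
#' @export
select_top_k <- function(tally, K = 10L) {
  stopifnot(inherits(tally, "vote_tally"), K >= 1)
  out <- arrange(as_tibble(tally), desc(.data$score), desc(.data$n_lists),
                 .data$feature)
  if (K > nrow(out)) {
    warn(sprintf("K = %d exceeds the %d-feature space: returning all", K, nrow(out)))
    K <- nrow(out)
  }
  out <- head(out, K)
  mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Tally all three voting strategies side by side
#'
#' @inheritParams tally_votes
#' @return Wide tibble with columns `feature`, `voting1`, `voting2`,
#'   `voting3`, sorted by descending `voting3`.
#' @export
vote_all_strategies <- function(canon, w1 = NULL, w2 = NULL) {
  if (is.data.frame(canon)) canon <- canonicalize(canon)
  t1 <- tally_votes(canon, "voting1", w1 = w1)
  t2 <- tally_votes(canon, "voting2", w1 = w1)
  t3 <- tally_votes(canon, "voting3", w1 = w1, w2 = w2)
  as_tibble(t1) %>%
    select("feature", voting1 = "score") %>%
    left_join(select(as_tibble(t2), "feature", voting2 = "score"), by = "feature") %>%
    left_join(select(as_tibble(t3), "feature", voting3 = "score"), by = "feature") %>%
    arrange(desc(.data$voting3), .data$feature)
}

#' Bundled example: five top-10 lists from a childhood-obesity cohort study
#'
#' The per-selector top-10 risk-factor lists (with effect signs) produced
#' by the five-method bank on a large restricted primary-care cohort,
#' shipped as a packaged fixture so the voting layer can be exercised and
#' demonstrated without the original data.
#'
#' @return Tibble with columns `selector`, `rank`, `feature`, `sign`.
#' @export
example_feature_lists <- function() {
  path <- system.file("extdata", "example_top10_lists.csv", package = "bfsmr",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "cicc")
}

#' @export
print.vote_tally <- function(x, ...) {
  cat(sprintf("<vote_tally: %s> %d features\n", attr(x, "strategy"), nrow(x)))
  NextMethod()
}

#' Score-share plot of a vote tally
#'
#' Shows each feature's share of the total voting score (percent of the
#' whole set), the standard way to visualize the ensemble's variable
#' importances.
#'
#' @param object A `vote_tally`.
#' @param top Show at most this many features (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vote_tally <- function(object, top = Inf, ...) {
  df <- as_tibble(object) %>%
    mutate(share = 100 * .data$score / sum(.data$score)) %>%
    arrange(desc(.data$share))
  if (is.finite(top)) df <- head(df, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$share,
    y = stats::reorder(.data$feature, .data$share)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "share of total voting score (%)", y = NULL,
      title = sprintf("Feature score shares (%s)", attr(object, "strategy"))
    ) +
    ggplot2::theme_minimal()
}
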