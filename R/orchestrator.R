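# End-to-end driver -----------------------------------------------------

#' Configuration of a full ensemble feature-selection run
#'
#' @param input A cohort file path, a `bfsmr_cohort`, or a
#'   [cohort_config()] (the cohort is then generated, missingness applied,
#'   and written to a temporary file so ingestion exercises the same
#'   streaming path as a real export).
#' @param schema A [feature_schema()]; derived automatically when the input
#'   is synthetic.
#' @param chunk_size Rows per chunk (default 10000).
#' @param split_ratio Train fraction per chunk (default 0.8).
#' @param bootstrap_frac Bootstrap sample size as a fraction of the train
#'   partition (default 0.1).
#' @param K Features per selector and in the final list (default 10).
#' @param selector_specs Named list of [selector_spec()]s (default the
#'   five-method bank).
#' @param strategy Primary voting strategy for the final list (default
#'   `"voting3"`); all three tallies are always computed.
#' @param tiers `"default"` (the three-tier weights of
#'   [default_tier_weights()], valid for the default bank), `"auto"`, or a
#'   named tier vector for [assign_model_weights()].
#' @param w1 Rank-weight vector (default [rank_weights_linear()]).
#' @param aliases An [alias_map()] or `NULL`.
#' @param percentile Outcome percentile (default 90).
#' @param positive Positive class for F-scores (default 1).
#' @param master_seed Integer master seed.
#' @return An object of class `bfsmr_config`.
#' @export
bfsmr_config <- function(input, schema = NULL, chunk_size = 10000L,
                         split_ratio = 0.8, bootstrap_frac = 0.1, K = 10L,
                         selector_specs = default_selector_specs(K),
                         strategy = c("voting3", "voting2", "voting1"),
                         tiers = "default", w1 = NULL, aliases = NULL,
                         percentile = 90, positive = 1L, master_seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(chunk_size >= 1, split_ratio > 0, split_ratio < 1,
            bootstrap_frac > 0, bootstrap_frac <= 1, K >= 1)
  ids <- vapply(selector_specs, `[[`, "", "selector")
  if (anyDuplicated(ids)) abort("selector ids must be unique within a run")
  structure(
    list(input = input, schema = schema, chunk_size = as.integer(chunk_size),
         split_ratio = split_ratio, bootstrap_frac = bootstrap_frac,
         K = as.integer(K), selector_specs = selector_specs,
         strategy = strategy, tiers = tiers, w1 = w1, aliases = aliases,
         percentile = percentile, positive = positive,
         master_seed = as.integer(master_seed)),
    class = "bfsmr_config"
  )
}

#' Run the full pipeline: ingest, map, reduce, evaluate, vote
#'
#' Streams the cohort in chunks, derives the stratified-percentile
#' outcome, encodes and imputes, draws per-chunk bootstrap samples, merges
#' them by set ID, runs the selector bank, evaluates every selector on the
#' shared test pool, assigns model weights, and fuses the ranked lists by
#' weighted voting. Fully deterministic given the master seed, and
#' invariant to chunk processing order (per-chunk derived seeds).
#'
#' @param config A [bfsmr_config()].
#' @return An object of class `bfsmr_result`: list with `rankings`,
#'   `performance`, `model_weights`, `tallies` (one `vote_tally` per
#'   strategy), `votes` (wide tibble over strategies), `top_features`,
#'   `truth` (for synthetic inputs) and `manifest`.
#' @export
run_bfsmr <- function(config) {
  stopifnot(inherits(config, "bfsmr_config"))
  input <- config$input
  truth <- NULL
  if (inherits(input, "cohort_config")) {
    coh <- inject_missingness(generate_cohort(input))
    input <- coh
  }
  if (inherits(input, "bfsmr_cohort")) {
    truth <- ground_truth(input)
    if (is.null(config$schema)) config$schema <- schema_from_config(input$config)
    path <- tempfile(fileext = ".csv")
    on.exit(unlink(path), add = TRUE)
    write_cohort(input, path)
    input <- path
  }
  if (is.null(config$schema)) abort("a feature schema is required for file inputs")

  ing <- ingest_cohort(input, config$schema, config$chunk_size, config$percentile)
  M <- length(config$selector_specs)
  assignments <- bind_rows(lapply(ing$chunks, map_chunk, M = M,
                                  split_ratio = config$split_ratio,
                                  frac = config$bootstrap_frac,
                                  master_seed = config$master_seed))
  if (nrow(assignments) == 0) abort("stage map: no usable chunks")
  merged <- shuffle_merge(assignments, ing$chunks)
  bank <- run_selector_bank(merged, config$selector_specs,
                            master_seed = config$master_seed,
                            positive = config$positive)
  w2 <- resolve_model_weights(config$tiers, bank$performance)
  canon <- canonicalize(bank$rankings, config$aliases)
  tallies <- lapply(
    setNames(nm = c("voting1", "voting2", "voting3")),
    function(s) tally_votes(canon, s, w1 = config$w1, w2 = w2)
  )
  top <- select_top_k(tallies[[config$strategy]], config$K)
  set_sizes <- vapply(merged$sets, function(s) nrow(s$x), integer(1))
  manifest <- list(
    n_rows = ing$n_rows, n_labelled = ing$n_labelled, n_dropped = ing$n_dropped,
    n_chunks = length(ing$chunks), set_sizes = set_sizes,
    n_test = length(merged$sets$sid0$y),
    test_positive_rate = mean(merged$sets$sid0$y),
    master_seed = config$master_seed, chunk_size = config$chunk_size,
    split_ratio = config$split_ratio, bootstrap_frac = config$bootstrap_frac,
    K = config$K, strategy = config$strategy,
    selectors = names(config$selector_specs)
  )
  structure(
    list(rankings = bank$rankings, performance = bank$performance,
         model_weights = w2, tallies = tallies,
         votes = vote_all_strategies(canon, w1 = config$w1, w2 = w2),
         top_features = top, truth = truth, manifest = manifest),
    class = "bfsmr_result"
  )
}

#' @noRd
resolve_model_weights <- function(tiers, performance) {
  if (identical(tiers, "default")) {
    w2 <- default_tier_weights()
    missing <- setdiff(performance$selector, names(w2))
    if (length(missing) > 0) {
      abort("`tiers = \"default\"` only covers the five-method bank; pass explicit tiers")
    }
    w2[performance$selector]
  } else if (identical(tiers, "auto")) {
    assign_model_weights(performance, "auto")
  } else {
    assign_model_weights(performance, tiers)
  }
}

#' Run the voting layer alone on prepared ranked lists
#'
#' Fixture mode: aggregates already-computed ranked lists (e.g. the
#' bundled [example_feature_lists()]) without any modelling. Runs in well
#' under a second.
#'
#' @param lists Ranked-list tibble (`selector`, `rank`, `feature`, ...).
#' @param w2 Named model-weight vector; default [default_tier_weights()]
#'   restricted to the selectors present.
#' @param w1 Rank-weight vector; default [rank_weights_linear()].
#' @param aliases An [alias_map()]; default [default_alias_map()].
#' @param K Final list size (default 10).
#' @return A `bfsmr_result` without performance/manifest model fields.
#' @export
vote_on_lists <- function(lists, w2 = NULL, w1 = NULL,
                          aliases = default_alias_map(), K = 10L) {
  canon <- canonicalize(lists, aliases)
  if (is.null(w2)) {
    w2 <- default_tier_weights()
    missing <- setdiff(unique(canon$lists$selector), names(w2))
    if (length(missing) > 0) {
      abort(paste("no default weight for selector(s):",
                  paste(missing, collapse = ", ")))
    }
  }
  tallies <- lapply(
    setNames(nm = c("voting1", "voting2", "voting3")),
    function(s) tally_votes(canon, s, w1 = w1, w2 = w2)
  )
  structure(
    list(rankings = as_tibble(lists), performance = NULL, model_weights = w2,
         tallies = tallies,
         votes = vote_all_strategies(canon, w1 = w1, w2 = w2),
         top_features = select_top_k(tallies$voting3, K),
         truth = NULL,
         manifest = list(mode = "vote-only", K = K,
                         selectors = unique(lists$selector))),
    class = "bfsmr_result"
  )
}

#' Write the result tables as delimited text
#'
#' Writes `rankings.csv` (per-selector ranked lists), `performance.csv`,
#' `vote_scores.csv` (feature by voting1/2/3, scores to one decimal),
#' `top_features.csv`, and `score_share.csv` (each feature's percentage of
#' the total score under the primary strategy, the quantity usually
#' visualized); optionally a score-share plot.
#'
#' @param result A `bfsmr_result`.
#' @param dir Output directory (created if needed).
#' @param plot Also save `score_share.pdf` (default FALSE).
#' @return The directory, invisibly.
#' @export
export_report <- function(result, dir, plot = FALSE) {
  stopifnot(inherits(result, "bfsmr_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(result$rankings, file.path(dir, "rankings.csv"), na = "")
  if (!is.null(result$performance)) {
    readr::write_csv(result$performance, file.path(dir, "performance.csv"))
  }
  votes <- mutate(result$votes, across(dplyr::starts_with("voting"),
                                       ~ round(.x, 1)))
  readr::write_csv(votes, file.path(dir, "vote_scores.csv"))
  readr::write_csv(result$top_features, file.path(dir, "top_features.csv"))
  primary <- result$manifest$strategy %||% "voting3"
  tal <- as_tibble(result$tallies[[primary]])
  share <- mutate(tal, share_pct = round(100 * .data$score / sum(.data$score), 2))
  readr::write_csv(share, file.path(dir, "score_share.csv"))
  if (plot) {
    ggplot2::ggsave(file.path(dir, "score_share.pdf"),
                    autoplot.vote_tally(result$tallies[[primary]]),
                    width = 7, height = 8)
  }
  invisible(dir)
}

# Broom-style accessors --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result
#'
#' @param x A `bfsmr_result`.
#' @param type `"votes"` (wide per-feature scores, default), `"top"`
#'   (final top-K), `"rankings"` (per-selector lists), or `"performance"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bfsmr_result <- function(x, type = c("votes", "top", "rankings",
                                          "performance"), ...) {
  type <- match.arg(type)
  switch(type,
    votes = x$votes,
    top = x$top_features,
    rankings = x$rankings,
    performance = x$performance %||% tibble()
  )
}

#' One-row summary of a pipeline result
#'
#' @param x A `bfsmr_result`.
#' @param ... Unused.
#' @return A one-row tibble with run sizes and the best accuracy/F-score.
#' @export
glance.bfsmr_result <- function(x, ...) {
  m <- x$manifest
  tibble(
    n_rows = m$n_rows %||% NA_integer_,
    n_labelled = m$n_labelled %||% NA_integer_,
    n_dropped = m$n_dropped %||% NA_integer_,
    n_chunks = m$n_chunks %||% NA_integer_,
    n_selectors = length(m$selectors),
    K = m$K,
    strategy = m$strategy %||% "voting3",
    best_accuracy = if (is.null(x$performance)) NA_real_ else max(x$performance$accuracy),
    best_f_score = if (is.null(x$performance)) NA_real_ else max(x$performance$f_score)
  )
}

#' @export
autoplot.bfsmr_result <- function(object, top = 30, ...) {
  primary <- object$manifest$strategy %||% "voting3"
  autoplot.vote_tally(object$tallies[[primary]], top = top)
}

#' @export
print.bfsmr_result <- function(x, ...) {
  cat(sprintf("<bfsmr_result> %d selectors, primary strategy %s\n",
              length(x$manifest$selectors),
              x$manifest$strategy %||% "voting3"))
  cat("Top features:\n")
  print(x$top_features, n = min(10, nrow(x$top_features)))
  invisible(x)
}
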