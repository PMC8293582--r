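# Shared test helpers: small hand-built chunks, random ranked lists, and a
# brute-force voting oracle independent of the package's tally code.

make_chunk <- function(n, p = 3, seed = 1, chunk_index = 0L, labels = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  structure(
    list(matrix = m,
         labels = labels %||% rbinom(n, 1, 0.5),
         feature_names = colnames(m),
         chunk_index = as.integer(chunk_index),
         n_dropped = 0L),
    class = "bfsmr_chunk"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_ranked_lists <- function(M, K, n_features = 8, seed = 1) {
  set.seed(seed)
  pool <- paste0("v", seq_len(max(n_features, K)))
  dplyr::bind_rows(lapply(seq_len(M), function(j) {
    tibble::tibble(
      selector = paste0("sel", j),
      rank = seq_len(K),
      feature = sample(pool, K)
    )
  }))
}

# Independent oracle: explicit double sum over (list j, rank k).
brute_force_tally <- function(lists, strategy, w1 = NULL, w2 = NULL) {
  K <- max(lists$rank)
  if (is.null(w1)) w1 <- K + 1 - seq_len(K)
  scores <- list()
  for (i in seq_len(nrow(lists))) {
    f <- lists$feature[i]
    w <- switch(strategy,
      voting1 = 1,
      voting2 = w1[lists$rank[i]],
      voting3 = w1[lists$rank[i]] * w2[[lists$selector[i]]]
    )
    scores[[f]] <- (scores[[f]] %||% 0) + w
  }
  tibble::tibble(feature = names(scores),
                 score = unname(unlist(scores)))
}

# Label a generated cohort by its empirical stratified nearest-rank
# percentile, independently of the ingest code path.
stratum_labels <- function(records, percentile = 90) {
  key <- paste(records$age, records$sex)
  thr <- tapply(records$bmi, key, function(v) {
    sort(v)[max(1, ceiling(percentile / 100 * length(v)))]
  })
  as.integer(records$bmi > thr[key])
}
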