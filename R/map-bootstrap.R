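# Map / shuffle stages --------------------------------------------------
#
# Per chunk: a random train/test split, then M with-replacement samples
# from the train partition tagged with set IDs 1..M; the untouched test
# partition is emitted once as set ID 0. Sets with the same ID are merged
# across chunks into the inputs of the selector (Reduce) stage.

#' Draw per-chunk bootstrap sample assignments
#'
#' The chunk is split into a test partition of `round((1 - split_ratio) * n)`
#' rows and a train partition with the rest. `M` independent
#' with-replacement samples of `floor(frac * train size)` rows are drawn
#' from the train partition (set IDs 1..M); the full test partition is
#' emitted as set ID 0. The RNG is seeded from `(master_seed, chunk_index)`
#' so the result does not depend on chunk processing order.
#'
#' @param chunk A `bfsmr_chunk`.
#' @param M Number of bootstrapped samples (one per selector).
#' @param split_ratio Train fraction, in (0, 1); default 0.8.
#' @param frac Bootstrap sample size as a fraction of the train partition,
#'   in (0, 1]; default 0.1. `frac = 1` is classic bagging.
#' @param master_seed Run master seed.
#' @return Tibble with columns `sid`, `chunk_index`, `row_indices` (list
#'   column of row positions within the chunk, with multiplicity for the
#'   bootstrap draws). A chunk with fewer than `M + 1` rows is skipped with
#'   a warning (zero-row result).
#' @export
map_chunk <- function(chunk, M, split_ratio = 0.8, frac = 0.1, master_seed = 1L) {
  stopifnot(inherits(chunk, "bfsmr_chunk"))
  stopifnot(split_ratio > 0, split_ratio < 1, frac > 0, frac <= 1, M >= 1)
  n <- nrow(chunk$matrix)
  if (n < M + 1) {
    warn(sprintf("chunk %d has %d rows (< M + 1 = %d): skipped",
                 chunk$chunk_index, n, M + 1))
    return(tibble(sid = integer(), chunk_index = integer(), row_indices = list()))
  }
  with_seed(derive_seed(master_seed, chunk$chunk_index), {
    n_test <- round((1 - split_ratio) * n)
    test_idx <- sort(sample.int(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)
    size <- floor(frac * length(train_idx))
    draws <- lapply(seq_len(M), function(s) {
      train_idx[sample.int(length(train_idx), size, replace = TRUE)]
    })
    tibble(
      sid = 0:M,
      chunk_index = chunk$chunk_index,
      row_indices = c(list(test_idx), draws)
    )
  })
}

#' Merge sample assignments across chunks by set ID
#'
#' The shuffle step: for every set ID, rows referenced by the assignments
#' are stacked in canonical (chunk_index, draw order), pooling each sid's
#' sample over all chunks. With per-chunk seeding this makes the merged
#' sets invariant to chunk processing order.
#'
#' @param assignments Row-bound output of [map_chunk()] over all chunks.
#' @param chunks List of the corresponding `bfsmr_chunk` objects.
#' @return An object of class `merged_sets`: list with `sets` (named list
#'   `sid0`, `sid1`, ... of `list(x = matrix, y = labels)`) and
#'   `feature_names`.
#' @export
shuffle_merge <- function(assignments, chunks) {
  stopifnot(is.data.frame(assignments))
  by_index <- setNames(chunks, vapply(chunks, function(c) as.character(c$chunk_index),
                                      character(1)))
  assignments <- arrange(assignments, .data$sid, .data$chunk_index)
  sids <- sort(unique(assignments$sid))
  sets <- lapply(sids, function(s) {
    rows <- assignments[assignments$sid == s, ]
    xs <- vector("list", nrow(rows)); ys <- vector("list", nrow(rows))
    for (i in seq_len(nrow(rows))) {
      ch <- by_index[[as.character(rows$chunk_index[i])]]
      idx <- rows$row_indices[[i]]
      xs[[i]] <- ch$matrix[idx, , drop = FALSE]
      ys[[i]] <- ch$labels[idx]
    }
    list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE))
  })
  names(sets) <- paste0("sid", sids)
  fn <- if (length(chunks) > 0) chunks[[1]]$feature_names else character()
  structure(list(sets = sets, feature_names = fn), class = "merged_sets")
}

#' @export
print.merged_sets <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) nrow(s$x), integer(1))
  cat(sprintf("<merged_sets> %s\n",
              paste(sprintf("%s: %d rows", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}
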