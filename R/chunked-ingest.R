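# Chunked ingestion -----------------------------------------------------
#
# The cohort file is never loaded whole. A first streaming pass accumulates
# per-stratum BMI values (for the percentile thresholds) and the observed
# categorical levels (the level registry); a second pass turns each raw
# block into an encoded, imputed, labelled Chunk.

#' Declare the raw columns of a cohort file
#'
#' @param entries Tibble with columns `raw_name`, `kind` (one of
#'   `"identifier"`, `"numeric"`, `"categorical"`, `"outcome_source"`),
#'   `levels` (list column of character vectors, `NULL` to discover levels
#'   in the reference pass) and `impute_policy` (`"median"` for numerics,
#'   `"zero"` dummy row for categoricals).
#' @return An object of class `feature_schema`.
#' @details Exactly one outcome-source group must be present: either the
#'   three columns `bmi`, `age`, `sex` (kind `outcome_source`) from which
#'   the binary outcome is derived, or a single pre-computed outcome column.
#' @export
feature_schema <- function(entries) {
  entries <- as_tibble(entries)
  stopifnot(all(c("raw_name", "kind", "levels", "impute_policy") %in% names(entries)))
  if (anyDuplicated(entries$raw_name)) abort("duplicate raw column names in schema")
  bad <- setdiff(entries$kind, c("identifier", "numeric", "categorical", "outcome_source"))
  if (length(bad) > 0) abort(paste("unknown schema kind:", paste(bad, collapse = ", ")))
  n_src <- sum(entries$kind == "outcome_source")
  if (!n_src %in% c(1L, 3L)) {
    abort("schema needs one outcome-source group: (bmi, age, sex) or one outcome column")
  }
  structure(list(entries = entries), class = "feature_schema")
}

#' Build a schema matching a synthetic cohort's column layout
#'
#' @param config A [cohort_config()].
#' @return A [feature_schema()] whose feature kinds and declared levels
#'   mirror the generator's `feature_specs`.
#' @export
schema_from_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$feature_specs
  feats <- tibble(
    raw_name = specs$name,
    kind = specs$kind,
    levels = lapply(seq_len(nrow(specs)), function(i) {
      if (specs$kind[i] == "categorical") level_names(specs$n_levels[i]) else NULL
    }),
    impute_policy = ifelse(specs$kind == "numeric", "median", "zero")
  )
  head_cols <- tibble(
    raw_name = c("child_id", "age", "sex", "bmi"),
    kind = c("identifier", "outcome_source", "outcome_source", "outcome_source"),
    levels = list(NULL, NULL, NULL, NULL),
    impute_policy = NA_character_
  )
  feature_schema(bind_rows(head_cols, feats))
}

#' Write / read a schema as delimited text
#'
#' Levels are stored semicolon-separated so the schema round-trips through
#' a plain csv config file.
#' @param schema A [feature_schema()].
#' @param path File path.
#' @return `path` (write) or a [feature_schema()] (read).
#' @export
write_feature_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  flat <- mutate(schema$entries, levels = vapply(
    .data$levels, function(l) paste(l %||% character(), collapse = ";"), character(1)
  ))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' @rdname write_feature_schema
#' @export
read_feature_schema <- function(path) {
  flat <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  flat$levels <- lapply(flat$levels, function(s) {
    if (is.na(s) || !nzchar(s)) NULL else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  feature_schema(flat)
}

#' Stream a delimited cohort file in fixed-size blocks
#'
#' Every input row lands in exactly one block, in file order; all blocks
#' have `chunk_size` rows except possibly the last. With a `callback`,
#' blocks are processed one at a time and never accumulated, which is the
#' memory-bounded mode; without one, the list of blocks is returned (desk
#' scale convenience).
#'
#' @param path Delimited text file with a header row; empty fields are
#'   missing values.
#' @param chunk_size Rows per block, at least 1.
#' @param callback Optional `function(block, chunk_index)`; its results are
#'   collected into a list.
#' @param delim Field delimiter, default comma.
#' @return List of tibbles (or of callback results), possibly empty.
#' @export
stream_chunks <- function(path, chunk_size = 10000L, callback = NULL, delim = ",") {
  if (!file.exists(path)) abort(paste("no such file:", path))
  stopifnot(chunk_size >= 1)
  out <- list()
  idx <- 0L
  cb <- readr::DataFrameCallback$new(function(block, pos) {
    prob <- readr::problems(block)
    if (nrow(prob) > 0) {
      abort(sprintf("malformed input at row %d of %s: %s",
                    prob$row[1], path, prob$expected[1]))
    }
    if (nrow(block) == 0) return(NULL)
    block <- as_tibble(block)
    res <- if (is.null(callback)) block else callback(block, idx)
    out[[idx + 1L]] <<- res
    idx <<- idx + 1L
    NULL
  })
  readr::read_delim_chunked(
    path, cb, delim = delim, chunk_size = chunk_size,
    col_types = readr::cols(.default = readr::col_guess()),
    na = "", progress = FALSE, show_col_types = FALSE,
    guess_max = chunk_size
  )
  out
}

#' First-pass reference: stratified BMI thresholds and level registry
#'
#' Computes, per (age, sex) stratum, the nearest-rank BMI percentile that
#' defines the overweight outcome, and records the observed levels of each
#' categorical feature (the level registry used to freeze dummy columns).
#' Strata with fewer than 10 records fall back to the pooled threshold with
#' a warning.
#'
#' @param blocks List of raw blocks (from [stream_chunks()]), or a single
#'   tibble, or a file path (streamed internally).
#' @param schema A [feature_schema()].
#' @param percentile Percentile in (0, 100); default 90 (overweight
#'   definition: BMI strictly above the stratum's 90th percentile).
#' @param chunk_size Used only when `blocks` is a path.
#' @return An object of class `outcome_reference` with elements `strata`
#'   (tibble: age, sex, threshold, n), `pooled` (numeric), `percentile`,
#'   and `registry` (named list of level vectors).
#' @export
build_outcome_reference <- function(blocks, schema, percentile = 90,
                                    chunk_size = 10000L) {
  stopifnot(percentile > 0, percentile < 100)
  if (is.character(blocks)) blocks <- stream_chunks(blocks, chunk_size)
  if (is.data.frame(blocks)) blocks <- list(blocks)

  cat_cols <- schema$entries$raw_name[schema$entries$kind == "categorical"]
  declared <- setNames(schema$entries$levels, schema$entries$raw_name)[cat_cols]

  acc <- list()   # per-stratum BMI accumulation (exact; desk scale)
  registry <- lapply(declared, function(l) l %||% character())
  for (block in blocks) {
    keep <- !(is.na(block$bmi) | is.na(block$age) | is.na(block$sex))
    b <- block[keep, , drop = FALSE]
    if (nrow(b) > 0) {
      key <- paste(b$age, b$sex, sep = "\r")
      sp <- split(b$bmi, key)
      for (k in names(sp)) acc[[k]] <- c(acc[[k]], sp[[k]])
    }
    for (cc in cat_cols) {
      obs <- unique(as.character(block[[cc]]))
      registry[[cc]] <- union(registry[[cc]], obs[!is.na(obs)])
    }
  }
  registry <- lapply(registry, sort)

  if (length(acc) == 0) abort("no records with complete bmi/age/sex")
  pooled <- nearest_rank_percentile(unlist(acc, use.names = FALSE), percentile)
  parts <- strsplit(names(acc), "\r", fixed = TRUE)
  strata <- tibble(
    age = as.integer(vapply(parts, `[[`, "", 1)),
    sex = vapply(parts, `[[`, "", 2),
    n = unname(vapply(acc, length, integer(1))),
    threshold = unname(vapply(acc, nearest_rank_percentile, numeric(1),
                              p = percentile))
  )
  small <- strata$n < 10
  if (any(small)) {
    warn(sprintf(
      "%d stratum(s) with fewer than 10 records: using pooled threshold %.3f",
      sum(small), pooled
    ))
    strata$threshold[small] <- pooled
  }
  strata <- arrange(strata, .data$age, .data$sex)
  structure(
    list(strata = strata, pooled = pooled, percentile = percentile,
         registry = registry),
    class = "outcome_reference"
  )
}

#' Derive binary overweight labels for one raw block
#'
#' A record is labelled 1 when its BMI is strictly greater than its (age,
#' sex) stratum's threshold. Records with missing BMI, age or sex cannot be
#' labelled and are dropped; the count is recorded in the `dropped`
#' attribute and reported.
#'
#' @param block Raw tibble with `bmi`, `age`, `sex` columns.
#' @param ref An `outcome_reference`.
#' @return The retained rows with an added integer column `.outcome`;
#'   attribute `dropped` holds the number of removed records.
#' @export
derive_labels <- function(block, ref) {
  stopifnot(inherits(ref, "outcome_reference"))
  keep <- !(is.na(block$bmi) | is.na(block$age) | is.na(block$sex))
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("dropped %d record(s) with missing bmi/age/sex", n_drop))
  }
  b <- block[keep, , drop = FALSE]
  idx <- match(paste(b$age, b$sex), paste(ref$strata$age, ref$strata$sex))
  thr <- ref$strata$threshold[idx]
  thr[is.na(thr)] <- ref$pooled
  b$.outcome <- as.integer(b$bmi > thr)
  attr(b, "dropped") <- n_drop
  b
}

#' Encode and impute one labelled block into a Chunk
#'
#' Categorical features expand to one dummy column per registry level (a
#' missing category is the all-zero row; a level unseen at registry freeze
#' maps to all-zeros with a note). Numeric missing values are imputed by
#' the chunk median (0 if the whole chunk column is missing). Column order
#' is schema order with registry-ordered levels, identical for every chunk
#' of a run.
#'
#' @param block Output of [derive_labels()] (has `.outcome`).
#' @param schema A [feature_schema()].
#' @param ref The `outcome_reference` carrying the level registry.
#' @param chunk_index Zero-based index of this chunk.
#' @return An object of class `bfsmr_chunk`: list with numeric `matrix`
#'   (records x encoded features), integer `labels`, `feature_names`,
#'   `chunk_index`, `n_dropped`.
#' @export
encode_and_impute <- function(block, schema, ref, chunk_index = 0L) {
  stopifnot(".outcome" %in% names(block))
  ent <- schema$entries
  cols <- list()
  for (i in seq_len(nrow(ent))) {
    nm <- ent$raw_name[i]
    if (ent$kind[i] == "numeric") {
      v <- as.numeric(block[[nm]])
      if (anyNA(v)) {
        med <- median(v, na.rm = TRUE)
        if (is.na(med)) med <- 0
        v[is.na(v)] <- med
      }
      cols[[nm]] <- v
    } else if (ent$kind[i] == "categorical") {
      levs <- ref$registry[[nm]] %||% character()
      raw <- as.character(block[[nm]])
      unseen <- !is.na(raw) & !(raw %in% levs)
      if (any(unseen)) {
        inform(sprintf("chunk %d: %d value(s) of %s outside the frozen level registry encoded as all-zero",
                       chunk_index, sum(unseen), nm))
      }
      for (lv in levs) {
        cols[[paste(nm, lv, sep = "_")]] <- as.numeric(!is.na(raw) & raw == lv)
      }
    }
  }
  mat <- do.call(cbind, cols)
  if (is.null(mat)) mat <- matrix(numeric(), nrow = nrow(block), ncol = 0)
  colnames(mat) <- names(cols)
  structure(
    list(
      matrix = mat,
      labels = as.integer(block$.outcome),
      feature_names = names(cols),
      chunk_index = as.integer(chunk_index),
      n_dropped = attr(block, "dropped") %||% 0L
    ),
    class = "bfsmr_chunk"
  )
}

#' Two-pass ingestion of a cohort file into encoded chunks
#'
#' Pass 1 builds the outcome reference (stratified percentile thresholds)
#' and the categorical level registry; pass 2 labels, encodes and imputes
#' each block. Convenience wrapper used by [run_bfsmr()].
#'
#' @inheritParams stream_chunks
#' @inheritParams build_outcome_reference
#' @param external_ref Optional pre-built `outcome_reference` (e.g. from an
#'   external reference population); skips pass 1's threshold estimation.
#' @return List with `chunks` (list of `bfsmr_chunk`), `ref`, and counting
#'   fields `n_rows`, `n_labelled`, `n_dropped`.
#' @export
ingest_cohort <- function(path, schema, chunk_size = 10000L, percentile = 90,
                          delim = ",", external_ref = NULL) {
  blocks <- stream_chunks(path, chunk_size, delim = delim)
  ref <- external_ref %||% build_outcome_reference(blocks, schema, percentile)
  chunks <- vector("list", length(blocks))
  n_rows <- 0L; n_drop <- 0L; n_lab <- 0L
  for (i in seq_along(blocks)) {
    lb <- derive_labels(blocks[[i]], ref)
    ch <- encode_and_impute(lb, schema, ref, chunk_index = i - 1L)
    n_rows <- n_rows + nrow(blocks[[i]])
    n_drop <- n_drop + ch$n_dropped
    n_lab <- n_lab + length(ch$labels)
    chunks[[i]] <- ch
  }
  list(chunks = chunks, ref = ref,
       n_rows = n_rows, n_labelled = n_lab, n_dropped = n_drop)
}

#' @export
print.outcome_reference <- function(x, ...) {
  cat(sprintf("<outcome_reference> %dth percentile, %d strata, pooled threshold %.3f\n",
              round(x$percentile), nrow(x$strata), x$pooled))
  invisible(x)
}

#' @export
print.bfsmr_chunk <- function(x, ...) {
  cat(sprintf("<bfsmr_chunk %d> %d records x %d encoded features, %d positives\n",
              x$chunk_index, nrow(x$matrix), ncol(x$matrix), sum(x$labels)))
  invisible(x)
}
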