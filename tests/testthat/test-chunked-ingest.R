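# Chunked ingestion: streaming block arithmetic, nearest-rank thresholds,
# strict-inequality labelling, encoding/imputation, and row conservation.

write_toy_file <- function(n, path) {
  df <- tibble::tibble(
    child_id = seq_len(n),
    age = rep_len(5:6, n),
    sex = rep_len(c("F", "M"), n),
    bmi = 15 + (seq_len(n) %% 7)
  )
  readr::write_csv(df, path, na = "")
  df
}

test_that("streaming splits a file into full blocks plus a short tail", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_file(148857, path)
  blocks <- stream_chunks(path, chunk_size = 10000)
  expect_length(blocks, 15)
  expect_true(all(vapply(blocks[1:14], nrow, integer(1)) == 10000))
  expect_equal(nrow(blocks[[15]]), 8857)
  # every row exactly once, in file order
  ids <- unlist(lapply(blocks, function(b) b$child_id))
  expect_equal(ids, seq_len(148857), ignore_attr = TRUE)
})

test_that("short and empty files stream correctly", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_file(10, path)
  expect_length(stream_chunks(path, chunk_size = 10000), 1)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("child_id,age,sex,bmi", empty)
  expect_length(stream_chunks(empty, chunk_size = 100), 0)
  expect_error(stream_chunks("no/such/file.csv"), "no such file")
})

test_that("nearest-rank percentile matches its definition and a sort-based oracle", {
  expect_equal(nearest_rank_percentile(1:10, 90), 9)
  expect_equal(nearest_rank_percentile(rep(3.5, 50), 90), 3.5)
  set.seed(11)
  x <- rnorm(1000, mean = 17, sd = 2)
  oracle <- sort(x)[ceiling(0.9 * 1000)]
  expect_equal(nearest_rank_percentile(x, 90), oracle)
})

test_that("outcome reference thresholds are per-stratum nearest-rank percentiles", {
  block <- tibble::tibble(
    child_id = 1:20,
    age = rep(c(5L, 6L), each = 10),
    sex = "F",
    bmi = c(1:10, 21:30)
  )
  schema <- feature_schema(tibble::tibble(
    raw_name = c("child_id", "age", "sex", "bmi"),
    kind = c("identifier", rep("outcome_source", 3)),
    levels = list(NULL, NULL, NULL, NULL),
    impute_policy = NA_character_
  ))
  ref <- build_outcome_reference(block, schema, percentile = 90)
  expect_equal(ref$strata$threshold[ref$strata$age == 5], 9)
  expect_equal(ref$strata$threshold[ref$strata$age == 6], 29)

  labelled <- derive_labels(block, ref)
  # strict >: BMI equal to the threshold is not overweight
  expect_equal(sum(labelled$.outcome[labelled$age == 5]), 1)
  expect_equal(labelled$.outcome[labelled$bmi == 9], 0)
  expect_equal(labelled$.outcome[labelled$bmi == 10], 1)
})

test_that("tiny strata fall back to the pooled threshold with a warning", {
  block <- tibble::tibble(
    child_id = 1:105,
    age = c(rep(5L, 100), rep(17L, 5)),
    sex = "M",
    bmi = c(rnorm(100, 16), rnorm(5, 22))
  )
  schema <- feature_schema(tibble::tibble(
    raw_name = c("child_id", "age", "sex", "bmi"),
    kind = c("identifier", rep("outcome_source", 3)),
    levels = list(NULL, NULL, NULL, NULL),
    impute_policy = NA_character_
  ))
  expect_warning(ref <- build_outcome_reference(block, schema), "pooled")
  expect_equal(ref$strata$threshold[ref$strata$age == 17], ref$pooled)
})

test_that("records without bmi/age/sex are dropped and counted", {
  block <- tibble::tibble(
    child_id = 1:6,
    age = c(5L, 5L, NA, 5L, 5L, 5L),
    sex = c("F", "F", "F", NA, "F", "F"),
    bmi = c(15, NA, 15, 15, 16, 30)
  )
  ref <- structure(
    list(strata = tibble::tibble(age = 5L, sex = "F", n = 4L, threshold = 20),
         pooled = 20, percentile = 90, registry = list()),
    class = "outcome_reference"
  )
  labelled <- suppressMessages(derive_labels(block, ref))
  expect_equal(nrow(labelled), 3)
  expect_equal(attr(labelled, "dropped"), 3)
  expect_equal(labelled$.outcome, c(0L, 0L, 1L))
})

test_that("encoding expands categoricals over the frozen registry and imputes medians", {
  block <- tibble::tibble(
    child_id = 1:4, age = 5L, sex = "F", bmi = c(15, 16, 17, 30),
    num = c(1, NA, 3, 5),
    cat = c("A", "B", NA, "Z"),
    .outcome = c(0L, 0L, 0L, 1L)
  )
  attr(block, "dropped") <- 0L
  schema <- feature_schema(tibble::tibble(
    raw_name = c("child_id", "age", "sex", "bmi", "num", "cat"),
    kind = c("identifier", rep("outcome_source", 3), "numeric", "categorical"),
    levels = list(NULL, NULL, NULL, NULL, NULL, c("A", "B", "C")),
    impute_policy = c(NA, NA, NA, NA, "median", "zero")
  ))
  ref <- structure(
    list(strata = tibble::tibble(age = 5L, sex = "F", n = 4L, threshold = 20),
         pooled = 20, percentile = 90,
         registry = list(cat = c("A", "B", "C"))),
    class = "outcome_reference"
  )
  ch <- suppressMessages(encode_and_impute(block, schema, ref, chunk_index = 2L))
  expect_s3_class(ch, "bfsmr_chunk")
  expect_equal(ch$feature_names, c("num", "cat_A", "cat_B", "cat_C"))
  expect_equal(ch$matrix[, "num"], c(1, 3, 3, 5))  # chunk median imputation
  expect_equal(unname(ch$matrix[1, c("cat_A", "cat_B", "cat_C")]), c(1, 0, 0))
  expect_equal(unname(ch$matrix[2, c("cat_A", "cat_B", "cat_C")]), c(0, 1, 0))
  # missing category and unseen level are both all-zero rows
  expect_equal(unname(rowSums(ch$matrix[3:4, c("cat_A", "cat_B", "cat_C")])), c(0, 0))
  expect_false(anyNA(ch$matrix))
  expect_equal(ch$labels, c(0L, 0L, 0L, 1L))
  # determinism
  ch2 <- suppressMessages(encode_and_impute(block, schema, ref, chunk_index = 2L))
  expect_identical(ch$matrix, ch2$matrix)
})

test_that("two-pass ingestion conserves rows and keeps column order stable", {
  cfg <- cohort_config(2500, 1000, effect_map = c(Tobacco_lv2 = 3),
                       master_seed = 13)
  coh <- inject_missingness(generate_cohort(cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  ing <- ingest_cohort(path, schema_from_config(cfg), chunk_size = 600)
  expect_length(ing$chunks, 5)
  expect_equal(ing$n_rows, 2500)
  expect_equal(ing$n_labelled + ing$n_dropped, ing$n_rows)
  name_sets <- unique(lapply(ing$chunks, `[[`, "feature_names"))
  expect_length(name_sets, 1)  # identical encoded column order in every chunk
  for (ch in ing$chunks) expect_false(anyNA(ch$matrix))
  # per-stratum prevalence bounded by (100 - percentile)/100 plus tie slack
  y <- unlist(lapply(ing$chunks, `[[`, "labels"))
  expect_lte(mean(y), 0.1 + 0.01)
})
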