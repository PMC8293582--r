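# Synthetic cohort generation -------------------------------------------
#
# Emulates a large primary-care cohort: one row per visit record, several
# records per child across ages 1-18, mixed numeric/categorical lifestyle
# and vitals variables with block-wise missingness, and a BMI whose
# age/sex-stratified upper tail defines the overweight outcome. Planted
# effects give ground truth for recovery tests.

#' Declare the feature columns of a synthetic cohort
#'
#' @param name Feature name (must be a valid column name).
#' @param kind `"numeric"` or `"categorical"`.
#' @param n_levels Number of levels for a categorical feature (ignored for
#'   numeric features). Levels are named `lv1`, `lv2`, ...
#' @param missing_rate Per-cell probability that the value is missing, in
#'   `[0, 1]`. Vitals-like variables are typically near 0, lifestyle
#'   questionnaire variables 0.3-0.7, rare forms above 0.8.
#' @return A one-row tibble; rows from several calls are combined with
#'   [dplyr::bind_rows()] into the `feature_specs` of [cohort_config()].
#' @export
feature_spec <- function(name, kind = c("numeric", "categorical"),
                         n_levels = NA_integer_, missing_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (kind == "categorical" && (is.na(n_levels) || n_levels < 2)) {
    abort("categorical features need `n_levels` >= 2")
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate > 1) {
    abort("`missing_rate` must lie in [0, 1]")
  }
  tibble(
    name = name, kind = kind,
    n_levels = if (kind == "categorical") as.integer(n_levels) else NA_integer_,
    missing_rate = as.numeric(missing_rate)
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles the sizes, feature declarations, planted effects and seed that
#' define one reproducible synthetic cohort. Planted effects act on the BMI
#' linear predictor: a numeric feature's key is its name, a categorical
#' level's key is its dummy-column name (`<feature>_<level>`, e.g.
#' `Diet_lv2`). Effect units are kg/m^2 of BMI per standard deviation of a
#' numeric feature, or per level indicator.
#'
#' @param n_records Total number of visit records.
#' @param n_children Number of distinct children; every child receives at
#'   least one record, extra records are assigned uniformly.
#' @param feature_specs Tibble from [feature_spec()] rows.
#' @param effect_map Named numeric vector of planted effect sizes. May be
#'   empty (a pure-noise cohort).
#' @param age_range Integer vector of length 2, inclusive age span in years.
#' @param bmi_noise_sd Standard deviation (kg/m^2) of the Gaussian BMI noise
#'   around the stratum baseline plus linear predictor.
#' @param master_seed Integer seed; every random stage derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_records, n_children,
                          feature_specs = default_feature_specs(),
                          effect_map = numeric(),
                          age_range = c(1L, 18L),
                          bmi_noise_sd = 2,
                          master_seed = 1L) {
  stopifnot(n_records >= n_children, n_children >= 1)
  stopifnot(length(age_range) == 2, age_range[1] >= 1, age_range[2] >= age_range[1])
  specs <- as_tibble(feature_specs)
  needed <- c("name", "kind", "n_levels", "missing_rate")
  if (!all(needed %in% names(specs))) {
    abort("`feature_specs` needs columns name, kind, n_levels, missing_rate")
  }
  if (anyDuplicated(specs$name)) abort("duplicate feature names in `feature_specs`")
  valid_keys <- effect_keys(specs)
  bad <- setdiff(names(effect_map), valid_keys)
  if (length(bad) > 0) {
    abort(paste0(
      "effect_map keys not matching any declared feature or level: ",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(
      n_records = as.integer(n_records),
      n_children = as.integer(n_children),
      feature_specs = specs,
      effect_map = effect_map,
      age_range = as.integer(age_range),
      bmi_noise_sd = bmi_noise_sd,
      master_seed = as.integer(master_seed)
    ),
    class = "cohort_config"
  )
}

#' Default feature set of the synthetic cohort
#'
#' A desk-scale stand-in for a primary-care variable panel: a block of
#' near-complete numeric vitals, a block of lifestyle variables with
#' moderate-to-high missingness, and a couple of rare-form categoricals
#' with extreme missingness.
#'
#' @return A tibble of [feature_spec()] rows.
#' @export
default_feature_specs <- function() {
  bind_rows(
    feature_spec("SystolicPressure", "numeric", missing_rate = 0.01),
    feature_spec("DiastolicPressure", "numeric", missing_rate = 0.01),
    feature_spec("Birthweight", "numeric", missing_rate = 0.02),
    feature_spec("Birthheight", "numeric", missing_rate = 0.02),
    feature_spec("MoBMI", "numeric", missing_rate = 0.05),
    feature_spec("MoSystolicPressure", "numeric", missing_rate = 0.05),
    feature_spec("ExerciseHours", "numeric", missing_rate = 0.4),
    feature_spec("ScreenHours", "numeric", missing_rate = 0.5),
    feature_spec("SugarIntake", "numeric", missing_rate = 0.6),
    feature_spec("Tobacco", "categorical", n_levels = 2, missing_rate = 0.35),
    feature_spec("BFType", "categorical", n_levels = 3, missing_rate = 0.5),
    feature_spec("DietEducation", "categorical", n_levels = 2, missing_rate = 0.55),
    feature_spec("SleepPattern", "categorical", n_levels = 3, missing_rate = 0.65),
    feature_spec("DietIntentChange", "categorical", n_levels = 2, missing_rate = 0.85)
  )
}

#' Study conditions of the parameter-recovery experiment
#'
#' The cohort used by the recovery tests: 30,000 records from 12,000
#' children with the default feature panel and three strongly planted
#' effects, each worth twice the BMI noise standard deviation per standard
#' deviation of the observed feature: two numeric vitals (SD 1, raw
#' coefficient +/-4 kg/m^2) and one binary lifestyle level (indicator SD
#' 0.5, raw coefficient 8 kg/m^2).
#'
#' @param master_seed Integer seed.
#' @param n_records,n_children Cohort sizes (defaults 30,000 / 12,000).
#' @return A [cohort_config()].
#' @export
recovery_cohort_config <- function(master_seed, n_records = 30000L,
                                   n_children = 12000L) {
  cohort_config(
    n_records, n_children,
    effect_map = c(SystolicPressure = 4, Birthweight = -4, Tobacco_lv2 = 8),
    master_seed = master_seed
  )
}

#' @noRd
level_names <- function(n) paste0("lv", seq_len(n))

#' @noRd
effect_keys <- function(specs) {
  keys <- specs$name[specs$kind == "numeric"]
  for (i in which(specs$kind == "categorical")) {
    keys <- c(keys, paste(specs$name[i], level_names(specs$n_levels[i]), sep = "_"))
  }
  keys
}

#' Generate a synthetic visit-record cohort
#'
#' Each record carries a child id, an integer age, a sex, a BMI and the
#' declared feature columns. BMI is the sum of an age/sex baseline, the
#' planted linear predictor over `effect_map`, and Gaussian noise, so that
#' thresholding BMI at each stratum's 90th percentile produces an outcome
#' correlated with the planted features and with known effect signs.
#' Repeated records of a child are drawn independently. Missingness is not
#' applied here; see [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @return An object of class `bfsmr_cohort`: a list with `records` (tibble)
#'   and `truth` (tibble of planted features ordered by absolute effect),
#'   plus the generating config.
#' @examples
#' cfg <- cohort_config(500, 200, master_seed = 7)
#' coh <- generate_cohort(cfg)
#' dim(coh$records)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_records
  specs <- config$feature_specs

  records <- with_seed(derive_seed(config$master_seed, 1L), {
    child_id <- c(
      seq_len(config$n_children),
      if (n > config$n_children) {
        sample.int(config$n_children, n - config$n_children, replace = TRUE)
      }
    )
    child_sex <- sample(c("F", "M"), config$n_children, replace = TRUE)
    out <- tibble(
      child_id = child_id,
      age = sample(seq(config$age_range[1], config$age_range[2]), n, replace = TRUE),
      sex = child_sex[child_id]
    )
    for (i in seq_len(nrow(specs))) {
      out[[specs$name[i]]] <- if (specs$kind[i] == "numeric") {
        rnorm(n)
      } else {
        sample(level_names(specs$n_levels[i]), n, replace = TRUE)
      }
    }
    out
  })

  lp <- rep(0, n)
  for (key in names(config$effect_map)) {
    beta <- config$effect_map[[key]]
    if (key %in% specs$name) {
      lp <- lp + beta * records[[key]]
    } else {
      feat <- specs$name[specs$kind == "categorical"]
      hit <- feat[startsWith(key, paste0(feat, "_"))][1]
      lev <- sub(paste0(hit, "_"), "", key)
      lp <- lp + beta * as.numeric(records[[hit]] == lev)
    }
  }
  baseline <- 14.5 + 0.25 * records$age + 0.3 * (records$sex == "M")
  noise <- with_seed(derive_seed(config$master_seed, 2L),
                     rnorm(n, sd = config$bmi_noise_sd))
  records$bmi <- pmax(baseline + lp + noise, 8)

  records <- records[, c("child_id", "age", "sex", "bmi",
                         setdiff(names(records), c("child_id", "age", "sex", "bmi")))]

  truth <- planted_truth(config$effect_map)
  structure(
    list(records = records, truth = truth, config = config),
    class = "bfsmr_cohort"
  )
}

#' @noRd
planted_truth <- function(effect_map) {
  if (length(effect_map) == 0) {
    return(tibble(feature = character(), sign = character(), effect = numeric()))
  }
  tb <- tibble(
    feature = names(effect_map),
    effect = as.numeric(effect_map),
    sign = unname(ifelse(effect_map >= 0, "+", "-"))
  )
  tb <- arrange(tb, desc(abs(.data$effect)), .data$feature)
  select(tb, "feature", "sign", "effect")
}

#' Apply missing-completely-at-random cell deletion
#'
#' Each feature cell is independently set to missing with its declared
#' `missing_rate`. Identifiers, age, sex and BMI are never removed. The
#' deletion pattern is seeded from the cohort's master seed, so repeated
#' calls on the same cohort give the same pattern.
#'
#' @param cohort A `bfsmr_cohort` from [generate_cohort()].
#' @param config Optional [cohort_config()]; defaults to the one stored in
#'   the cohort.
#' @return The cohort with missing cells in its `records`.
#' @export
inject_missingness <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "bfsmr_cohort"))
  specs <- config$feature_specs
  records <- cohort$records
  n <- nrow(records)
  records <- with_seed(derive_seed(config$master_seed, 3L), {
    for (i in seq_len(nrow(specs))) {
      rate <- specs$missing_rate[i]
      if (rate > 0) {
        gone <- runif(n) < rate
        records[[specs$name[i]]][gone] <- NA
      }
    }
    records
  })
  cohort$records <- records
  cohort
}

#' Planted ground truth of a synthetic cohort
#'
#' @param cohort A `bfsmr_cohort`.
#' @return Tibble with columns `feature` and `sign`, ordered by decreasing
#'   absolute planted effect; ties are ordered by name.
#' @export
ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "bfsmr_cohort"))
  select(cohort$truth, "feature", "sign")
}

#' Write a cohort (and optionally its ground truth) as delimited text
#'
#' The cohort file is comma-separated with a header row and empty fields
#' for missing values, the format [stream_chunks()] reads back.
#'
#' @param cohort A `bfsmr_cohort`.
#' @param path Output file for the records.
#' @param truth_path Optional output file for the two-column truth table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "bfsmr_cohort"))
  readr::write_csv(cohort$records, path, na = "")
  if (!is.null(truth_path)) {
    readr::write_csv(ground_truth(cohort), truth_path, na = "")
  }
  invisible(path)
}

#' @export
print.bfsmr_cohort <- function(x, ...) {
  cat(sprintf(
    "<bfsmr_cohort> %d records, %d children, %d feature columns, %d planted effects\n",
    nrow(x$records), x$config$n_children, nrow(x$config$feature_specs),
    nrow(x$truth)
  ))
  invisible(x)
}
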