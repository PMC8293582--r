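# Seed handling ---------------------------------------------------------

#' Derive a reproducible child seed from a master seed and a stream index
#'
#' Runs use one master seed; every independent random stream (a chunk, a
#' bootstrap replicate, a selector) derives its own seed so results do not
#' depend on processing order. The derivation is a small multiplicative hash
#' kept inside the 32-bit integer range.
#'
#' @param master_seed Integer master seed for the run.
#' @param stream_index Non-negative integer identifying the stream.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(master_seed, stream_index) {
  m <- 2147483647
  x <- (as.double(master_seed) %% m + 1) * 48271 %% m
  x <- (x + as.double(stream_index) * 16807) %% m
  as.integer((x * 69621) %% m)
}

#' Evaluate an expression under a local, restored RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Percentiles ------------------------------------------------------------

#' Nearest-rank empirical percentile
#'
#' The percentile of a sample by the nearest-rank definition: the smallest
#' order statistic whose rank is at least `ceiling(p/100 * n)`. Deterministic
#' and robust to ties, unlike interpolating definitions.
#'
#' @param x Numeric vector (missing values removed before ranking).
#' @param p Percentile in (0, 100).
#' @return A single numeric value; `NA` if `x` has no non-missing entries.
#' @examples
#' nearest_rank_percentile(1:10, 90) # 9
#' @export
nearest_rank_percentile <- function(x, p) {
  stopifnot(is.numeric(p), length(p) == 1, p > 0, p < 100)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, partial = NULL)[[max(1L, ceiling(p / 100 * n))]]
}

# Small helpers ----------------------------------------------------------

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize columns of a numeric matrix to zero mean and unit variance
#'
#' Constant columns are left centred at zero (divisor 1) rather than
#' producing NaNs.
#' @keywords internal
#' @noRd
standardize_matrix <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)
}
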