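#' Time-shifted surrogate of a single series
#'
#' Cyclically rotates a series: an integer `d` is drawn uniformly from
#' `[ceiling(0.05 n), floor(0.95 n)]` and the first `d` values are moved to
#' the end, giving `{x[d+1], ..., x[n], x[1], ..., x[d]}`.  The rotation
#' preserves the marginal distribution and autocorrelation of the series
#' while destroying its cross-couplings with other variables, which makes
#' it the null model for the significance tests in this package.  The draw
#' uses the current RNG state; callers seed a substream beforehand.
#'
#' @param x numeric vector of length at least 20.
#' @param d optional fixed shift (bypasses the random draw).
#' @return The rotated series, with the shift in attribute `"shift"`.
#' @export
time_shift_surrogate <- function(x, d = NULL) {
  n <- length(x)
  if (n < 20L) stop("series too short for time-shift surrogates (n = ", n, ")")
  if (is.null(d)) d <- draw_shifts(n, 1L)
  d <- as.integer(d)
  if (d < 1L || d >= n) stop("shift d must be in [1, n - 1]")
  structure(c(x[(d + 1L):n], x[1:d]), shift = d)
}

# uniform draws from the admissible shift range
draw_shifts <- function(n, count) {
  lo <- ceiling(0.05 * n); hi <- floor(0.95 * n)
  if (lo > hi) stop("series too short for time-shift surrogates (n = ", n, ")")
  sample(lo:hi, count, replace = TRUE)
}

#' Rank-based one-sided p-value against a surrogate ensemble
#'
#' Ranks the original statistic `q0` within the pooled list
#' `{q0, q1, ..., qM}` in ascending order and returns the corrected
#' one-sided p-value `1 - (r0 - 0.326) / (M + 1 + 0.348)`.  Rank ties
#' between `q0` and surrogate values are broken uniformly at random from
#' the current RNG stream, so the rank is unbiased under ties and
#' reproducible by seed.
#'
#' @param q0 statistic on the original data.
#' @param surrogates numeric vector of `M` surrogate statistics.
#' @return The p-value, strictly decreasing in the rank of `q0`.
#' @export
rank_pvalue <- function(q0, surrogates) {
  M <- length(surrogates)
  if (M < 1L || !all(is.finite(c(q0, surrogates))))
    stop("need a complete finite surrogate ensemble")
  nties <- sum(surrogates == q0)
  r0 <- sum(surrogates < q0) + 1L +
    if (nties > 0L) sample.int(nties + 1L, 1L) - 1L else 0L
  1 - (r0 - 0.326) / (M + 1 + 0.348)
}

#' Nearest-rank empirical percentile threshold
#'
#' Returns the `(1 - alpha)` empirical quantile of a set of surrogate
#' statistics under the nearest-rank rule (sorted value at index
#' `ceiling((1 - alpha) * M)`): conservative, distribution-free, and exact
#' for the discrete ensembles used here.
#'
#' @param values numeric vector of surrogate statistics.
#' @param alpha tail level in (0, 1).
#' @return The threshold value.
#' @export
percentile_threshold <- function(values, alpha) {
  M <- length(values)
  if (M < 1L) stop("need at least one value")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sort(values)[max(1L, ceiling((1 - alpha) * M))]
}
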