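#' Lagged term
#'
#' A (variable, lag) pair: the value of variable `var` at time `t - lag`
#' when predicting the target at `t + 1`.  Lag 0 denotes the current value
#' `x_t`.  These are the elements of the candidate set from which
#' non-uniform (mixed) embeddings are built.
#'
#' @param var integer variable index (1-based).
#' @param lag nonnegative integer lag.
#' @return A `lagged_term` object.
#' @export
lagged_term <- function(var, lag) {
  var <- as.integer(var); lag <- as.integer(lag)
  if (length(var) != 1L || length(lag) != 1L || is.na(var) || is.na(lag))
    stop("`var` and `lag` must be scalar integers")
  if (var < 1L) stop("`var` must be >= 1")
  if (lag < 0L) stop("`lag` must be >= 0")
  structure(list(var = var, lag = lag), class = "lagged_term")
}

#' @export
print.lagged_term <- function(x, ...) {
  cat("<lagged_term> var ", x$var, ", lag ", x$lag, "\n", sep = "")
  invisible(x)
}

#' Full candidate set of lagged terms
#'
#' All (variable, lag) pairs with lag in `0:Lmax`, for every variable of a
#' `K`-variable series: the pool from which mixed-embedding terms are
#' greedily selected.
#'
#' @param K number of variables.
#' @param Lmax maximum candidate lag.
#' @return A data frame with columns `var` and `lag`, `K * (Lmax + 1)` rows.
#' @export
candidate_set <- function(K, Lmax) {
  if (K < 2L) stop("K must be >= 2")
  if (Lmax < 1L) stop("Lmax must be >= 1")
  expand.grid(lag = 0:Lmax, var = seq_len(K))[, c("var", "lag")]
}

#' Materialize a lagged design matrix aligned with the one-step future
#'
#' Builds the design matrix whose column `j` holds
#' `series[t - terms[[j]]$lag, terms[[j]]$var]`, together with the future
#' vector `series[t + 1, target]`, over exactly the times `t` for which
#' both are observable.  With `max_lag` the largest lag among the terms,
#' the effective number of rows is `n - max_lag - horizon`.
#'
#' @param series an [mv_series()].
#' @param terms a list of [lagged_term()]s (or a data frame with `var` and
#'   `lag` columns).
#' @param target variable index whose future forms the response.
#' @param horizon prediction horizon; only 1 is supported.
#' @return A list with `X` (design matrix), `y` (future vector), and
#'   `t_range` (the 1-based time indices `t` of the rows).
#' @export
lag_matrix <- function(series, terms, target, horizon = 1L) {
  series <- as_mv_series(series)
  if (horizon != 1L) stop("only horizon = 1 is supported")
  tl <- terms_df(terms, ncol(series))
  n <- nrow(series)
  max_lag <- max(0L, tl$lag)
  if (max_lag >= n - 1L)
    stop("maximum lag ", max_lag, " leaves no valid rows for n = ", n)
  tv <- seq.int(max_lag + 1L, n - 1L)
  X <- vapply(seq_len(nrow(tl)), function(j) series[tv - tl$lag[j], tl$var[j]],
              numeric(length(tv)))
  X <- matrix(X, nrow = length(tv))
  colnames(X) <- paste0(colnames(series)[tl$var], "[t-", tl$lag, "]")
  list(X = X, y = series[tv + 1L, target], t_range = tv)
}

# normalize list-of-lagged_term / data.frame input to a data frame
terms_df <- function(terms, K) {
  if (inherits(terms, "lagged_term")) terms <- list(terms)
  if (is.data.frame(terms)) {
    df <- terms[, c("var", "lag")]
  } else {
    if (!length(terms)) stop("`terms` must be nonempty")
    df <- data.frame(var = vapply(terms, `[[`, integer(1), "var"),
                     lag = vapply(terms, `[[`, integer(1), "lag"))
  }
  if (any(df$var < 1L | df$var > K))
    stop("variable index out of range [1, ", K, "]")
  if (any(df$lag < 0L)) stop("lags must be >= 0")
  df
}
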