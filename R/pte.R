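#' @title Partial transfer entropy on uniform embeddings
#' @description
#' Partial transfer entropy (PTE) quantifies the direct influence of a
#' source variable X on a target Y within a K-variable system as
#' `I(y_{t+1}; x_t | y_t, z_t)`: the information the source's delay vector
#' carries about the target's next value beyond what the target's own past
#' and the remaining variables' pasts (`z_t`, all other observed variables)
#' already provide.  Every variable is represented by the uniform delay
#' vector `[x_t, x_{t-tau}, ..., x_{t-(m-1)tau}]`.  With K = 2 the
#' conditioning reduces to `y_t` alone and PTE coincides with bivariate
#' transfer entropy.  Significance is assessed by recomputing the measure
#' with the raw source series cyclically time-shifted (embeddings rebuilt
#' from the shifted series) and ranking the original value within the
#' surrogate ensemble.
#' @name pte
NULL

# uniform-embedding blocks shared by value/test: future column, fixed
# conditioning block (target + all variables except the source), raw source
uniform_blocks <- function(S, source, target, config) {
  n <- nrow(S); K <- ncol(S)
  m <- config$m; tau <- config$tau
  max_lag <- (m - 1L) * tau
  if (n <= max_lag + 1L + config$k)
    stop("series too short for m = ", m, ", tau = ", tau,
         ", k = ", config$k, " (n = ", n, ")")
  tv <- seq.int(max_lag + 1L, n - 1L)
  lags <- seq.int(0L, by = tau, length.out = m)
  emb <- function(v) vapply(lags, function(l) S[tv - l, v], numeric(length(tv)))
  cond_vars <- c(target, setdiff(seq_len(K), c(source, target)))
  cond <- do.call(cbind, lapply(cond_vars, emb))
  list(src = S[, source], lags = lags,
       fut = matrix(S[tv + 1L, target], ncol = 1L),
       cond = cond, t0 = max_lag, n = n)
}

check_pair <- function(S, source, target) {
  K <- ncol(S)
  if (source == target) stop("source and target must differ")
  if (source < 1L || source > K || target < 1L || target > K)
    stop("variable index out of range [1, ", K, "]")
}

#' Partial transfer entropy value
#'
#' @param data an [mv_series()] (or coercible matrix).
#' @param source,target variable indices (1-based); rows-drive-columns
#'   direction source -> target.
#' @param config an [analysis_config()].
#' @return The PTE value in nats.
#' @seealso [pte_test()], [pte_network()]
#' @export
pte_value <- function(data, source, target, config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  check_pair(S, source, target)
  b <- uniform_blocks(S, source, target, config)
  cmi_shift_surrogates_cpp(b$src, b$lags, b$fut, b$cond, b$t0,
                           config$k, 0L)[1L]
}

.pte_core <- function(S, source, target, config, pair_seed) {
  b <- uniform_blocks(S, source, target, config)
  with_seed(pair_seed, {
    shifts <- c(0L, draw_shifts(b$n, config$nsur))
    q <- cmi_shift_surrogates_cpp(b$src, b$lags, b$fut, b$cond, b$t0,
                                  config$k, shifts)
    p <- rank_pvalue(q[1L], q[-1L])
  })
  causality_result("PTE", source, target, colnames(S), q[1L], p,
                   significant = p <= config$alpha_test)
}

#' Surrogate significance test for partial transfer entropy
#'
#' Computes the PTE value, an ensemble of `nsur` surrogate values with the
#' raw source series time-shifted, and the rank-based one-sided p-value;
#' the link is significant when `p <= alpha_test`.
#'
#' @inheritParams pte_value
#' @return A `causality_result` with `value`, `p_value`, `significant`.
#' @export
pte_test <- function(data, source, target, config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  check_pair(S, source, target)
  .pte_core(S, source, target, config,
            derive_seed(config$seed, "pte", source, target))
}

#' Partial transfer entropy network
#'
#' Runs [pte_test()] for every ordered pair of variables.  Each pair draws
#' its surrogates from its own seed substream, so results are identical to
#' calling [pte_test()] pair by pair and independent of evaluation order.
#'
#' @inheritParams pte_value
#' @return A `causality_network` with K x K matrices `values`, `p_values`
#'   and `significant` (rows drive columns, diagonal `NA`).
#' @export
pte_network <- function(data, config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  K <- ncol(S)
  vals <- p <- matrix(NA_real_, K, K, dimnames = list(colnames(S), colnames(S)))
  sig <- matrix(NA, K, K, dimnames = dimnames(vals))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    r <- .pte_core(S, i, j, config, derive_seed(config$seed, "pte", i, j))
    vals[i, j] <- r$value; p[i, j] <- r$p_value; sig[i, j] <- r$significant
  }
  causality_network("PTE", colnames(S), vals, p, sig, config = config)
}
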