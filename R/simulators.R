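#' @title Benchmark systems with known ground truth
#' @description
#' Three coupled systems whose true directed networks are known, used to
#' benchmark the causality measures: S1, a linear VAR of order 5 in four
#' variables; S2, a nonlinear VAR of order 1 in three variables mixing one
#' linear and two nonlinear couplings; and S3, a ring-free lattice of K
#' coupled Henon maps whose end maps are autonomous and whose interior
#' maps are driven by both neighbors with strength `c`.  Each simulator
#' discards a transient (`burn_in` samples, default 1000, comfortably
#' beyond every memory depth in the dynamics) and returns the realized
#' series together with the ground-truth adjacency (rows drive columns).
#' @name simulators
NULL

sim_result <- function(series, truth, system_id, params) {
  structure(list(series = series, truth = truth, system_id = system_id,
                 params = params),
            class = "simulated_realization")
}

#' @export
print.simulated_realization <- function(x, ...) {
  cat("<simulated_realization>", x$system_id, "with K =", ncol(x$series),
      "variables, n =", nrow(x$series), "samples,",
      sum(x$truth), "true links\n")
  invisible(x)
}

#' Ground-truth adjacency of a benchmark system
#'
#' @param system_id `"S1"`, `"S2"` or `"S3"`.
#' @param K number of variables (S3 only; S1 is 4-variable, S2
#'   3-variable).
#' @return A logical adjacency matrix, rows drive columns, diagonal
#'   `FALSE`.  S3 has the `2 * (K - 2)` links `X_{i-1} -> X_i` and
#'   `X_{i+1} -> X_i` for interior `i`.
#' @export
ground_truth_adjacency <- function(system_id, K = NULL) {
  switch(system_id,
    S1 = {
      adj <- matrix(FALSE, 4L, 4L)
      adj[1L, 3L] <- adj[2L, 1L] <- adj[2L, 3L] <- adj[4L, 2L] <- TRUE
      adj
    },
    S2 = {
      adj <- matrix(FALSE, 3L, 3L)
      adj[1L, 2L] <- adj[1L, 3L] <- adj[2L, 3L] <- TRUE
      adj
    },
    S3 = {
      if (is.null(K) || K < 3L) stop("S3 needs K >= 3")
      adj <- matrix(FALSE, K, K)
      for (i in seq.int(2L, K - 1L)) adj[c(i - 1L, i + 1L), i] <- TRUE
      adj
    },
    stop("unknown system '", system_id, "' (expected S1, S2 or S3)"))
}

#' Simulate the linear VAR benchmark (S1)
#'
#' Four variables, autoregressive order 5, iid standard-normal
#' innovations:
#' \preformatted{
#' x1[t] = 0.8 x1[t-1] + 0.65 x2[t-4] + e1
#' x2[t] = 0.6 x2[t-1] + 0.6  x4[t-5] + e2
#' x3[t] = 0.5 x3[t-3] - 0.6  x1[t-1] + 0.4 x2[t-4] + e3
#' x4[t] = 1.2 x4[t-1] - 0.7  x4[t-2] + e4
#' }
#' True links: X1 -> X3, X2 -> X1, X2 -> X3, X4 -> X2.  The system is
#' covariance-stationary (companion spectral radius < 1); iteration starts
#' from the zero state and the transient is discarded.
#'
#' @param n number of retained samples (>= 64).
#' @param seed integer seed.
#' @param burn_in discarded transient length.
#' @param noise_sd innovation standard deviation (1 for the benchmark; 0
#'   exposes the deterministic skeleton).
#' @return A `simulated_realization`.
#' @export
simulate_s1 <- function(n, seed = 1L, burn_in = 1000L, noise_sd = 1) {
  if (n < 64L) stop("n must be >= 64")
  total <- n + burn_in + 5L
  x <- matrix(0, total, 4L)
  e <- with_seed(seed, matrix(stats::rnorm(total * 4L, sd = noise_sd), total, 4L))
  for (t in 6:total) {
    x[t, 1L] <- 0.8 * x[t - 1L, 1L] + 0.65 * x[t - 4L, 2L] + e[t, 1L]
    x[t, 2L] <- 0.6 * x[t - 1L, 2L] + 0.6 * x[t - 5L, 4L] + e[t, 2L]
    x[t, 3L] <- 0.5 * x[t - 3L, 3L] - 0.6 * x[t - 1L, 1L] +
      0.4 * x[t - 4L, 2L] + e[t, 3L]
    x[t, 4L] <- 1.2 * x[t - 1L, 4L] - 0.7 * x[t - 2L, 4L] + e[t, 4L]
  }
  sim_result(mv_series(x[(total - n + 1L):total, , drop = FALSE]),
             ground_truth_adjacency("S1"), "S1",
             list(K = 4L, n = n, seed = seed, burn_in = burn_in))
}

#' Simulate the nonlinear VAR benchmark (S2)
#'
#' Three variables, order 1, with the bounded map core
#' `f(x) = 3.4 x (1 - x^2) exp(-x^2)` and 0.4-scaled standard-normal
#' innovations:
#' \preformatted{
#' x1[t] = f(x1[t-1]) + 0.4 e1
#' x2[t] = f(x2[t-1]) + 0.5 x1[t-1] x2[t-1] + 0.4 e2
#' x3[t] = f(x3[t-1]) + 0.3 x2[t-1] + 0.5 x1[t-1]^2 + 0.4 e3
#' }
#' True links: X1 -> X2 and X1 -> X3 (nonlinear), X2 -> X3 (linear).
#'
#' @inheritParams simulate_s1
#' @param coupled set `FALSE` to zero the three coupling coefficients
#'   (three independent channels; useful as a null system).
#' @return A `simulated_realization`.
#' @export
simulate_s2 <- function(n, seed = 1L, burn_in = 1000L, coupled = TRUE) {
  if (n < 64L) stop("n must be >= 64")
  total <- n + burn_in + 1L
  x <- matrix(0, total, 3L)
  e <- with_seed(seed, matrix(stats::rnorm(total * 3L), total, 3L))
  f <- function(v) 3.4 * v * (1 - v^2) * exp(-v^2)
  cc <- if (coupled) c(0.5, 0.3, 0.5) else c(0, 0, 0)
  for (t in 2:total) {
    p <- x[t - 1L, ]
    x[t, 1L] <- f(p[1L]) + 0.4 * e[t, 1L]
    x[t, 2L] <- f(p[2L]) + cc[1L] * p[1L] * p[2L] + 0.4 * e[t, 2L]
    x[t, 3L] <- f(p[3L]) + cc[2L] * p[2L] + cc[3L] * p[1L]^2 + 0.4 * e[t, 3L]
  }
  sim_result(mv_series(x[(total - n + 1L):total, , drop = FALSE]),
             ground_truth_adjacency("S2"), "S2",
             list(K = 3L, n = n, seed = seed, burn_in = burn_in,
                  coupled = coupled))
}

#' Simulate coupled Henon maps (S3)
#'
#' A chain of K Henon maps; the end maps run autonomously and each
#' interior map is driven multiplicatively by both neighbors:
#' \preformatted{
#' x1[t] = 1.4 - x1[t-1]^2 + 0.3 x1[t-2]
#' xi[t] = 1.4 - 0.5 c x(i-1)[t-1] x(i+1)[t-1] - (1-c) xi[t-1]^2
#'             + 0.3 xi[t-2],   i = 2..K-1
#' xK[t] = 1.4 - xK[t-1]^2 + 0.3 xK[t-2]
#' }
#' Initial pairs are drawn uniformly from (-0.5, 0.5), inside the
#' attractor basin; if a trajectory diverges (|x| > 10) the initial
#' conditions are redrawn from an incremented sub-seed, up to 100 times.
#'
#' @inheritParams simulate_s1
#' @param K number of maps (>= 3).
#' @param c coupling strength in `[0, 1]`; `c = 0` gives K independent
#'   maps.
#' @return A `simulated_realization`.
#' @export
simulate_s3 <- function(K, c, n, seed = 1L, burn_in = 1000L) {
  if (K < 3L) stop("K must be >= 3")
  if (c < 0 || c > 1) stop("c must be in [0, 1]")
  if (n < 64L) stop("n must be >= 64")
  total <- n + burn_in + 2L
  interior <- seq.int(2L, K - 1L)
  for (try in 0:100) {
    if (try == 100L)
      stop("persistent divergence after 100 initial-condition redraws")
    x <- matrix(0, total, K)
    x[1:2, ] <- with_seed(derive_seed(seed, "init", try),
                          matrix(stats::runif(2L * K, -0.5, 0.5), 2L, K))
    diverged <- FALSE
    for (t in 3:total) {
      p1 <- x[t - 1L, ]; p2 <- x[t - 2L, ]
      xt <- numeric(K)
      xt[1L] <- 1.4 - p1[1L]^2 + 0.3 * p2[1L]
      xt[K] <- 1.4 - p1[K]^2 + 0.3 * p2[K]
      xt[interior] <- 1.4 - 0.5 * c * p1[interior - 1L] * p1[interior + 1L] -
        (1 - c) * p1[interior]^2 + 0.3 * p2[interior]
      if (any(abs(xt) > 10)) { diverged <- TRUE; break }
      x[t, ] <- xt
    }
    if (!diverged) break
  }
  sim_result(mv_series(x[(total - n + 1L):total, , drop = FALSE]),
             ground_truth_adjacency("S3", K), "S3",
             list(K = K, c = c, n = n, seed = seed, burn_in = burn_in,
                  redraws = try))
}

#' Simulate a benchmark system by name
#'
#' Dispatcher over [simulate_s1()], [simulate_s2()] and [simulate_s3()];
#' convenient for scripted runs.
#'
#' @inheritParams ground_truth_adjacency
#' @inheritParams simulate_s3
#' @return A `simulated_realization`.
#' @export
simulate_system <- function(system_id, n, seed = 1L, K = NULL, c = NULL,
                            burn_in = 1000L) {
  switch(system_id,
    S1 = simulate_s1(n, seed, burn_in),
    S2 = simulate_s2(n, seed, burn_in),
    S3 = {
      if (is.null(K) || is.null(c)) stop("S3 needs K and c")
      simulate_s3(K, c, n, seed, burn_in)
    },
    stop("unknown system '", system_id, "' (expected S1, S2 or S3)"))
}

#' Export a simulated realization as delimited text plus a JSON sidecar
#'
#' Writes the series as CSV and a sidecar `<path>.json` holding the
#' system id, parameters, and the ground-truth edge list.
#'
#' @param sim a `simulated_realization`.
#' @param path output path for the series CSV.
#' @return Invisibly, the two paths written.
#' @export
write_realization <- function(sim, path) {
  write_mv_series(sim$series, path)
  idx <- which(sim$truth, arr.ind = TRUE)
  side <- list(system = sim$system_id, params = sim$params,
               truth_edges = data.frame(
                 source = colnames(sim$series)[idx[, 1L]],
                 target = colnames(sim$series)[idx[, 2L]]))
  jp <- paste0(path, ".json")
  writeLines(jsonlite::toJSON(side, dataframe = "rows", auto_unbox = TRUE,
                              pretty = TRUE), jp)
  invisible(c(path, jp))
}
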