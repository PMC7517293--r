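#' Analysis configuration
#'
#' Collects the tunable parameters shared by the three causality measures.
#' Defaults follow the standard practice for these estimators: `k = 10`
#' neighbors, `nsur = 100` surrogates, significance level 0.05 for the
#' uniform-embedding PTE test and 0.01 for the mixed-embedding stopping
#' criterion, and delay `tau = 1`.
#'
#' @param m embedding dimension of the uniform scheme (PTE); set it to the
#'   maximum lag of the generating dynamics when known.
#' @param tau embedding delay of the uniform scheme.
#' @param Lmax maximum candidate lag for mixed-embedding selection
#'   (PTENUE/LATE); slightly larger than `m` is sufficient.
#' @param k number of nearest neighbors of the KNN estimator.
#' @param nsur number of time-shifted surrogates.
#' @param alpha_test significance level of the PTE surrogate test.
#' @param alpha_stop significance level of the CMI-based mixed-embedding
#'   stopping criterion and of the link-level surrogate test.
#' @param la_alpha_stop significance level of the LA-based (LATE) stopping
#'   criterion; looser by default, reflecting that the approximate
#'   criterion carries weak synergies the full-CMI link test later
#'   re-examines.
#' @param seed integer seed; every random draw in an analysis is taken from
#'   substreams derived deterministically from it, so results are
#'   reproducible and independent of evaluation order.
#' @param max_terms hard cap on the number of selected mixed-embedding
#'   terms (guards non-termination for extreme `alpha_stop`).
#' @param la_sum_over for the LATE selection criterion: average the
#'   redundancy sums over the already-`"selected"` terms (default) or over
#'   the whole candidate pool (`"all"`).
#' @param la_cond_sign sign of the conditional-redundancy term in the LATE
#'   criterion: `"add"` (default; the chain-rule form
#'   `I(y;w|V) = I(y;w) - I(w;V) + I(w;V|y)` of the feature-selection
#'   literature) or `"subtract"`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(m = 1L, tau = 1L, Lmax = m + 1L, k = 10L,
                            nsur = 100L, alpha_test = 0.05,
                            alpha_stop = 0.01, la_alpha_stop = 0.05,
                            seed = 1L, max_terms = 20L,
                            la_sum_over = c("selected", "all"),
                            la_cond_sign = c("add", "subtract")) {
  stopifnot(m >= 1L, tau >= 1L, Lmax >= 1L, k >= 1L, nsur >= 1L,
            alpha_test > 0, alpha_test < 1, alpha_stop > 0, alpha_stop < 1,
            la_alpha_stop > 0, la_alpha_stop < 1, max_terms >= 1L)
  structure(list(m = as.integer(m), tau = as.integer(tau),
                 Lmax = as.integer(Lmax), k = as.integer(k),
                 nsur = as.integer(nsur), alpha_test = alpha_test,
                 alpha_stop = alpha_stop, la_alpha_stop = la_alpha_stop,
                 seed = as.integer(seed),
                 max_terms = as.integer(max_terms),
                 la_sum_over = match.arg(la_sum_over),
                 la_cond_sign = match.arg(la_cond_sign)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config> m =", x$m, "tau =", x$tau, "Lmax =", x$Lmax,
      "k =", x$k, "nsur =", x$nsur, "\n  alpha_test =", x$alpha_test,
      "alpha_stop =", x$alpha_stop, "seed =", x$seed, "\n")
  invisible(x)
}

# Deterministic substream derivation: hashes the global seed together with
# a label and integer indices into a 31-bit seed.  Constants fit exact
# double arithmetic (69069 * 2^31 < 2^53).
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647)
  mix <- function(h, v) (h * 69069 + v + 1) %% 2147483647
  for (x in list(...)) {
    if (is.character(x)) {
      for (u in utf8ToInt(x)) h <- mix(h, u)
    } else {
      h <- mix(h, as.double(x))
    }
  }
  as.integer(h)
}

# Run code under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  code
}

# Standardize and apply the one-off deterministic tie-breaking jitter
# (uniform, magnitude 1e-10 standard deviations per coordinate).  Chaotic
# maps can emit exactly repeated values; the jitter makes neighbor ranks
# unique while leaving estimates unchanged to ~1e-10.
prepare_series <- function(series, config) {
  s <- standardize(series)
  jit <- with_seed(derive_seed(config$seed, "jitter"),
                   matrix(stats::runif(length(s), -1e-10, 1e-10), nrow(s)))
  mv_series(unclass(s) + jit, colnames(s))
}
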