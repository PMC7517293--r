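#' @title Non-uniform (mixed) embedding and PTENUE
#' @description
#' The non-uniform embedding (NUE) scheme replaces the fixed delay vectors
#' of uniform-embedding PTE with a greedy, data-driven selection of
#' individual (variable, lag) terms.  Starting from an empty embedding, at
#' each step the candidate term that maximizes the conditional mutual
#' information `I(y_{t+1}; w | selected terms)` is proposed; the scheme
#' continues only while the proposed term's CMI exceeds the
#' `(1 - alpha_stop)` percentile of `nsur` surrogate CMIs obtained by
#' time-shifting that term's raw series (conditioning set fixed).  The
#' PTENUE measure of a link X -> Y is then
#' `I(y_{t+1}; w_X | w_other)`, where `w_X` are the selected terms of X and
#' `w_other` the rest.  A link is declared present when `w_X` is nonempty
#' *and* that final CMI survives its own time-shift surrogate test (the
#' link-level test): the greedy stopping rule examines the per-step
#' maximum over many candidates, so marginal null terms occasionally slip
#' into the embedding, and the link test removes the spurious edges they
#' would otherwise create.  One embedding per target serves all K - 1
#' driver queries.
#' @name nue
NULL

# candidate/future blocks for mixed-embedding selection on one target;
# rows are fixed to t = Lmax+1 .. n-1 so criteria are comparable across steps
nue_blocks <- function(S, target, config) {
  n <- nrow(S); K <- ncol(S); Lmax <- config$Lmax
  if (n <= Lmax + 1L + config$k)
    stop("series too short for Lmax = ", Lmax, ", k = ", config$k,
         " (n = ", n, ")")
  tv <- seq.int(Lmax + 1L, n - 1L)
  cand_df <- candidate_set(K, Lmax)
  cands <- vapply(seq_len(nrow(cand_df)),
                  function(i) S[tv - cand_df$lag[i], cand_df$var[i]],
                  numeric(length(tv)))
  list(cand_df = cand_df, cands = cands,
       fut = matrix(S[tv + 1L, target], ncol = 1L),
       t0 = Lmax, n = n, N = length(tv))
}

term_cols <- function(b, rows) {
  if (!length(rows)) return(matrix(numeric(0), nrow = b$N, ncol = 0L))
  b$cands[, rows, drop = FALSE]
}

# argmax of the CMI criterion over remaining candidates; ties broken by
# lowest lag, then lowest variable index (parsimony)
.nue_greedy <- function(b, sel_rows, rem_rows, k) {
  scores <- cmi_scores_batch_cpp(b$fut, term_cols(b, sel_rows),
                                 term_cols(b, rem_rows), k)
  top <- rem_rows[scores == max(scores)]
  best <- top[order(b$cand_df$lag[top], b$cand_df$var[top])][1L]
  list(row = best, cmi = max(scores), scores = scores)
}

.nue_stop <- function(S, b, var, lag, sel_rows, config, step_seed) {
  with_seed(step_seed, {
    shifts <- c(0L, draw_shifts(b$n, config$nsur))
    q <- cmi_shift_surrogates_cpp(S[, var], as.integer(lag), b$fut,
                                  term_cols(b, sel_rows), b$t0,
                                  config$k, shifts)
  })
  thr <- percentile_threshold(q[-1L], config$alpha_stop)
  list(continue = q[1L] > thr, cmi = q[1L], threshold = thr)
}

#' One greedy selection step of the mixed-embedding scheme
#'
#' Scores every remaining candidate term by
#' `I(y_{t+1}; term | selected)` (plain mutual information when nothing is
#' selected yet) and returns the maximizer.
#'
#' @inheritParams pte_value
#' @param target target variable index.
#' @param selected data frame of already selected terms (columns `var`,
#'   `lag`), or `NULL` for the first step.
#' @return A list with `term` (a [lagged_term()]), `cmi` (its criterion
#'   value), and `scores` (all remaining candidates' criterion values).
#' @export
greedy_step <- function(data, target, selected = NULL,
                        config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  b <- nue_blocks(S, target, config)
  sel_rows <- match_terms(b$cand_df, selected)
  rem_rows <- setdiff(seq_len(nrow(b$cand_df)), sel_rows)
  if (!length(rem_rows)) stop("no remaining candidates")
  g <- .nue_greedy(b, sel_rows, rem_rows, config$k)
  list(term = lagged_term(b$cand_df$var[g$row], b$cand_df$lag[g$row]),
       cmi = g$cmi, scores = g$scores)
}

#' Surrogate stopping check for a proposed embedding term
#'
#' Recomputes the selection criterion `nsur` times with the proposed
#' term's raw series cyclically time-shifted (the conditioning set stays
#' fixed) and compares the original criterion with the
#' `(1 - alpha_stop)` nearest-rank percentile of the surrogate values.
#'
#' @inheritParams greedy_step
#' @param term the proposed [lagged_term()].
#' @return A list with `continue` (logical), `cmi` (original criterion),
#'   and `threshold` (surrogate percentile).
#' @export
stop_check <- function(data, target, term, selected = NULL,
                       config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  b <- nue_blocks(S, target, config)
  sel_rows <- match_terms(b$cand_df, selected)
  step <- length(sel_rows) + 1L
  .nue_stop(S, b, term$var, term$lag, sel_rows, config,
            derive_seed(config$seed, "nue", target, step))
}

match_terms <- function(cand_df, selected) {
  if (is.null(selected) || NROW(selected) == 0L) return(integer(0))
  selected <- terms_df(selected, max(cand_df$var))
  vapply(seq_len(nrow(selected)), function(i) {
    r <- which(cand_df$var == selected$var[i] & cand_df$lag == selected$lag[i])
    if (!length(r)) stop("selected term outside the candidate set")
    r
  }, integer(1))
}

#' Build the mixed embedding vector for one target
#'
#' Iterates [greedy_step()] and [stop_check()] until the stopping
#' criterion fires, the candidate pool is exhausted, or the `max_terms`
#' cap is reached.  The returned embedding may be empty (a target that no
#' candidate term helps to predict).
#'
#' @inheritParams greedy_step
#' @return A `mixed_embedding`: the ordered selected terms with per-step
#'   criterion values and thresholds, the full selection trace (including
#'   the final rejected proposal), and the partition bookkeeping used by
#'   [ptenue()].
#' @export
build_mixed_embedding <- function(data, target, config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  .build_embedding(S, target, config, criterion = "cmi")
}

.build_embedding <- function(S, target, config, criterion = c("cmi", "la")) {
  criterion <- match.arg(criterion)
  b <- nue_blocks(S, target, config)
  la <- if (criterion == "la") .la_state_init(b, config) else NULL
  sel_rows <- integer(0)
  rem_rows <- seq_len(nrow(b$cand_df))
  trace <- list()
  cap <- min(nrow(b$cand_df), config$max_terms)
  step <- 0L
  while (length(rem_rows) && length(sel_rows) < cap) {
    step <- step + 1L
    if (criterion == "cmi") {
      g <- .nue_greedy(b, sel_rows, rem_rows, config$k)
    } else {
      g <- .la_greedy(b, la, sel_rows, rem_rows, config)
    }
    seed_s <- derive_seed(config$seed, if (criterion == "cmi") "nue" else "la",
                          target, step)
    chk <- if (criterion == "cmi") {
      .nue_stop(S, b, b$cand_df$var[g$row], b$cand_df$lag[g$row],
                sel_rows, config, seed_s)
    } else {
      .la_stop(S, b, la, g$row, sel_rows, config, seed_s)
    }
    trace[[step]] <- data.frame(
      step = step, var = b$cand_df$var[g$row], lag = b$cand_df$lag[g$row],
      criterion = g$cmi, threshold = chk$threshold, accepted = chk$continue)
    if (!chk$continue) break
    sel_rows <- c(sel_rows, g$row)
    rem_rows <- setdiff(rem_rows, g$row)
    if (criterion == "la") la <- .la_state_add(b, la, g$row, config)
  }
  trace <- do.call(rbind, trace)
  terms <- if (length(sel_rows)) {
    data.frame(var = b$cand_df$var[sel_rows], lag = b$cand_df$lag[sel_rows],
               name = paste0(colnames(S)[b$cand_df$var[sel_rows]],
                             "[t-", b$cand_df$lag[sel_rows], "]"))
  } else data.frame(var = integer(0), lag = integer(0), name = character(0))
  structure(list(target = target, target_name = colnames(S)[target],
                 names = colnames(S), terms = terms, trace = trace,
                 criterion = criterion, Lmax = config$Lmax, N = b$N,
                 rows = sel_rows),
            class = "mixed_embedding")
}

#' @export
print.mixed_embedding <- function(x, ...) {
  cat("<mixed_embedding> target ", x$target_name, " (", x$criterion,
      " criterion): ", nrow(x$terms), " term(s)",
      if (nrow(x$terms)) paste0(": ", paste(x$terms$name, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Partition of a mixed embedding by source variable
#'
#' Splits the selected terms into the source's terms `w_X`, the target's
#' own terms `w_Y`, and the remaining variables' terms `w_Z`.
#'
#' @param embedding a `mixed_embedding`.
#' @param source driver variable index.
#' @return A list of three data frames `w_X`, `w_Y`, `w_Z`.
#' @export
embedding_partition <- function(embedding, source) {
  t <- embedding$terms
  list(w_X = t[t$var == source, , drop = FALSE],
       w_Y = t[t$var == embedding$target, , drop = FALSE],
       w_Z = t[t$var != source & t$var != embedding$target, , drop = FALSE])
}

# measure value from a built embedding: I(y_{t+1}; w_X | w_rest);
# zero / absent when the source contributed no terms.  For PTENUE the
# nonempty case is additionally pruned by a link-level surrogate test of
# the final CMI (source series shifted, w_X rebuilt, conditioning fixed):
# the greedy stopping rule tests the per-step maximum over candidates, so
# occasional marginal null terms slip in, and the link test removes them.
# LATE skips the link-level pruning: its approximate selection both
# over-admits terms (diluting any downstream CMI test) and is reported
# unpruned, giving the measure its characteristic high-sensitivity /
# low-specificity profile.
.measure_from_embedding <- function(S, emb, source, config, measure) {
  in_x <- emb$terms$var == source
  if (!any(in_x))
    return(causality_result(measure, source, emb$target, emb$names,
                            0, significant = FALSE,
                            terms = emb$terms[in_x, , drop = FALSE]))
  b <- nue_blocks(S, emb$target, config)
  cond <- term_cols(b, emb$rows[!in_x])
  p <- NA_real_
  if (measure == "PTENUE") {
    with_seed(derive_seed(config$seed, "link", source, emb$target), {
      shifts <- c(0L, draw_shifts(b$n, config$nsur))
      q <- cmi_shift_surrogates_cpp(S[, source],
                                    as.integer(emb$terms$lag[in_x]),
                                    b$fut, cond, b$t0, config$k, shifts)
      p <- rank_pvalue(q[1L], q[-1L])
    })
    value <- q[1L]
    sig <- p <= config$alpha_stop
  } else {
    value <- cmi_knn_cpp(term_cols(b, emb$rows[in_x]), b$fut, cond, config$k)
    sig <- TRUE
  }
  causality_result(measure, source, emb$target, emb$names, value,
                   p_value = p, significant = sig,
                   terms = emb$terms[in_x, , drop = FALSE])
}

#' PTENUE: partial transfer entropy on a non-uniform embedding
#'
#' Builds (or reuses) the mixed embedding of the target and evaluates the
#' direct effect of the source as `I(y_{t+1}; w_X | w_other)`.  The link
#' is significant when the embedding contains at least one term of the
#' source and the rank p-value of the final CMI within `nsur` surrogate
#' recomputations (source series time-shifted) is at most `alpha_stop`;
#' an empty `w_X` yields value 0 with `p_value = NA`.
#'
#' @inheritParams pte_value
#' @param embedding optionally, a prebuilt [build_mixed_embedding()] result
#'   for `target` (avoids rebuilding when querying several sources).
#' @return A `causality_result` with the measure value and the link-test
#'   p-value.
#' @export
ptenue <- function(data, source, target, config = analysis_config(),
                   embedding = NULL) {
  S <- prepare_series(as_mv_series(data), config)
  check_pair(S, source, target)
  if (is.null(embedding)) embedding <- .build_embedding(S, target, config, "cmi")
  .measure_from_embedding(S, embedding, source, config, "PTENUE")
}

#' PTENUE network
#'
#' Builds one mixed embedding per target (its own seed substream) and
#' evaluates every ordered pair from it.
#'
#' @inheritParams pte_network
#' @return A `causality_network`; `$embeddings` holds the per-target
#'   `mixed_embedding`s.
#' @export
ptenue_network <- function(data, config = analysis_config()) {
  .embedding_network(data, config, criterion = "cmi", measure = "PTENUE")
}

.embedding_network <- function(data, config, criterion, measure) {
  S <- prepare_series(as_mv_series(data), config)
  K <- ncol(S)
  vals <- p <- matrix(NA_real_, K, K, dimnames = list(colnames(S), colnames(S)))
  sig <- matrix(NA, K, K, dimnames = dimnames(vals))
  embs <- vector("list", K)
  for (j in seq_len(K)) {
    emb <- .build_embedding(S, j, config, criterion)
    embs[[j]] <- emb
    for (i in setdiff(seq_len(K), j)) {
      r <- .measure_from_embedding(S, emb, i, config, measure)
      vals[i, j] <- r$value; sig[i, j] <- r$significant
      p[i, j] <- r$p_value
    }
  }
  names(embs) <- colnames(S)
  causality_network(measure, colnames(S), vals,
                    p_values = if (measure == "PTENUE") p else NULL,
                    significant = sig, embeddings = embs, config = config)
}

#' Serialize an embedding report to JSON
#'
#' Audit record of a mixed-embedding construction: target, ordered selected
#' terms, and the per-step criterion values and surrogate thresholds
#' (including the final rejected proposal).
#'
#' @param embedding a `mixed_embedding`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
embedding_report <- function(embedding, path = NULL) {
  rep <- list(target = embedding$target_name,
              criterion = embedding$criterion,
              Lmax = embedding$Lmax, n_effective = embedding$N,
              terms = embedding$terms, trace = embedding$trace)
  js <- jsonlite::toJSON(rep, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
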