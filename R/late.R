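#' @title LATE: low-dimensional-approximation transfer entropy
#' @description
#' LATE follows the same greedy mixed-embedding construction as PTENUE but
#' replaces each step's high-dimensional CMI criterion with a
#' low-dimensional approximation borrowed from information-theoretic
#' feature selection, patterned on the chain-rule identity
#' `I(y_{t+1}; w | V) = I(y_{t+1}; w) - I(w; V) + I(w; V | y_{t+1})`: a
#' candidate `w` is scored by its relevance `I(y_{t+1}; w)`, minus a
#' pairwise redundancy penalty `(2/|V|) * sum_i I(w; w_i)`, plus a
#' conditional-redundancy (synergy) bonus
#' `(2/|V|) * sum_i I(w; w_i | y_{t+1})`, summed over the already selected
#' set `V`.  Only 2- and 3-dimensional information terms are ever
#' estimated, regardless of how large the embedding grows.  The stopping
#' rule mirrors the NUE one, with the LA criterion replacing the full CMI
#' in the surrogate recomputation, at its own level `la_alpha_stop`
#' (looser by default: the pairwise approximation understates weak
#' synergistic contributions relative to its surrogate threshold, and a
#' stringent level strips the measure of nearly all sensitivity on weakly
#' coupled systems).  The final LATE value of a link is the full CMI
#' `I(y_{t+1}; w_X | w_other)` on the selected embedding, and a link is
#' declared present exactly when `w_X` is nonempty — no link-level
#' pruning, which gives LATE its characteristic profile: the highest
#' sensitivity and the lowest specificity of the three measures.
#'
#' Two ambiguities in how such criteria are written are exposed as
#' switches in [analysis_config()]: `la_sum_over` (redundancy sums over
#' the selected set `V`, the default, or over the whole candidate pool)
#' and `la_cond_sign` (conditional-redundancy added, the default, or
#' subtracted; subtracting penalizes synergy and in practice stops
#' selection as soon as one strong term is in).
#' @name late
NULL

la_weight <- function(nset, mode, nB) {
  if (mode == "all") 2 / nB else if (nset > 0L) 2 / nset else 0
}

#' Low-dimensional-approximation score of a candidate term
#'
#' Direct (unbatched) evaluation of the LATE selection criterion from its
#' `1 + 2|V|` constituent mutual-information terms, exposed for audit.
#'
#' @inheritParams greedy_step
#' @param candidate a [lagged_term()] not yet selected.
#' @return An object of class `la_score`: `relevance`, `redundancy` and
#'   `conditional_redundancy` (means over the summed set), the per-term
#'   `components`, and the combined `total`.
#' @export
la_score <- function(data, target, candidate, selected = NULL,
                     config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  b <- nue_blocks(S, target, config)
  row <- match_terms(b$cand_df, data.frame(var = candidate$var,
                                           lag = candidate$lag))
  sel_rows <- match_terms(b$cand_df, selected)
  if (row %in% sel_rows) stop("candidate is already selected")
  set_rows <- if (config$la_sum_over == "all")
    setdiff(seq_len(nrow(b$cand_df)), row) else sel_rows
  w <- b$cands[, row]
  relevance <- knn_mi(w, b$fut, config$k)
  red <- vapply(set_rows, function(r) knn_mi(w, b$cands[, r], config$k),
                numeric(1))
  cred <- vapply(set_rows, function(r)
    knn_cmi(w, b$cands[, r], b$fut, config$k), numeric(1))
  wt <- la_weight(length(sel_rows), config$la_sum_over, nrow(b$cand_df))
  sgn <- if (config$la_cond_sign == "subtract") 1 else -1
  total <- relevance - wt * sum(red) - sgn * wt * sum(cred)
  structure(list(relevance = relevance,
                 redundancy = if (length(red)) mean(red) else 0,
                 conditional_redundancy = if (length(cred)) mean(cred) else 0,
                 components = list(redundancy = red,
                                   conditional_redundancy = cred),
                 total = total),
            class = "la_score")
}

#' @export
print.la_score <- function(x, ...) {
  cat("<la_score> relevance ", format(x$relevance, digits = 4),
      ", mean redundancy ", format(x$redundancy, digits = 4),
      ", mean cond. redundancy ", format(x$conditional_redundancy, digits = 4),
      " -> total ", format(x$total, digits = 4), "\n", sep = "")
  invisible(x)
}

# ---- internal batch state for the LA selection loop ----
# rel: relevance per candidate (computed once); red_sum / cred_sum:
# running sums over the summed set, updated when a term is accepted.
.la_state_init <- function(b, config) {
  nB <- nrow(b$cand_df)
  rel <- cmi_scores_batch_cpp(b$fut, term_cols(b, integer(0)), b$cands,
                              config$k)
  red_sum <- cred_sum <- numeric(nB)
  if (config$la_sum_over == "all") {
    for (r in seq_len(nB)) {
      yr <- b$cands[, r, drop = FALSE]
      mi <- cmi_scores_batch_cpp(yr, term_cols(b, integer(0)), b$cands,
                                 config$k)
      cm <- cmi_scores_batch_cpp(yr, b$fut, b$cands, config$k)
      mi[r] <- cm[r] <- 0  # exclude the self pair
      red_sum <- red_sum + mi; cred_sum <- cred_sum + cm
    }
  }
  list(rel = rel, red_sum = red_sum, cred_sum = cred_sum)
}

.la_state_add <- function(b, la, new_row, config) {
  if (config$la_sum_over == "all") return(la)
  yr <- b$cands[, new_row, drop = FALSE]
  la$red_sum <- la$red_sum +
    cmi_scores_batch_cpp(yr, term_cols(b, integer(0)), b$cands, config$k)
  la$cred_sum <- la$cred_sum +
    cmi_scores_batch_cpp(yr, b$fut, b$cands, config$k)
  la
}

.la_totals <- function(la, nsel, nB, config) {
  wt <- la_weight(nsel, config$la_sum_over, nB)
  sgn <- if (config$la_cond_sign == "subtract") 1 else -1
  la$rel - wt * la$red_sum - sgn * wt * la$cred_sum
}

.la_greedy <- function(b, la, sel_rows, rem_rows, config) {
  totals <- .la_totals(la, length(sel_rows), nrow(b$cand_df), config)
  scores <- totals[rem_rows]
  top <- rem_rows[scores == max(scores)]
  best <- top[order(b$cand_df$lag[top], b$cand_df$var[top])][1L]
  list(row = best, cmi = max(scores), scores = scores)
}

# surrogate stop check on the LA criterion: the proposed term's raw series
# is shifted and every term involving it is recomputed per shift
.la_stop <- function(S, b, la, row, sel_rows, config, step_seed) {
  var <- b$cand_df$var[row]; lag <- as.integer(b$cand_df$lag[row])
  with_seed(step_seed, {
    shifts <- c(0L, draw_shifts(b$n, config$nsur))
  })
  src <- S[, var]
  none <- term_cols(b, integer(0))
  rel <- cmi_shift_surrogates_cpp(src, lag, b$fut, none, b$t0, config$k,
                                  shifts)
  set_rows <- if (config$la_sum_over == "all")
    setdiff(seq_len(nrow(b$cand_df)), row) else sel_rows
  pen <- numeric(length(shifts))
  sgn <- if (config$la_cond_sign == "subtract") 1 else -1
  for (r in set_rows) {
    yr <- b$cands[, r, drop = FALSE]
    pen <- pen +
      cmi_shift_surrogates_cpp(src, lag, yr, none, b$t0, config$k, shifts) +
      sgn * cmi_shift_surrogates_cpp(src, lag, yr, b$fut, b$t0, config$k,
                                     shifts)
  }
  wt <- la_weight(length(sel_rows), config$la_sum_over, nrow(b$cand_df))
  totals <- rel - wt * pen
  thr <- percentile_threshold(totals[-1L], config$la_alpha_stop)
  list(continue = totals[1L] > thr, cmi = totals[1L], threshold = thr)
}

#' Build a mixed embedding with the low-dimensional-approximation criterion
#'
#' Same greedy scheme as [build_mixed_embedding()], with the per-step CMI
#' criterion replaced by the LA score and the stopping surrogates computed
#' under the same approximation.
#'
#' @inheritParams build_mixed_embedding
#' @return A `mixed_embedding` with `criterion = "la"`.
#' @export
build_mixed_embedding_la <- function(data, target,
                                     config = analysis_config()) {
  S <- prepare_series(as_mv_series(data), config)
  .build_embedding(S, target, config, criterion = "la")
}

#' LATE measure for one ordered pair
#'
#' @inheritParams ptenue
#' @param embedding optionally, a prebuilt [build_mixed_embedding_la()]
#'   result for `target`.
#' @return A `causality_result`; significant exactly when the LA-selected
#'   embedding contains a term of the source.
#' @export
late <- function(data, source, target, config = analysis_config(),
                 embedding = NULL) {
  S <- prepare_series(as_mv_series(data), config)
  check_pair(S, source, target)
  if (is.null(embedding)) embedding <- .build_embedding(S, target, config, "la")
  .measure_from_embedding(S, embedding, source, config, "LATE")
}

#' LATE network
#'
#' @inheritParams pte_network
#' @return A `causality_network` with per-target LA embeddings.
#' @export
late_network <- function(data, config = analysis_config()) {
  .embedding_network(data, config, criterion = "la", measure = "LATE")
}
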