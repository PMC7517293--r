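#' @title Scoring estimated networks against ground truth
#' @description
#' An estimated directed network over K variables is compared with the
#' ground-truth adjacency over the `K * (K - 1)` ordered off-diagonal
#' pairs.  Performance is summarized by sensitivity (true positive rate),
#' specificity (true negative rate), and the F1-score
#' `2 TP / (2 TP + FP + FN)`, all reported as percentages; Monte-Carlo
#' summaries average the per-realization percentages rather than pooling
#' counts.
#' @name evaluation
NULL

#' Confusion counts of an estimated adjacency against the truth
#'
#' @param estimated,truth logical (or 0/1) square matrices of equal
#'   dimension, rows drive columns; diagonals are ignored.
#' @return An object of class `evaluation_result` with integer counts
#'   `TP`, `FP`, `TN`, `FN` (summing to `K * (K - 1)`) and the three
#'   metrics of [causality_metrics()].
#' @export
confusion_counts <- function(estimated, truth) {
  if (!all(dim(estimated) == dim(truth)))
    stop("estimated and truth adjacencies must have the same shape")
  K <- nrow(truth)
  off <- which(diag(K) == 0)
  est <- matrix(as.logical(estimated), K)[off]
  tru <- matrix(as.logical(truth), K)[off]
  if (anyNA(est) || anyNA(tru)) stop("adjacencies must not contain NA")
  counts <- list(TP = sum(est & tru), FP = sum(est & !tru),
                 TN = sum(!est & !tru), FN = sum(!est & tru), K = K)
  structure(c(counts, causality_metrics(counts)),
            class = "evaluation_result")
}

#' Sensitivity, specificity and F1-score from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `f1 = 2 TP / (2 TP + FP + FN)`, each as a percentage.  A truth with no
#' links (or no non-links) leaves the corresponding rate undefined and is
#' rejected; `f1` is 0 when `TP = 0` with errors present and 100 for the
#' empty perfect case.
#'
#' @param counts a list or `evaluation_result` with `TP`, `FP`, `TN`,
#'   `FN`.
#' @return A list with `sensitivity`, `specificity`, `f1` (percent).
#' @export
causality_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (TP + FN == 0L) stop("truth has no links: sensitivity undefined")
  if (TN + FP == 0L) stop("truth has no non-links: specificity undefined")
  f1 <- if (2L * TP + FP + FN == 0L) 100 else 200 * TP / (2L * TP + FP + FN)
  list(sensitivity = 100 * TP / (TP + FN),
       specificity = 100 * TN / (TN + FP),
       f1 = f1)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> TP", x$TP, "FP", x$FP, "TN", x$TN, "FN", x$FN,
      "| sensitivity", round(x$sensitivity, 2),
      "specificity", round(x$specificity, 2),
      "F1", round(x$f1, 2), "\n")
  invisible(x)
}

#' Mean metrics over realizations
#'
#' Arithmetic mean of the per-realization percentages (not pooled
#' counts).
#'
#' @param results nonempty list of `evaluation_result`s.
#' @return A list with mean `sensitivity`, `specificity`, `f1`.
#' @export
aggregate_metrics <- function(results) {
  if (!length(results)) stop("empty result list")
  list(sensitivity = mean(vapply(results, `[[`, numeric(1), "sensitivity")),
       specificity = mean(vapply(results, `[[`, numeric(1), "specificity")),
       f1 = mean(vapply(results, `[[`, numeric(1), "f1")))
}
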