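#' k-nearest-neighbor mutual information estimate
#'
#' KSG estimator of `I(X;Y)` in nats under the maximum norm: for every
#' point, `epsilon` is the distance to its k-th neighbor in the joint
#' `(X,Y)` space (self excluded), and the marginal neighbor counts use the
#' strict inequality `< epsilon`.  The estimate is
#' `psi(k) + psi(N) - <psi(n_x+1) + psi(n_y+1)>` and may be slightly
#' negative for independent data; no clipping is applied because
#' significance is always judged against surrogates, not against zero.
#'
#' @param x,y numeric vectors or matrices with equal row counts.
#' @param k number of neighbors.
#' @return The mutual information estimate in nats.
#' @examples
#' x <- rnorm(500); y <- x + rnorm(500)
#' knn_mi(x, y, k = 10)
#' @export
knn_mi <- function(x, y, k = 10L) {
  x <- as_points(x); y <- as_points(y)
  check_points(nrow(x), k, x, y)
  cmi_knn_cpp(x, y, empty_block(nrow(x)), as.integer(k))
}

#' k-nearest-neighbor conditional mutual information estimate
#'
#' Neighbor-count estimator of `I(X;Y|Z)` in nats (Frenzel-Pompe form):
#' `psi(k) - <psi(n_xz+1) + psi(n_yz+1) - psi(n_z+1)>`, with a shared
#' per-point `epsilon` taken in the full joint space.  With `z = NULL` the
#' conditioning block is empty and the result equals [knn_mi()] exactly.
#'
#' @param x,y,z numeric vectors or matrices with equal row counts; `z` may
#'   be `NULL` or have zero columns.
#' @inheritParams knn_mi
#' @return The conditional mutual information estimate in nats.
#' @export
knn_cmi <- function(x, y, z = NULL, k = 10L) {
  x <- as_points(x); y <- as_points(y)
  z <- if (is.null(z) || (is.matrix(z) && ncol(z) == 0L))
    empty_block(nrow(x)) else as_points(z)
  check_points(nrow(x), k, x, y, z)
  cmi_knn_cpp(x, y, z, as.integer(k))
}

as_points <- function(v) {
  if (is.null(dim(v))) v <- matrix(as.numeric(v), ncol = 1L)
  storage.mode(v) <- "double"
  v
}

empty_block <- function(n) matrix(numeric(0), nrow = n, ncol = 0L)

check_points <- function(n, k, ...) {
  for (m in list(...)) {
    if (nrow(m) != n) stop("point sets must have equal row counts")
    if (ncol(m) > 0L && !all(is.finite(m))) stop("point sets must be finite")
  }
  if (n < k + 1L)
    stop("need at least k + 1 = ", k + 1L, " points, got ", n)
  invisible(NULL)
}
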