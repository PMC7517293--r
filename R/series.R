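#' Multivariate time series container
#'
#' Wraps an `n x K` numeric matrix of observations (rows are time points,
#' columns are variables) with unique variable names.  All measures in the
#' package operate on this container.
#'
#' @param values numeric matrix or data frame, one column per variable.
#' @param names optional character vector of variable names; defaults to the
#'   column names of `values`, or `X1..XK`.
#' @return An object of class `mv_series`: the validated numeric matrix with
#'   column names, plus `n` and `K` attributes accessible via [dim()].
#' @examples
#' s <- mv_series(cbind(a = rnorm(100), b = rnorm(100)))
#' dim(s)
#' @export
mv_series <- function(values, names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix or data frame")
  n <- nrow(values); K <- ncol(values)
  if (n < 2L) stop("a series needs at least 2 time points (n = ", n, ")")
  if (K < 2L) stop("a multivariate series needs at least 2 variables (K = ", K, ")")
  if (is.null(names)) names <- colnames(values)
  if (is.null(names)) names <- paste0("X", seq_len(K))
  if (length(names) != K) stop("`names` must have one entry per column")
  if (anyDuplicated(names)) stop("variable names must be unique")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", bad[1L], ", column ", bad[2L],
         " (", names[bad[2L]], ")")
  }
  colnames(values) <- names
  rownames(values) <- NULL
  structure(values, class = c("mv_series", "matrix", "array"))
}

#' @export
print.mv_series <- function(x, ...) {
  cat("<mv_series> n =", nrow(x), "time points, K =", ncol(x), "variables:",
      paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

as_mv_series <- function(x) {
  if (inherits(x, "mv_series")) x else mv_series(x)
}

#' Column-wise z-score standardization
#'
#' Centers and scales every variable to sample mean 0 and standard
#' deviation 1.  All distance computations in the package run on
#' standardized series so that the maximum norm weighs variables
#' comparably.
#'
#' @param series an [mv_series()] (or coercible matrix).
#' @return An `mv_series` of the same shape and names.
#' @export
standardize <- function(series) {
  series <- as_mv_series(series)
  sds <- apply(series, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(series)[sds == 0], collapse = ", "),
         " (zero variance, cannot standardize)")
  }
  out <- scale(series, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  mv_series(out, colnames(series))
}

#' Read a delimited multivariate series from disk
#'
#' Expects one column per variable and a header row of variable names; the
#' field separator (comma or tab) is auto-detected from the header line.
#' Missing or non-numeric values are rejected with a row/column report.
#'
#' @param path path to the text file.
#' @return An [mv_series()].
#' @export
read_mv_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("need at least 2 columns, found ", ncol(df))
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("missing or non-numeric values, e.g. at data row ", bad[1L, 1L],
         ", column '", colnames(df)[bad[1L, 2L]], "' (",
         nrow(bad), " cell(s) affected)")
  }
  mv_series(mat, colnames(df))
}

#' Log-return transform
#'
#' Per-column transform `r_t = log(p_t) - log(p_{t-1})`, the usual
#' stationarizing step for price-level series before network inference.
#' The output has one fewer row than the input.
#'
#' @param series an [mv_series()] of strictly positive levels.
#' @return An `mv_series` of log returns.
#' @export
log_returns <- function(series) {
  series <- as_mv_series(series)
  if (any(series <= 0))
    stop("log returns require strictly positive values")
  lp <- log(unclass(series))
  mv_series(lp[-1L, , drop = FALSE] - lp[-nrow(lp), , drop = FALSE],
            colnames(series))
}

#' Export a series as delimited text
#'
#' @param series an [mv_series()].
#' @param path output path; comma-separated with a header row.
#' @return `path`, invisibly.
#' @export
write_mv_series <- function(series, path) {
  series <- as_mv_series(series)
  utils::write.csv(as.data.frame(unclass(series)), path, row.names = FALSE)
  invisible(path)
}
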