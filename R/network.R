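#' @title Causality result and network containers
#' @description Internal constructors for the per-pair result and the K x K
#'   network of results returned by the `*_network()` functions.  In every
#'   matrix the convention is rows drive columns.
#' @name causality-containers
NULL

causality_result <- function(measure, source, target, names, value,
                             p_value = NA_real_, significant, terms = NULL) {
  structure(list(measure = measure, source = source, target = target,
                 source_name = names[source], target_name = names[target],
                 value = value, p_value = p_value,
                 significant = significant, terms = terms),
            class = "causality_result")
}

#' @export
print.causality_result <- function(x, ...) {
  cat("<", x$measure, "> ", x$source_name, " -> ", x$target_name,
      ": value ", format(x$value, digits = 4),
      if (!is.na(x$p_value)) paste0(", p = ", format(x$p_value, digits = 4)),
      ", ", if (x$significant) "significant" else "not significant", "\n",
      sep = "")
  invisible(x)
}

causality_network <- function(measure, names, values, p_values, significant,
                              embeddings = NULL, config) {
  structure(list(measure = measure, names = names, K = length(names),
                 values = values, p_values = p_values,
                 significant = significant, embeddings = embeddings,
                 config = config),
            class = "causality_network")
}

#' @export
print.causality_network <- function(x, ...) {
  cat("<causality_network> measure", x$measure, "on K =", x$K,
      "variables;", sum(x$significant, na.rm = TRUE), "of",
      x$K * (x$K - 1L), "ordered pairs significant\n")
  cat("rows drive columns:\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Edge list of a causality network
#'
#' @param network a network returned by [pte_network()], [ptenue_network()]
#'   or [late_network()].
#' @param significant_only keep only significant links.
#' @return A data frame with columns `source`, `target`, `value`,
#'   `p_value`, `significant`, one row per ordered pair.
#' @export
network_edges <- function(network, significant_only = FALSE) {
  K <- network$K
  idx <- which(diag(K) == 0, arr.ind = TRUE)
  df <- data.frame(
    source = network$names[idx[, 1L]], target = network$names[idx[, 2L]],
    value = network$values[idx],
    p_value = if (is.null(network$p_values)) NA_real_ else network$p_values[idx],
    significant = network$significant[idx])
  df <- df[order(match(df$source, network$names),
                 match(df$target, network$names)), ]
  rownames(df) <- NULL
  if (significant_only) df <- df[df$significant, ]
  df
}

#' Significant-link adjacency matrix
#'
#' @inheritParams network_edges
#' @return A logical K x K matrix, rows drive columns, diagonal `FALSE`.
#' @export
significant_adjacency <- function(network) {
  adj <- network$significant
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  adj
}

#' Write a causality network to CSV
#'
#' Writes the measure-value matrix (rows drive columns) and the edge list.
#'
#' @inheritParams network_edges
#' @param path_matrix,path_edges output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_network_csv <- function(network, path_matrix = NULL, path_edges = NULL) {
  if (!is.null(path_matrix)) {
    m <- as.data.frame(network$values)
    colnames(m) <- network$names
    utils::write.csv(cbind(driver = network$names, m), path_matrix,
                     row.names = FALSE)
  }
  if (!is.null(path_edges))
    utils::write.csv(network_edges(network), path_edges, row.names = FALSE)
  invisible(c(path_matrix, path_edges))
}
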