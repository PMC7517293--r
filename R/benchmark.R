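#' @title Benchmark runner and real-data analysis
#' @description
#' [run_benchmark()] regenerates the simulation study at configurable
#' scale: for every (length, realization) cell of a plan it simulates the
#' chosen system, runs each requested measure's network operation, scores
#' the estimate against the ground truth, and aggregates
#' sensitivity/specificity/F1 over realizations.  [analyze_real_data()]
#' applies a measure to a user-supplied delimited series.  Everything is
#' seeded through deterministic substreams of one plan seed, so reruns
#' reproduce every number (and every output file) exactly.
#' @name benchmark
NULL

system_defaults <- function(system_id) {
  m <- switch(system_id, S1 = 5L, S2 = 1L, S3 = 2L,
              stop("unknown system '", system_id, "'"))
  list(m = m, Lmax = m + 1L)
}

#' Define a benchmark experiment plan
#'
#' @param system `"S1"`, `"S2"` or `"S3"`.
#' @param lengths time-series lengths to run.
#' @param realizations Monte-Carlo realizations per length.
#' @param measures subset of `c("PTE", "PTENUE", "LATE")`.
#' @param K,c S3 size and coupling strength (ignored otherwise).
#' @param config optional [analysis_config()]; by default the embedding
#'   dimension is the system's maximum generating delay (S1: 5, S2: 1,
#'   S3: 2) with `tau = 1` and `Lmax = m + 1`.
#' @param seed master seed for the whole plan.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(system, lengths, realizations = 100L,
                            measures = c("PTE", "PTENUE", "LATE"),
                            K = NULL, c = NULL, config = NULL, seed = 1L) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (!length(lengths)) stop("lengths must be nonempty")
  if (realizations < 1L) stop("realizations must be >= 1")
  if (is.null(config)) {
    d <- system_defaults(system)
    config <- analysis_config(m = d$m, Lmax = d$Lmax, seed = seed)
  }
  if (system == "S3" && (is.null(K) || is.null(c)))
    stop("S3 plans need K and c")
  structure(list(system = system, lengths = as.integer(lengths),
                 realizations = as.integer(realizations),
                 measures = measures, K = K, c = c, config = config,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

network_fun <- function(measure) {
  switch(measure, PTE = pte_network, PTENUE = ptenue_network,
         LATE = late_network, stop("unknown measure '", measure, "'"))
}

#' Run a benchmark plan
#'
#' @param plan an [experiment_plan()].
#' @param out_dir optional directory; when given, writes `results.csv`
#'   (tidy per-realization rows), `summary.csv` (mean metrics per measure
#'   and length plus a grand mean over lengths), per-cell detection-rate
#'   matrices `detection_<measure>_n<length>.csv` (percent of realizations
#'   in which each ordered pair was significant), and `manifest.json`.
#' @param verbose print per-cell progress with elapsed time.
#' @return A list with `results`, `summary`, `detection`, and `errors`
#'   (per-cell failures, recorded without aborting the run).
#' @export
run_benchmark <- function(plan, out_dir = NULL, verbose = TRUE) {
  rows <- list(); errors <- list(); det <- list()
  for (n in plan$lengths) {
    for (r in seq_len(plan$realizations)) {
      sim <- simulate_system(plan$system, n,
                             seed = derive_seed(plan$seed, "sim", n, r),
                             K = plan$K, c = plan$c)
      cfg <- plan$config
      cfg$seed <- derive_seed(plan$seed, "run", n, r)
      for (meas in plan$measures) {
        t0 <- proc.time()[["elapsed"]]
        cell <- tryCatch({
          net <- network_fun(meas)(sim$series, cfg)
          ev <- confusion_counts(significant_adjacency(net), sim$truth)
          key <- paste0(meas, "_n", n)
          det[[key]] <- if (is.null(det[[key]]))
            significant_adjacency(net) + 0 else
            det[[key]] + significant_adjacency(net)
          data.frame(system = plan$system, measure = meas,
                     K = ncol(sim$series),
                     c = if (is.null(plan$c)) NA_real_ else plan$c,
                     n = n, realization = r,
                     TP = ev$TP, FP = ev$FP, TN = ev$TN, FN = ev$FN,
                     sensitivity = ev$sensitivity,
                     specificity = ev$specificity, f1 = ev$f1)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          errors[[length(errors) + 1L]] <-
            data.frame(system = plan$system, measure = meas, n = n,
                       realization = r, message = conditionMessage(cell))
          if (verbose)
            message(sprintf("[%s n=%d r=%d] ERROR: %s", meas, n, r,
                            conditionMessage(cell)))
          next
        }
        rows[[length(rows) + 1L]] <- cell
        if (verbose)
          message(sprintf("[%s n=%d r=%d] F1 = %.2f (%.1fs)", meas, n, r,
                          cell$f1, proc.time()[["elapsed"]] - t0))
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (!is.null(results)) summarize_benchmark(results) else NULL
  detection <- lapply(det, function(m) 100 * m / plan$realizations)
  errors <- if (length(errors)) do.call(rbind, errors) else NULL
  out <- list(results = results, summary = summary, detection = detection,
              errors = errors, plan = plan)
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

summarize_benchmark <- function(results) {
  agg <- stats::aggregate(results[, c("sensitivity", "specificity", "f1")],
                          by = list(measure = results$measure, n = results$n),
                          FUN = mean)
  grand <- stats::aggregate(results[, c("sensitivity", "specificity", "f1")],
                            by = list(measure = results$measure), FUN = mean)
  grand$n <- NA_integer_
  rbind(agg, grand[, colnames(agg)])
}

write_benchmark <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$results))
    utils::write.csv(out$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  if (!is.null(out$summary))
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  for (key in names(out$detection))
    utils::write.csv(out$detection[[key]],
                     file.path(out_dir, paste0("detection_", key, ".csv")),
                     row.names = FALSE)
  if (!is.null(out$errors))
    utils::write.csv(out$errors, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
  plan <- out$plan
  manifest <- list(system = plan$system, lengths = plan$lengths,
                   realizations = plan$realizations,
                   measures = plan$measures, K = plan$K, c = plan$c,
                   seed = plan$seed,
                   config = unclass(plan$config),
                   package_version = as.character(utils::packageVersion("ptenet")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Infer a causality network from a delimited data file
#'
#' Reads a delimited multivariate series (header row of variable names,
#' comma or tab separated), optionally takes per-column log returns, runs
#' the selected measure's network operation, and reports the inferred
#' links together with a per-variable out-degree ranking (the "leading
#' forces" view: variables ordered by how many others they significantly
#' drive).
#'
#' @param path path to the delimited file.
#' @param measure one of `"PTENUE"`, `"PTE"`, `"LATE"`.
#' @param config an [analysis_config()].
#' @param log_returns transform levels to log returns first.
#' @param out_dir optional directory for `adjacency.csv`, `edges.csv` and
#'   `out_degree.csv`.
#' @return A list with `network`, `edges`, and `out_degree` (a data frame
#'   sorted by descending out-degree).
#' @export
analyze_real_data <- function(path, measure = c("PTENUE", "PTE", "LATE"),
                              config = analysis_config(),
                              log_returns = FALSE, out_dir = NULL) {
  measure <- match.arg(measure)
  series <- read_mv_series(path)
  if (log_returns) series <- log_returns(series)
  net <- network_fun(measure)(series, config)
  adj <- significant_adjacency(net)
  od <- data.frame(variable = net$names, out_degree = rowSums(adj))
  od <- od[order(-od$out_degree, od$variable), ]
  rownames(od) <- NULL
  edges <- network_edges(net)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_network_csv(net, file.path(out_dir, "adjacency.csv"),
                      file.path(out_dir, "edges.csv"))
    utils::write.csv(od, file.path(out_dir, "out_degree.csv"),
                     row.names = FALSE)
  }
  list(network = net, edges = edges, out_degree = od)
}

#' Score an estimated adjacency against a ground-truth adjacency
#'
#' Both inputs may be matrices or paths to CSV files of 0/1 indicators
#' (header row; an optional leading character column of row labels is
#' dropped).
#'
#' @param estimated,truth adjacency matrices or CSV paths.
#' @return An `evaluation_result`.
#' @export
score_networks <- function(estimated, truth) {
  confusion_counts(read_adjacency(estimated), read_adjacency(truth))
}

read_adjacency <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    df <- utils::read.table(x, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.numeric(df[[1L]]) && !is.logical(df[[1L]])) df <- df[, -1L]
    x <- as.matrix(df)
  }
  if (nrow(x) != ncol(x)) stop("adjacency must be square")
  x
}
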