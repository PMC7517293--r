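# shared fixtures: everything is generated in code, seeded

# small config for quick unit tests (few surrogates where the test does not
# exercise the significance machinery itself)
quick_config <- function(...) {
  analysis_config(nsur = 30L, ...)
}

# K independent Gaussian white-noise channels: the fully uncoupled null
noise_series <- function(n, K, seed) {
  with_seed_test(seed, mv_series(matrix(rnorm(n * K), n, K)))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# mean metrics of a measure on simulated realizations
run_cell <- function(simfun, netfun, cfg_args, seeds) {
  evs <- lapply(seeds, function(s) {
    sim <- simfun(s)
    cfg <- do.call(analysis_config, c(cfg_args, list(seed = s)))
    net <- netfun(sim$series, cfg)
    confusion_counts(significant_adjacency(net), sim$truth)
  })
  aggregate_metrics(evs)
}
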