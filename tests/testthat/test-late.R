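test_that("with nothing selected the LA score is pure relevance", {
  sim <- simulate_s2(300, seed = 1)
  cfg <- quick_config(m = 1, Lmax = 2, seed = 1)
  sc <- la_score(sim$series, 2, lagged_term(1, 0), config = cfg)
  expect_identical(sc$total, sc$relevance)
  expect_identical(sc$redundancy, 0)
  expect_identical(sc$conditional_redundancy, 0)
})

test_that("the selection-loop criterion equals a term-by-term recomposition", {
  sim <- simulate_s2(300, seed = 2)
  cfg <- quick_config(m = 1, Lmax = 2, seed = 2)
  emb <- build_mixed_embedding_la(sim$series, 3, cfg)
  expect_gte(nrow(emb$trace), 1L)
  for (i in seq_len(nrow(emb$trace))) {
    row <- emb$trace[i, ]
    sel <- emb$terms[seq_len(i - 1L), c("var", "lag"), drop = FALSE]
    sc <- la_score(sim$series, 3, lagged_term(row$var, row$lag),
                   selected = if (i > 1L) sel else NULL, config = cfg)
    expect_equal(row$criterion, sc$total, tolerance = 1e-6)
  }
})

test_that("a near-duplicate of a selected term is penalized", {
  # strongly autocorrelated channels: lag-1 copy is redundant with lag-0
  set.seed(3)
  n <- 400
  ar <- function() as.numeric(arima.sim(list(ar = 0.95), n))
  dat <- cbind(a = ar(), b = ar())
  cfg <- quick_config(m = 1, Lmax = 2, seed = 3, la_cond_sign = "subtract")
  sc <- la_score(dat, 2, lagged_term(1, 1),
                 selected = data.frame(var = 1L, lag = 0L), config = cfg)
  expect_gt(sc$redundancy, 0.5)
  expect_lt(sc$total, sc$relevance)
})

test_that("score components recombine under both sign conventions", {
  sim <- simulate_s2(300, seed = 4)
  sel <- data.frame(var = c(2L, 1L), lag = c(0L, 0L))
  for (sgn in c("add", "subtract")) {
    cfg <- quick_config(m = 1, Lmax = 2, seed = 4, la_cond_sign = sgn)
    sc <- la_score(sim$series, 3, lagged_term(2, 1), selected = sel,
                   config = cfg)
    expect_length(sc$components$redundancy, 2L)
    expect_length(sc$components$conditional_redundancy, 2L)
    wt <- 2 / 2
    ref <- sc$relevance - wt * sum(sc$components$redundancy) -
      (if (sgn == "subtract") 1 else -1) * wt *
        sum(sc$components$conditional_redundancy)
    expect_equal(sc$total, ref, tolerance = 1e-12)
  }
})

test_that("summing over the whole candidate pool is a distinct reading", {
  sim <- simulate_s2(300, seed = 5)
  cfg_all <- quick_config(m = 1, Lmax = 1, seed = 5, la_sum_over = "all")
  sc <- la_score(sim$series, 2, lagged_term(1, 0), config = cfg_all)
  # sums run over the other |B| - 1 = 5 candidates even with nothing selected
  expect_length(sc$components$redundancy, 5L)
  expect_false(identical(sc$total, sc$relevance))
})

test_that("LA embeddings on a pure-noise target are almost always empty", {
  # stringent stopping level isolates the null calibration of the rule
  empties <- vapply(1:10, function(s) {
    emb <- build_mixed_embedding_la(noise_series(384, 3, seed = 300 + s), 2,
                                    analysis_config(m = 1, Lmax = 2, seed = s,
                                                    la_alpha_stop = 0.01))
    nrow(emb$terms) == 0L
  }, logical(1))
  expect_gte(mean(empties), 0.7)
})

test_that("LATE declares links exactly when the source contributes terms", {
  sim <- simulate_s2(512, seed = 6)
  cfg <- analysis_config(m = 1, Lmax = 2, seed = 6)
  emb <- build_mixed_embedding_la(sim$series, 3, cfg)
  net_row <- late(sim$series, 1, 3, cfg, embedding = emb)
  expect_identical(net_row$significant, any(emb$terms$var == 1L))
  # a strong nonlinear driver on ample data is selected
  expect_true(net_row$significant)
  # identical embedding reused by the network path
  net <- late_network(sim$series, cfg)
  expect_identical(net$values[1, 3], net_row$value)
})

test_that("LATE is less specific than PTENUE on the linear VAR", {
  spec_l <- spec_p <- numeric(2)
  for (s in 1:2) {
    sim <- simulate_s1(400, seed = s)
    cfg <- analysis_config(m = 5, Lmax = 6, seed = s)
    evl <- confusion_counts(significant_adjacency(late_network(sim$series, cfg)),
                            sim$truth)
    evp <- confusion_counts(significant_adjacency(ptenue_network(sim$series, cfg)),
                            sim$truth)
    spec_l[s] <- evl$specificity; spec_p[s] <- evp$specificity
  }
  expect_lte(mean(spec_l), mean(spec_p))
})
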