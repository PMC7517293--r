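test_that("greedy step matches an exhaustive scan of the criterion", {
  sim <- simulate_s2(400, seed = 1)
  cfg <- quick_config(m = 1, Lmax = 2, seed = 6)
  sel <- data.frame(var = 2L, lag = 0L)
  g <- greedy_step(sim$series, target = 2, selected = sel, config = cfg)
  # oracle: score every candidate with the generic estimator
  S <- ptenet:::prepare_series(sim$series, cfg)
  b <- ptenet:::nue_blocks(S, 2, cfg)
  cond <- b$cands[, ptenet:::match_terms(b$cand_df, sel), drop = FALSE]
  scores <- vapply(seq_len(nrow(b$cand_df)), function(r)
    knn_cmi(b$cands[, r], b$fut, cond, cfg$k), numeric(1))
  rem <- setdiff(seq_len(nrow(b$cand_df)),
                 ptenet:::match_terms(b$cand_df, sel))
  best <- rem[which.max(scores[rem])]
  expect_identical(g$term$var, b$cand_df$var[best])
  expect_identical(g$term$lag, b$cand_df$lag[best])
  expect_equal(g$cmi, max(scores[rem]), tolerance = 1e-6)
})

test_that("a single remaining candidate is returned unconditionally", {
  s <- noise_series(200, 2, seed = 2)
  cfg <- quick_config(m = 1, Lmax = 1, seed = 1)
  full <- candidate_set(2, 1)
  sel <- full[-2, ]
  g <- greedy_step(s, target = 1, selected = sel, config = cfg)
  expect_identical(c(g$term$var, g$term$lag),
                   c(full$var[2], full$lag[2]))
  expect_error(greedy_step(s, target = 1, selected = full, config = cfg),
               "no remaining")
})

test_that("the first selected term for a driven VAR target is a parent variable", {
  # predicting x3[t+1]: generating variables are x3, x1, x2 (never x4);
  # the first, unconditional step may pick an autocorrelated lag of a
  # parent rather than the generating lag itself
  for (s in 3:4) {
    sim <- simulate_s1(1024, seed = s)
    cfg <- analysis_config(m = 5, Lmax = 6, seed = s)
    g <- greedy_step(sim$series, target = 3, config = cfg)
    expect_true(g$term$var %in% c(1L, 2L, 3L))
    expect_gt(g$cmi, 0.2)
  }
})

test_that("stop check accepts an informative term and is seed-stable", {
  sim <- simulate_s2(512, seed = 4)
  cfg <- analysis_config(m = 1, Lmax = 2, seed = 4)
  chk <- stop_check(sim$series, target = 2, term = lagged_term(2, 0),
                    config = cfg)
  expect_true(chk$continue)
  chk2 <- stop_check(sim$series, target = 2, term = lagged_term(2, 0),
                     config = cfg)
  expect_identical(chk$threshold, chk2$threshold)
})

test_that("embeddings on a pure-noise target are almost always empty", {
  empties <- vapply(1:15, function(s) {
    emb <- build_mixed_embedding(noise_series(384, 3, seed = 100 + s), 2,
                                 analysis_config(m = 1, Lmax = 2, seed = s))
    nrow(emb$terms) == 0L
  }, logical(1))
  expect_gte(mean(empties), 0.8)
})

test_that("the coupled Henon target selects both neighbors and no junk lag", {
  for (s in 1:2) {
    sim <- simulate_s3(3, 0.3, 1024, seed = s)
    emb <- build_mixed_embedding(sim$series, 2,
                                 analysis_config(m = 2, Lmax = 3, seed = s))
    expect_true(all(c(1L, 3L) %in% emb$terms$var))
  }
})

test_that("embedding construction is deterministic given the seed", {
  sim <- simulate_s2(512, seed = 5)
  cfg <- analysis_config(m = 1, Lmax = 2, seed = 11)
  e1 <- build_mixed_embedding(sim$series, 3, cfg)
  e2 <- build_mixed_embedding(sim$series, 3, cfg)
  expect_identical(e1$terms, e2$terms)
  expect_identical(e1$trace, e2$trace)
  expect_false(anyDuplicated(e1$terms[, c("var", "lag")]) > 0)
})

test_that("a source with no selected terms yields value 0 and no link", {
  sim <- simulate_s2(512, seed = 6)
  dat <- cbind(unclass(sim$series),
               X4 = with_seed_test(42, rnorm(512)))
  cfg <- analysis_config(m = 1, Lmax = 2, seed = 2)
  emb <- build_mixed_embedding(dat, 2, cfg)
  if (!any(emb$terms$var == 4L)) {
    r <- ptenue(dat, 4, 2, cfg, embedding = emb)
    expect_identical(r$value, 0)
    expect_false(r$significant)
  }
  r13 <- ptenue(dat, 1, 2, cfg, embedding = emb)
  expect_true(is.finite(r13$value))
})

test_that("one embedding per target serves every driver query", {
  sim <- simulate_s3(3, 0.3, 512, seed = 7)
  cfg <- analysis_config(m = 2, Lmax = 3, seed = 7)
  net <- ptenue_network(sim$series, cfg)
  emb <- build_mixed_embedding(sim$series, 2, cfg)
  expect_identical(net$embeddings[["X2"]]$terms, emb$terms)
  r <- ptenue(sim$series, 1, 2, cfg, embedding = emb)
  expect_identical(net$values[1, 2], r$value)
})

test_that("embedding partition is disjoint and exhaustive", {
  sim <- simulate_s3(3, 0.3, 512, seed = 8)
  emb <- build_mixed_embedding(sim$series, 2,
                               analysis_config(m = 2, Lmax = 3, seed = 8))
  p <- embedding_partition(emb, source = 1)
  expect_identical(nrow(p$w_X) + nrow(p$w_Y) + nrow(p$w_Z), nrow(emb$terms))
  expect_true(all(p$w_X$var == 1L))
  expect_true(all(p$w_Y$var == 2L))
})

test_that("the embedding report serializes the selection audit trail", {
  sim <- simulate_s2(512, seed = 9)
  emb <- build_mixed_embedding(sim$series, 2,
                               analysis_config(m = 1, Lmax = 2, seed = 9))
  js <- jsonlite::fromJSON(embedding_report(emb))
  expect_identical(js$target, "X2")
  expect_identical(js$criterion, "cmi")
  expect_true(all(c("step", "var", "lag", "criterion", "threshold",
                    "accepted") %in% names(js$trace)))
  f <- tempfile(fileext = ".json")
  embedding_report(emb, f)
  expect_identical(jsonlite::fromJSON(f)$target, "X2")
  unlink(f)
})
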