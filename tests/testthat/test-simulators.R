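test_that("realizations are bit-reproducible by seed", {
  a <- simulate_s1(256, seed = 42); b <- simulate_s1(256, seed = 42)
  expect_identical(unclass(a$series), unclass(b$series))
  expect_false(identical(unclass(a$series),
                         unclass(simulate_s1(256, seed = 43)$series)))
  h1 <- simulate_s3(5, 0.3, 256, seed = 9)
  h2 <- simulate_s3(5, 0.3, 256, seed = 9)
  expect_identical(unclass(h1$series), unclass(h2$series))
})

test_that("ground truths list the documented links and no self-links", {
  t1 <- ground_truth_adjacency("S1")
  expect_identical(sum(t1), 4L)
  expect_true(t1[1, 3] && t1[2, 1] && t1[2, 3] && t1[4, 2])
  t2 <- ground_truth_adjacency("S2")
  expect_identical(sum(t2), 3L)
  expect_true(t2[1, 2] && t2[1, 3] && t2[2, 3])
  t3 <- ground_truth_adjacency("S3", 9)
  expect_identical(sum(t3), 14L)
  expect_identical(sum(ground_truth_adjacency("S3", 50)), 96L)
  expect_true(all(!diag(t1), !diag(t2), !diag(t3)))
  expect_error(ground_truth_adjacency("S9"), "unknown system")
})

test_that("the linear VAR is stationary: companion spectral radius < 1", {
  # coefficient matrices A1..A5 of the order-5 system
  A <- array(0, c(4, 4, 5))
  A[1, 1, 1] <- 0.8; A[2, 1, 4] <- 0.65
  A[2, 2, 1] <- 0.6; A[4, 2, 5] <- 0.6
  A[3, 3, 3] <- 0.5; A[1, 3, 1] <- -0.6; A[2, 3, 4] <- 0.4
  A[4, 4, 1] <- 1.2; A[4, 4, 2] <- -0.7
  # companion: x(t) stacked over 5 lags (rows = driving var in A[,j,l])
  comp <- matrix(0, 20, 20)
  for (l in 1:5) comp[1:4, (4 * l - 3):(4 * l)] <- t(A[, , l])
  comp[5:20, 1:16] <- diag(16)
  expect_lt(max(Mod(eigen(comp, only.values = TRUE)$values)), 1)
})

test_that("the linear VAR output is variance-stable across thirds", {
  s <- simulate_s1(18000, seed = 1)$series
  thirds <- split(seq_len(nrow(s)), rep(1:3, each = 6000))
  v <- sapply(thirds, function(ix) apply(s[ix, ], 2, var))
  per_channel_ratio <- apply(v, 1, function(x) max(x) / min(x))
  expect_lt(max(per_channel_ratio), 1.5)
})

test_that("the zero-noise linear VAR decays to the origin", {
  s <- simulate_s1(256, seed = 2, noise_sd = 0)
  expect_lt(max(abs(s$series)), 1e-6)
})

test_that("the nonlinear VAR stays bounded over a long run", {
  s <- simulate_s2(100000, seed = 3)$series
  expect_true(all(abs(s) < 10))
})

test_that("decoupled channels of the nonlinear VAR share no information", {
  s <- simulate_s2(2048, seed = 4, coupled = FALSE)$series
  expect_lt(abs(knn_mi(s[, 1], s[, 2], 10)), 0.05)
  expect_lt(abs(knn_mi(s[, 2], s[, 3], 10)), 0.05)
})

test_that("Henon lattices stay on the attractor for benchmark couplings", {
  for (K in c(3, 9)) for (cc in c(0.1, 0.3)) {
    for (s in 1:8) {
      x <- simulate_s3(K, cc, 512, seed = s)$series
      expect_true(all(abs(x) <= 5))
    }
  }
  x50 <- simulate_s3(50, 0.3, 512, seed = 1)$series
  expect_true(all(abs(x50) <= 5))
})

test_that("uncoupled Henon maps are mutually uninformative", {
  s <- simulate_s3(3, 0, 2048, seed = 5)$series
  expect_lt(abs(knn_mi(s[, 1], s[, 2], 10)), 0.05)
  expect_lt(abs(knn_mi(s[, 1], s[, 3], 10)), 0.05)
})

test_that("a realization exports with a faithful JSON sidecar", {
  sim <- simulate_s3(3, 0.3, 128, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_realization(sim, f)
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_identical(side$system, "S3")
  expect_identical(nrow(side$truth_edges), 2L)
  expect_identical(sort(side$truth_edges$target), c("X2", "X2"))
  back <- read_mv_series(f)
  expect_equal(unclass(back), unclass(sim$series), tolerance = 1e-12)
  unlink(c(f, paste0(f, ".json")))
})
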