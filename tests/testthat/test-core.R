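test_that("standardize gives zero mean, unit sd, and is idempotent", {
  s <- noise_series(200, 3, seed = 1)
  z <- standardize(3 * unclass(s) + 7)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unclass(standardize(z)), unclass(z), tolerance = 1e-12)
})

test_that("standardize rejects a constant column by name", {
  m <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_error(standardize(m), "b")
})

test_that("mv_series validates shape, names and finiteness", {
  expect_error(mv_series(matrix(1:4, 4, 1)), "2 variables")
  expect_error(mv_series(matrix(1, 1, 2)), "2 time points")
  expect_error(mv_series(matrix(rnorm(20), 10, 2), names = c("a", "a")),
               "unique")
  m <- matrix(rnorm(20), 10, 2); m[3, 2] <- NA
  expect_error(mv_series(m), "row 3, column 2")
})

test_that("lag_matrix matches direct enumeration on random small cases", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(8:20, 1)
    s <- mv_series(matrix(rnorm(n * 3), n, 3))
    nt <- sample(1:4, 1)
    terms <- lapply(seq_len(nt), function(i)
      lagged_term(sample(1:3, 1), sample(0:(n - 3), 1)))
    lm <- lag_matrix(s, terms, target = 2)
    max_lag <- max(vapply(terms, `[[`, integer(1), "lag"))
    expect_identical(nrow(lm$X), n - max_lag - 1L)
    for (j in seq_len(nt)) {
      tj <- terms[[j]]
      expect_identical(lm$X[, j], unname(s[lm$t_range - tj$lag, tj$var]))
    }
    expect_identical(lm$y, unname(s[lm$t_range + 1L, 2]))
  }
})

test_that("lag_matrix rejects lags that leave no valid rows", {
  s <- noise_series(10, 2, seed = 2)
  expect_error(lag_matrix(s, lagged_term(1, 9), target = 2), "no valid rows")
  expect_identical(nrow(lag_matrix(s, lagged_term(1, 0), target = 2)$X), 9L)
})

test_that("delimited reader autodetects separators and reports bad cells", {
  s <- noise_series(30, 3, seed = 3)
  fc <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".tsv")
  write_mv_series(s, fc)
  write.table(as.data.frame(unclass(s)), ft, sep = "\t", row.names = FALSE)
  expect_equal(unclass(read_mv_series(fc)), unclass(s), tolerance = 1e-12)
  expect_equal(unclass(read_mv_series(ft)), unclass(s), tolerance = 1e-12)
  df <- as.data.frame(unclass(s)); df[5, 2] <- NA
  fbad <- tempfile(fileext = ".csv")
  write.csv(df, fbad, row.names = FALSE)
  expect_error(read_mv_series(fbad), "row 5")
  unlink(c(fc, ft, fbad))
})

test_that("log returns shorten by one and require positive levels", {
  p <- mv_series(cbind(a = exp(cumsum(rnorm(50, sd = 0.01))),
                       b = exp(cumsum(rnorm(50, sd = 0.01)))))
  r <- log_returns(p)
  expect_identical(nrow(r), 49L)
  expect_equal(r[1, "a"], log(p[2, "a"]) - log(p[1, "a"]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(log_returns(cbind(a = c(-1, 1, 2), b = c(1, 2, 3))),
               "positive")
})

test_that("candidate set enumerates K * (Lmax + 1) unique terms", {
  b <- candidate_set(4, 6)
  expect_identical(nrow(b), 4L * 7L)
  expect_false(anyDuplicated(b) > 0)
})

test_that("seed substreams are deterministic and label-sensitive", {
  expect_identical(ptenet:::derive_seed(7, "pte", 1, 2),
                   ptenet:::derive_seed(7, "pte", 1, 2))
  expect_false(ptenet:::derive_seed(7, "pte", 1, 2) ==
                 ptenet:::derive_seed(7, "pte", 2, 1))
  expect_false(ptenet:::derive_seed(7, "nue", 1) ==
                 ptenet:::derive_seed(7, "pte", 1))
})
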