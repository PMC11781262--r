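test_that("icc handles the trivial cases exactly", {
  set.seed(11)
  v <- rnorm(20)
  expect_identical(icc(cbind(a = v, b = v)), 1)        # identical raters
  expect_identical(icc(cbind(a = v)), 1)               # singleton convention
  expect_identical(icc(cbind(a = v, b = v, c = v)), 1)
})

test_that("icc matches an independent ANOVA oracle", {
  x <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 5))
  expect_equal(icc(x), icc_oracle(x), tolerance = 1e-12)
  expect_equal(icc(x), 0.96695618, tolerance = 1e-7)  # frozen oracle value

  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    k <- sample(2:6, 1)
    y <- matrix(rnorm(n * k), n, k)
    colnames(y) <- paste0("f", 1:k)
    expect_equal(icc(y), icc_oracle(y), tolerance = 1e-10)
  }
})

test_that("icc is invariant to affine rescaling and bounded by 1", {
  set.seed(31)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x
  y[, 2] <- 5 + 3 * y[, 2]  # affine rescale of one column
  y[, 3] <- y[, 3] / 7 - 2
  expect_equal(icc(x), icc(y), tolerance = 1e-12)

  for (i in 1:50) {
    n <- sample(4:30, 1)
    k <- sample(2:5, 1)
    z <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("f", 1:k)))
    expect_lte(icc(z), 1)
  }
})

test_that("two-feature icc follows the closed form in the correlation", {
  # for standardized pairs, ICC = ((1+r) - (n-1)(1-r)/n) / ((1+r) + (n-1)(1-r)/n),
  # which converges to the Pearson correlation as n grows
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    r <- pearson_oracle(a, b)
    closed <- ((1 + r) - (n - 1) * (1 - r) / n) /
      ((1 + r) + (n - 1) * (1 - r) / n)
    expect_equal(icc(cbind(a = a, b = b)), closed, tolerance = 1e-12)
  }
  n <- 2000
  a <- rnorm(n)
  b <- 0.6 * a + rnorm(n)
  expect_equal(icc(cbind(a = a, b = b)), cor(a, b), tolerance = 0.01)
})

test_that("icc rejects degenerate input", {
  expect_error(icc(cbind(a = rep(2, 5), b = rnorm(5))), "constant feature")
  expect_error(icc(cbind(a = 1)), "at least 2 samples")
  # negative ICC is legal output
  a <- c(1, 2, 3, 4)
  expect_lt(icc(cbind(a = a, b = rev(a))), 0)
})

test_that("correlation_distance matches the hand formula and its invariants", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3))
  d <- correlation_distance(x)
  expect_equal(d[1, 2], 1 - pearson_oracle(x[, "a"], x[, "b"]),
               tolerance = 1e-12)
  expect_equal(d[1, 2], 0.2, tolerance = 1e-12)
  expect_equal(d[1, 1], 0)
  a <- rnorm(10)
  d2 <- correlation_distance(cbind(a = a, b = -a))
  expect_equal(d2[1, 2], 2, tolerance = 1e-12)
  expect_equal(correlation_distance(cbind(a = a, b = -a),
                                    "one_minus_abs_r")[1, 2],
               0, tolerance = 1e-12)

  set.seed(51)
  for (i in 1:20) {
    z <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, paste0("f", 1:6)))
    dm <- correlation_distance(z)
    expect_equal(dm, t(dm), tolerance = 1e-12)
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 2))
  }
  expect_error(correlation_distance(cbind(a = rep(1, 5), b = rnorm(5))),
               "constant feature")
})

test_that("reduce_mean standardizes then averages", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  z2 <- (c(2, 4, 9) - 5) / sqrt(13)
  expect_equal(reduce_mean(x), (c(-1, 0, 1) + z2) / 2, tolerance = 1e-12)
  expect_equal(reduce_mean(x), c(-0.9160251, -0.1386750, 1.0547002),
               tolerance = 1e-6)  # frozen hand arithmetic

  v <- rnorm(8)
  expect_equal(reduce_mean(cbind(a = v)), as.numeric(scale(v)),
               tolerance = 1e-12)
  expect_equal(reduce_mean(cbind(a = v, b = v)), as.numeric(scale(v)),
               tolerance = 1e-12)
  expect_error(reduce_mean(cbind(a = rep(1, 4))), "constant feature")
})

test_that("reduce_pc1 matches an eigen-decomposition oracle", {
  set.seed(61)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  z <- scale(x)
  ev <- eigen(cor(x))$vectors[, 1]
  oracle <- as.numeric(z %*% ev)
  if (cor(oracle, rowMeans(z)) < 0) oracle <- -oracle
  expect_equal(reduce_pc1(x), oracle, tolerance = 1e-8)

  v <- rnorm(12)
  expect_equal(reduce_pc1(cbind(a = v)), as.numeric(scale(v)),
               tolerance = 1e-12)
  # rank-1 case: proportional to the shared standardized column
  w <- 3 * v + 2
  p <- reduce_pc1(cbind(a = v, b = w))
  expect_equal(abs(cor(p, v)), 1, tolerance = 1e-12)
  expect_gt(cor(p, scale(v)[, 1]), 0)
})

test_that("mean and pc1 reducers agree on tight exchangeable blocks", {
  sim <- generate_block_data(n_samples = 200, block_sizes = 6, rho = 0.9,
                             seed = 71)
  expect_gt(cor(reduce_mean(sim$data), reduce_pc1(sim$data)), 0.99)
})

test_that("normalized mutual information behaves at its limits", {
  set.seed(81)
  v <- rnorm(300)
  expect_equal(mutual_information_metric(cbind(a = v, b = v), v), 1,
               tolerance = 1e-12)
  expect_identical(mutual_information_metric(cbind(a = v), rnorm(300)), 1)

  # independent draws: score near zero
  x <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  expect_lt(mutual_information_metric(x, rnorm(2000)), 0.02)

  expect_error(mutual_information_metric(cbind(a = rep(0, 9), b = rnorm(9)),
                                         rnorm(9)),
               "constant feature")
  expect_error(mutual_information_metric(cbind(a = rnorm(9), b = rnorm(9)),
                                         rep(1, 9)),
               "constant feature")
})

test_that("normalized MI tracks the Gaussian closed form", {
  rho <- 0.8
  n <- 5000
  set.seed(91)
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  est <- mutual_information_metric(cbind(a = a, b = b), b)

  # oracle: closed-form MI normalized by independently computed binned
  # marginal entropies (equal-frequency bins are near-uniform, H ~ log B)
  B <- max(2, ceiling(n^(1 / 3)))
  hx <- -sum(rep(1 / B, B) * log(rep(1 / B, B)))
  expected <- -0.5 * log(1 - rho^2) / hx
  expect_equal(est, expected, tolerance = 0.05)

  # estimator stays in [0, 1] across dependence strengths
  for (r in c(0, 0.3, 0.6, 0.9, 0.99)) {
    y <- r * a + sqrt(1 - r^2) * rnorm(n)
    s <- mutual_information_metric(cbind(a = a, y = y), y)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})
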