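test_that("the Bayes factor agrees with an independent quadrature oracle", {
  # grid over (r, n): relative error below 1e-6 against the Euler-integral
  # trapezoid oracle
  grid <- expand.grid(r = c(-0.8, -0.5, -0.2, 0, 0.2, 0.4, 0.6, 0.75, 0.9),
                      n = c(10, 33, 60))
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; n <- grid$n[i]
    got <- bf10_from_r(r, n)
    want <- bf10_oracle(r, n)
    expect_lt(abs(got - want) / want, 1e-6)
  }
})

test_that("orthogonal vectors of length 33 give a Bayes factor below one", {
  x <- c(rep(1, 16), rep(-1, 16), 0)
  y <- c(rep(c(1, -1), 16), 0)
  expect_equal(cor(x, y), 0)
  res <- pearson_bf10(x, y)
  expect_equal(res$r, 0)
  expect_lt(res$bf10, 1)
  expect_equal(res$bf10, bf10_oracle(0, 33), tolerance = 1e-6)
})

test_that("perfect correlation dominates and degenerate input errors", {
  x <- seq_len(12)
  res <- pearson_bf10(x, 2 * x + 3)
  expect_gt(res$bf10, 1e3)
  expect_error(pearson_bf10(rep(1, 10), rnorm(10)), "must both vary")
  expect_error(pearson_bf10(1:3, 3:1), "at least 4")
})

test_that("evidence increases with effect size and with sample size", {
  bfs_r <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), bf10_from_r, numeric(1), n = 30)
  expect_true(all(diff(bfs_r) > 0))
  bfs_n <- vapply(c(10, 20, 40, 80), function(n) bf10_from_r(0.5, n), numeric(1))
  expect_true(all(diff(bfs_n) > 0))
  # two-sided: sign of r does not matter
  expect_equal(bf10_from_r(0.5, 30), bf10_from_r(-0.5, 30), tolerance = 1e-9)
})

test_that("Bayes factors map onto the printed evidence scale", {
  expect_equal(classify_bf(12.61), "strong evidence for H1")
  expect_equal(classify_bf(0.22), "moderate evidence for H0")
  expect_equal(classify_bf(1), "anecdotal evidence (no direction)")
  expect_equal(classify_bf(2), "anecdotal evidence for H1")
  expect_equal(classify_bf(3), "moderate evidence for H1")     # boundary up
  expect_equal(classify_bf(10), "strong evidence for H1")
  expect_equal(classify_bf(35), "very strong evidence for H1")
  expect_equal(classify_bf(150), "extreme evidence for H1")
  expect_equal(classify_bf(1 / 3), "moderate evidence for H0")
  expect_equal(classify_bf(1 / 20), "strong evidence for H0")
  expect_error(classify_bf(0), "positive")
})

test_that("bootstrap Mahalanobis flags a far point and agrees with the chi-square oracle", {
  withr::with_seed(9, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30, 0, 0.5)
  })
  x <- c(x, 10); y <- c(y, -10)
  hits <- mahalanobis_bootstrap_outliers(x, y, seed = 4)
  expect_true(31L %in% hits)
  # plain Mahalanobis oracle on the clean points also isolates 31
  d2 <- stats::mahalanobis(cbind(x, y), colMeans(cbind(x[1:30], y[1:30])),
                           cov(cbind(x[1:30], y[1:30])))
  expect_gt(d2[31], qchisq(0.975, 2))
  expect_true(all(d2[setdiff(hits, 31L)] > qchisq(0.9, 2)))

  # determinism under a fixed seed
  expect_identical(hits, mahalanobis_bootstrap_outliers(x, y, seed = 4))
  expect_error(mahalanobis_bootstrap_outliers(1:10, 2 * (1:10), seed = 1),
               "singular")
})

test_that("clean bivariate data is rarely flagged", {
  withr::with_seed(12, {
    x <- rnorm(40); y <- rnorm(40)
  })
  expect_lte(length(mahalanobis_bootstrap_outliers(x, y, seed = 2)), 2)
})

test_that("correlation comparisons reduce to their closed forms", {
  eq <- compare_correlations(0.5, 0.5, 40, mode = "dependent", r_between = 0.3)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  ind <- compare_correlations(0.6, 0.0, 50, 50, mode = "independent")
  z_manual <- (atanh(0.6) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(ind$z, z_manual)
  expect_lt(ind$p, 0.05)

  expect_error(compare_correlations(1, 0.5, 30), "magnitude 1")
  expect_error(compare_correlations(0.5, 0.2, 30, mode = "dependent"),
               "r_between")
})

test_that("the dependent comparison matches a permutation null on trivariate data", {
  withr::with_seed(33, {
    n <- 60
    shared <- rnorm(n)
    a <- 0.5 * shared + rnorm(n, 0, 0.8)
    b <- 0.5 * shared + rnorm(n, 0, 0.8)
  })
  r1 <- cor(shared, a); r2 <- cor(shared, b); rab <- cor(a, b)
  obs <- compare_correlations(r1, r2, n, mode = "dependent", r_between = rab)

  # permutation null: swap a/b within subjects at random
  zs <- withr::with_seed(34, {
    vapply(1:400, function(i) {
      swap <- runif(n) < 0.5
      aa <- ifelse(swap, b, a); bb <- ifelse(swap, a, b)
      compare_correlations(cor(shared, aa), cor(shared, bb), n,
                           mode = "dependent", r_between = cor(aa, bb))$z
    }, numeric(1))
  })
  p_perm <- mean(abs(zs) >= abs(obs$z))
  expect_lt(abs(p_perm - obs$p), 0.12)             # Monte-Carlo tolerance
  # the null z distribution is approximately standard normal
  expect_lt(abs(sd(zs) - 1), 0.25)
})

test_that("feature correlation wraps outlier removal and records what it removed", {
  withr::with_seed(44, {
    x <- rnorm(35); y <- 0.7 * x + rnorm(35, 0, 0.6)
  })
  x[35] <- 9; y[35] <- -9
  res <- correlate_features(x, y, seed = 6)
  expect_true(35L %in% res$removed_ids)
  expect_equal(res$n_used, 35 - length(res$removed_ids))
  expect_gt(res$r, 0.5)
  expect_gt(res$bf10, 3)
})
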