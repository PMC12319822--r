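#' Gauss hypergeometric function 2F1 by direct series
#'
#' Power-series evaluation, adequate for `0 <= z < 1` with `c - a - b > 0`
#' (the regime used by the correlation likelihood, where `a = b = 1/2` and
#' `c = n - 1/2`).
#'
#' @param a,b,c Parameters.
#' @param z Argument in `[0, 1)`.
#' @param tol Relative truncation tolerance.
#' @param max_terms Series length cap.
#' @return The series value.
#' @export
hyp2f1 <- function(a, b, c, z, tol = 1e-14, max_terms = 100000L) {
  assert_that(z >= 0 && z < 1, "series evaluation needs 0 <= z < 1")
  term <- 1; total <- 1
  for (k in seq_len(max_terms)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((c + k - 1) * k) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  warning("2F1 series did not converge to tolerance; returning partial sum")
  total
}

#' Likelihood ratio of a sample correlation under rho vs rho = 0
#'
#' Ratio of the sampling density of the Pearson correlation `r` (n pairs
#' drawn from a bivariate normal with population correlation `rho`) to its
#' density under `rho = 0`; terms free of `rho` cancel:
#' `(1 - rho^2)^((n-1)/2) * (1 - rho*r)^(3/2 - n) *
#'  2F1(1/2, 1/2; n - 1/2; (1 + rho*r)/2) / 2F1(1/2, 1/2; n - 1/2; 1/2)`.
#'
#' @param rho Population correlation(s) in (-1, 1).
#' @param r Observed sample correlation.
#' @param n Number of pairs.
#' @return Likelihood ratio, vectorised over `rho`.
#' @export
corr_likelihood_ratio <- function(rho, r, n) {
  denom <- hyp2f1(0.5, 0.5, n - 0.5, 0.5)
  vapply(rho, function(p) {
    z <- (1 + p * r) / 2
    (1 - p^2)^((n - 1) / 2) * (1 - p * r)^(1.5 - n) *
      hyp2f1(0.5, 0.5, n - 0.5, min(z, 1 - 1e-12)) / denom
  }, numeric(1))
}

#' Stretched-beta prior density on a correlation
#'
#' The default prior of Bayesian correlation tests: `(rho + 1)/2` follows a
#' `Beta(1/kappa, 1/kappa)` distribution, so `kappa = 1` is uniform on
#' (-1, 1).
#'
#' @param rho Correlation value(s).
#' @param kappa Prior width (default 1).
#' @return Density value(s).
#' @export
stretched_beta <- function(rho, kappa = 1) {
  dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
}

#' Default-prior Bayes factor for a Pearson correlation
#'
#' Computes the sample Pearson correlation and the two-sided Bayes factor
#' BF10 for a nonzero population correlation, integrating the correlation
#' likelihood ratio over the stretched-beta prior of width `kappa`
#' (numerical quadrature over (-1, 1)). The evidence category follows
#' [classify_bf()].
#'
#' @param x,y Paired numeric vectors (n >= 4 after any outlier removal).
#' @param kappa Prior width (default 1, the common software default).
#' @param removed_ids Optional indices already removed as outliers, recorded
#'   in the result for provenance.
#' @return A `correlation_result` list: `r`, `n_used`, `bf10`, `category`,
#'   `kappa`, `removed_ids`.
#' @export
pearson_bf10 <- function(x, y, kappa = 1, removed_ids = integer(0)) {
  assert_that(length(x) == length(y), "x and y must be the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 4, "need at least 4 complete pairs (got %d)", n)
  assert_that(sd(x) > 0 && sd(y) > 0, "x and y must both vary")
  r <- cor(x, y)
  bf10 <- bf10_from_r(r, n, kappa)
  structure(list(r = r, n_used = n, bf10 = bf10,
                 category = classify_bf(bf10), kappa = kappa,
                 removed_ids = removed_ids),
            class = "correlation_result")
}

#' Bayes factor from a precomputed correlation and sample size
#'
#' @param r Sample Pearson correlation with `|r| < 1` (a degenerate `|r| = 1`
#'   returns `Inf`).
#' @param n Number of pairs.
#' @param kappa Prior width.
#' @return BF10 (H1: rho != 0 vs H0: rho = 0).
#' @export
bf10_from_r <- function(r, n, kappa = 1) {
  if (abs(r) >= 1) return(Inf)
  stats::integrate(function(p) corr_likelihood_ratio(p, r, n) *
                     stretched_beta(p, kappa),
                   -1, 1, rel.tol = 1e-9, subdivisions = 500L)$value
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f (n = %d), BF10 = %.3g: %s\n",
              x$r, x$n_used, x$bf10, x$category))
  if (length(x$removed_ids) > 0)
    cat("  removed outliers:", paste(x$removed_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a Bayes factor on the standard evidence scale
#'
#' BF10 of 1-3 is anecdotal, 3-10 moderate, 10-30 strong, 30-100 very
#' strong and > 100 extreme evidence for H1; the reciprocal bands support
#' H0. Boundary values are assigned to the stronger category, and BF10 = 1
#' is "no evidence".
#'
#' @param bf10 Bayes factor (> 0).
#' @return Character label, e.g. `"strong evidence for H1"`.
#' @export
classify_bf <- function(bf10) {
  assert_that(is.finite(bf10) || bf10 == Inf, "bf10 must be a positive number")
  assert_that(bf10 > 0, "bf10 must be positive")
  if (bf10 == 1) return("anecdotal evidence (no direction)")
  b <- if (bf10 > 1) bf10 else 1 / bf10
  strength <- if (b >= 100) "extreme" else if (b >= 30) "very strong" else
    if (b >= 10) "strong" else if (b >= 3) "moderate" else "anecdotal"
  sprintf("%s evidence for %s", strength, if (bf10 > 1) "H1" else "H0")
}

#' Bivariate outlier detection by bootstrapped Mahalanobis distance
#'
#' For each point, the squared Mahalanobis distance is averaged over
#' bootstrap resamples that do not contain the point itself (leave-one-
#' available resamples), so an extreme point cannot mask itself by inflating
#' the covariance. Points whose average distance exceeds the out-of-sample
#' reference quantile are flagged; because centre and covariance are
#' estimated, that reference is the scaled F distribution
#' `2 (n-1)/(n-2) * (n+1)/n * F(2, n-2)` rather than the chi-squared
#' approximation (which over-flags at these sample sizes).
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param quantile Flagging quantile (default 0.975).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return Integer vector of flagged indices (possibly empty).
#' @export
mahalanobis_bootstrap_outliers <- function(x, y, n_boot = 1000, quantile = 0.975,
                                           seed = 1L) {
  assert_that(length(x) == length(y), "x and y must be the same length")
  ok <- is.finite(x) & is.finite(y)
  assert_that(all(ok), "x and y must be finite")
  n <- length(x)
  assert_that(n >= 5, "need at least 5 pairs (got %d)", n)
  X <- cbind(x, y)
  assert_that(abs(cor(x, y)) < 1 - 1e-12 && sd(x) > 0 && sd(y) > 0,
              "degenerate (collinear or constant) data: covariance is singular")
  d2_sum <- numeric(n); d2_cnt <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      S <- cov(Xb)
      if (!is.finite(determinant(S)$modulus) || det(S) < 1e-12 * prod(diag(S)))
        next
      mu <- colMeans(Xb)
      d2 <- stats::mahalanobis(X, mu, S)
      out_of_bag <- !(seq_len(n) %in% idx)
      d2_sum[out_of_bag] <- d2_sum[out_of_bag] + d2[out_of_bag]
      d2_cnt[out_of_bag] <- d2_cnt[out_of_bag] + 1
    }
  })
  assert_that(all(d2_cnt > 0), "too few bootstrap resamples; increase n_boot")
  thr <- 2 * (n - 1) / (n - 2) * (n + 1) / n * stats::qf(quantile, 2, n - 2)
  which(d2_sum / d2_cnt > thr)
}

#' Fisher z-test comparing two correlations
#'
#' Both coefficients are Fisher z-transformed. In `"independent"` mode the
#' difference is scaled by `sqrt(1/(n1 - 3) + 1/(n2 - 3))`. In
#' `"dependent"` mode (default) the correlations share one variable within
#' the same sample of `n` subjects and the statistic follows Steiger's
#' modified z, which needs `r_between`, the correlation between the two
#' non-shared variables.
#'
#' @param r1,r2 Correlation coefficients with absolute value < 1.
#' @param n Sample size of `r1` (shared sample size in dependent mode).
#' @param n2 Sample size of `r2` (independent mode only; defaults to `n`).
#' @param mode `"dependent"` or `"independent"`.
#' @param r_between Correlation between the two non-shared variables
#'   (dependent mode only).
#' @return A `correlation_comparison` list: `r1`, `r2`, `z`, `p` (two-
#'   tailed), `mode`, `n`.
#' @export
compare_correlations <- function(r1, r2, n, n2 = n,
                                 mode = c("dependent", "independent"),
                                 r_between = NULL) {
  mode <- match.arg(mode)
  assert_that(abs(r1) < 1 && abs(r2) < 1,
              "correlations of magnitude 1 cannot be compared")
  assert_that(n >= 4 && n2 >= 4, "need at least 4 subjects")
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (mode == "independent") {
    z <- (z1 - z2) / sqrt(1 / (n - 3) + 1 / (n2 - 3))
  } else {
    assert_that(!is.null(r_between),
                "dependent mode needs `r_between`, the correlation between the two non-shared variables")
    rb <- (r1 + r2) / 2
    cov_term <- (r_between * (1 - 2 * rb^2) -
                   0.5 * rb^2 * (1 - 2 * rb^2 - r_between^2)) / (1 - rb^2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  }
  structure(list(r1 = r1, r2 = r2, z = z, p = 2 * pnorm(-abs(z)),
                 mode = mode, n = c(n, n2)),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> r1 = %.3f vs r2 = %.3f (%s): z = %.3f, p = %.4f\n",
              x$r1, x$r2, x$mode, x$z, x$p))
  invisible(x)
}

#' Correlate two subject-level features with outlier removal and BF10
#'
#' Convenience wrapper chaining [mahalanobis_bootstrap_outliers()] and
#' [pearson_bf10()].
#'
#' @inheritParams pearson_bf10
#' @inheritParams mahalanobis_bootstrap_outliers
#' @param remove_outliers Apply the bootstrap Mahalanobis rule first
#'   (default `TRUE`).
#' @return A `correlation_result` with the removed indices recorded.
#' @export
correlate_features <- function(x, y, kappa = 1, remove_outliers = TRUE,
                               n_boot = 1000, quantile = 0.975, seed = 1L) {
  removed <- integer(0)
  if (remove_outliers) {
    removed <- mahalanobis_bootstrap_outliers(x, y, n_boot = n_boot,
                                              quantile = quantile, seed = seed)
    if (length(removed) > 0) {
      x <- x[-removed]; y <- y[-removed]
    }
  }
  pearson_bf10(x, y, kappa = kappa, removed_ids = removed)
}
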