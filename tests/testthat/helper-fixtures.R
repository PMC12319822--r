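# Shared fixtures: small, fast simulation configurations used across tests.
# All fixtures are generated in code at test time; nothing is read from disk.

small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, sampling_rate = 250,
         n_channels = c(MAG = 4L, GRAD = 4L),
         grid_dims = c(2L, 2L, 2L), snr = 5),
    list(...))
  do.call(sim_config, args)
}

# sine-wave recording helper: one channel group plus EMG, no events
tone_recording <- function(freq, fs = 500, dur = 10, amp = 1, n_ch = 2) {
  t <- (seq_len(fs * dur) - 1) / fs
  dat <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch), nrow = n_ch,
                byrow = TRUE)
  recording(dat, rep("EEG", n_ch), fs)
}

# independent sequential-ESD oracle: recompute every step from scratch with
# plain vector arithmetic, evaluating all k <= k_max prefixes
gesd_oracle <- function(values, alpha = 0.05, max_fraction = 0.2) {
  n <- length(values)
  k_max <- max(1L, floor(max_fraction * n))
  idx <- seq_len(n)
  x <- values
  order_removed <- integer(0)
  stats_R <- numeric(0)
  crit <- numeric(0)
  for (i in seq_len(k_max)) {
    if (sd(x) == 0 || !is.finite(sd(x))) break
    d <- abs(x - mean(x))
    worst <- which(d == max(d))[1]
    stats_R[i] <- d[worst] / sd(x)
    ni <- n - i + 1
    p <- 1 - alpha / (2 * ni)
    tv <- qt(p, ni - 2)
    crit[i] <- (ni - 1) * tv / sqrt((ni - 2 + tv^2) * ni)
    order_removed[i] <- idx[worst]
    idx <- idx[-worst]
    x <- x[-worst]
  }
  pass <- which(stats_R > crit)
  if (length(pass) == 0) integer(0) else sort(order_removed[seq_len(max(pass))])
}

# independent Bayes-factor oracle: trapezoid quadrature of the full sampling
# density of r over the stretched-beta prior, with 2F1 evaluated through its
# Euler integral representation instead of the package's power series
bf10_oracle <- function(r, n, kappa = 1, n_grid = 4001) {
  hyp_euler <- function(c_par, z) {
    # 2F1(1/2, 1/2; c; z) * Beta(1/2, c - 1/2) via the Euler integral
    f <- function(u) u^(-0.5) * (1 - u)^(c_par - 1.5) * (1 - z * u)^(-0.5)
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  c_par <- n - 0.5
  dens <- function(rho) {
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(1.5 - n) *
      hyp_euler(c_par, (1 + rho * r) / 2)
  }
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_grid)
  prior <- dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
  num <- vapply(rho, dens, numeric(1)) * prior
  h <- rho[2] - rho[1]
  integral <- h * (sum(num) - (num[1] + num[length(num)]) / 2)
  integral / dens(0)
}
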