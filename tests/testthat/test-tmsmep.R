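test_that("peak-to-peak amplitude is max minus min inside the window", {
  fs <- 5000
  t <- (0:499) / fs
  # 250 Hz tone: 20 samples per cycle, so the peaks are sampled exactly
  expect_equal(peak_to_peak(0.5 * sin(2 * pi * 250 * t), fs, c(0, 0.1)), 1.0)
  expect_equal(peak_to_peak(rep(0.3, 500), fs, c(0, 0.1)), 0)
  expect_error(peak_to_peak(rep(0, 500), fs, c(0.2, 0.3)), "empty")

  # programmed biphasic MEP recovered within noise tolerance
  tr <- simulate_mep_trace(1.3, noise_sd = 0.01, seed = 2)
  expect_lt(abs(peak_to_peak(tr$trace, tr$fs, tr$response_window) - 1.3), 0.05)
})

test_that("Grubbs single iteration matches the t-distribution critical value", {
  x <- c(rep(1, 9), 3)
  # independent critical-value computation
  n <- 10
  tcrit <- qt(1 - 0.05 / (2 * n), n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  G <- max(abs(x - mean(x))) / sd(x)
  expect_gt(G, gcrit)                               # oracle says: reject
  expect_equal(grubbs_once(x), 10L)

  # borderline case below the critical value: nothing rejected
  y <- c(1.0, 1.1, 0.9, 1.05, 0.95, 1.2)
  Gy <- max(abs(y - mean(y))) / sd(y)
  ny <- length(y)
  ty <- qt(1 - 0.05 / (2 * ny), ny - 2)
  gy <- (ny - 1) / sqrt(ny) * sqrt(ty^2 / (ny - 2 + ty^2))
  expect_lt(Gy, gy)
  expect_length(grubbs_once(y), 0)
  expect_length(grubbs_once(rep(2, 5)), 0)
})

test_that("rejection rules fire in their documented order", {
  base <- data.frame(protocol = "spMEP", block = rep(1:2, each = 5),
                     trial = 1:10, p2p_mv = 1,
                     prepulse_mv = 0.02, conditioned = FALSE)
  withr::with_seed(3, base$p2p_mv <- rlnorm(10, 0, 0.05))

  r1 <- base; r1$p2p_mv[4] <- 0.05
  out1 <- reject_mep_trials(r1)
  expect_true(out1$rejected[4])
  expect_match(out1$reason[4], "no reliable MEP")

  r2 <- base; r2$prepulse_mv[7] <- 0.15
  out2 <- reject_mep_trials(r2)
  expect_true(out2$rejected[7])
  expect_match(out2$reason[7], "precontraction")

  # rule 1 keeps small *conditioned* responses (genuine inhibition)
  rc <- base; rc$protocol <- "SICI2.5ms"; rc$conditioned <- TRUE
  rc$p2p_mv <- rc$p2p_mv * 0.06
  outc <- reject_mep_trials(rc)
  expect_false(any(grepl("no reliable MEP", outc$reason)))

  # Grubbs catches a single extreme survivor per protocol
  r4 <- data.frame(protocol = "spMEP", block = 1, trial = 1:10,
                   p2p_mv = c(rep(1, 9) + seq(-0.04, 0.04, by = 0.01), 3),
                   prepulse_mv = 0.02, conditioned = FALSE)
  out4 <- reject_mep_trials(r4, sd_mult = 10)       # disable rule 3
  expect_true(out4$rejected[10])
  expect_match(out4$reason[10], "Grubbs")
  expect_equal(sum(out4$rejected), 1)

  # rule 3: amplitudes outside mean +/- 2 SD per condition x block; the SD
  # includes the candidate, so the planted value must be far out
  r3 <- base; r3$block <- 1
  r3$p2p_mv[2] <- mean(base$p2p_mv) + 12 * sd(base$p2p_mv)
  stopifnot(abs(r3$p2p_mv[2] - mean(r3$p2p_mv)) > 2 * sd(r3$p2p_mv))
  out3 <- reject_mep_trials(r3, alpha = 1e-9)       # mute Grubbs
  expect_true(out3$rejected[2])
  expect_match(out3$reason[2], "2 SD")

  expect_error(reject_mep_trials(base[1:2, ]), "fewer than 3")
})

test_that("rejection stays mild on generator defaults", {
  cfg <- small_config(seed = 61)
  worst <- 0
  for (s in 1:10) {
    tt <- do.call(rbind, lapply(c("spMEP_early", "SICI_early"), function(p)
      simulate_mep_trials(cfg, p, 15L, s * 7)))
    rej <- reject_mep_trials(tt)
    per_cond <- tapply(rej$rejected, rej$protocol, sum)
    worst <- max(worst, max(per_cond))
  }
  expect_lt(worst, 5)
})

test_that("SICI is the ratio of conditioned to unconditioned means", {
  tt <- data.frame(protocol = rep(c("SICI_early", "spMEP_early"), each = 3),
                   block = 1, trial = 1:6,
                   p2p_mv = c(0.5, 0.5, 0.5, 1, 1, 1),
                   prepulse_mv = 0, conditioned = rep(c(TRUE, FALSE), each = 3))
  s <- sici(tt, "SICI_early", "spMEP_early")
  expect_equal(s$ratio, 0.5)
  expect_equal(unname(s$n_used), c(3L, 3L))

  # same label on both sides gives exactly 1
  expect_equal(sici(tt, "spMEP_early", "spMEP_early")$ratio, 1)

  # unit invariance: mV vs uV applied consistently
  tt_uv <- tt; tt_uv$p2p_mv <- tt$p2p_mv * 1000
  expect_equal(sici(tt_uv, "SICI_early", "spMEP_early")$ratio, s$ratio)

  expect_error(sici(tt[tt$protocol == "spMEP_early", ], "SICI_early", "spMEP_early"),
               "no retained conditioned")
})

test_that("the estimated SICI ratio recovers the generator truth", {
  cfg <- small_config(seed = 62)
  cfg$mep_model$sici_ratio <- 0.4
  est <- vapply(1:10, function(s) {
    tt <- rbind(simulate_mep_trials(cfg, "spMEP_early", 15L, 100 + s),
                simulate_mep_trials(cfg, "SICI_early", 15L, 200 + s))
    sici(reject_mep_trials(tt), "SICI_early", "spMEP_early")$ratio
  }, numeric(1))
  expect_true(all(abs(est - 0.4 * exp(cfg$mep_model$log_sd^2 / 2) /
                        exp(cfg$mep_model$log_sd^2 / 2)) < 0.15))
  expect_lt(abs(mean(est) - 0.4), 0.05)
})
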