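test_that("trial schedules reproduce the task designs", {
  s1 <- make_trial_schedule("MA1", 1)
  expect_equal(length(unique(s1$trial)), 70)
  expect_equal(sum(s1$label == "nogo"), 14)          # 20% of 70
  expect_equal(sum(s1$label %in% c("go", "nogo")), 70)
  # cue-stimulus interval: 200 ms cue + 1 s fixation
  cue <- s1$time_s[s1$label == "cue"]
  stim <- s1$time_s[s1$label %in% c("go", "nogo")]
  expect_equal(stim - cue, rep(1.2, 70))
  # inter-trial interval uniform 2-4 s after the 200 ms stimulus
  gaps <- cue[-1] - stim[-70] - 0.2
  expect_true(all(gaps >= 2 & gaps <= 4))

  s3 <- make_trial_schedule("MA1-exp3", 2)
  expect_equal(sum(s3$label == "go"), 140)
  expect_equal(sum(s3$label == "nogo"), 0)
  cue3 <- s3$time_s[s3$label == "cue"]
  stim3 <- s3$time_s[s3$label == "go"]
  gaps3 <- round(cue3[-1] - stim3[-140] - 0.2, 6)
  expect_true(all(gaps3 %in% c(2.7, 3.2, 3.7, 4.2, 4.7)))

  s2 <- make_trial_schedule("MA2", 3)
  expect_equal(nrow(s2), 4 * 8 * 8)                  # 32-flash cycle x 8
  expect_equal(diff(s2$time_s), rep(1, 255))         # 1 Hz pacing
  expect_equal(as.vector(table(s2$digit)), rep(64L, 4))

  expect_error(make_trial_schedule("bogus", 1), "unknown task_id")
})

test_that("simulated recordings are deterministic and carry the promised structure", {
  cfg <- small_config(seed = 3)
  sch <- make_trial_schedule("MA1", 4)
  sch <- sch[sch$trial <= 6, ]
  tru <- make_ground_truth(cfg, sch, 5)
  r1 <- simulate_recording(cfg, sch, tru, 6)
  r2 <- simulate_recording(cfg, sch, tru, 6)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)

  # EMG burst RMS well above pre-cue baseline
  emg <- r1$data[which(r1$channel_groups == "EMG"), ]
  fs <- r1$sampling_rate
  tr <- tru$trials[1, ]
  burst <- emg[round(tr$onset_s * fs):round(tr$offset_s * fs)]
  base <- emg[round((tr$go_time_s - 0.6) * fs):round((tr$go_time_s - 0.2) * fs)]
  expect_gt(sqrt(mean(burst^2)), 5 * sqrt(mean(base^2)))
})

test_that("injected slow-gamma activity shows up at its true frequency in the sensor spectrum", {
  cfg <- small_config(seed = 8, snr = 50, source_background_rms = 0, line_rel = 0)
  cfg$band_truth$slow_gamma$freq <- 43
  sch <- make_trial_schedule("MA1", 9)
  sch <- sch[sch$trial <= 8, ]
  tru <- make_ground_truth(cfg, sch, 10)
  rec <- simulate_recording(cfg, sch, tru, 11)
  fs <- rec$sampling_rate
  # pool movement windows and inspect the magnitude spectrum in 30-60 Hz
  seg <- lapply(seq_len(nrow(tru$trials)), function(i) {
    idx <- round(tru$trials$onset_s[i] * fs):round(tru$trials$offset_s[i] * fs)
    rec$data[1, idx]
  })
  x <- unlist(seg)
  n <- stats::nextn(length(x))
  spec <- Mod(fft(c(x, numeric(n - length(x)))))[seq_len(n / 2)]
  freqs <- (seq_len(n / 2) - 1) * fs / n
  inband <- freqs >= 30 & freqs <= 60
  fpeak <- freqs[inband][which.max(spec[inband])]
  expect_lt(abs(fpeak - 43), 1)
})

test_that("population traits hit the target correlation and reject degenerate sizes", {
  cfg0 <- small_config(seed = 21, n_subjects = 50L, trait_corr = 0)
  pop0 <- simulate_population(cfg0)
  expect_lt(abs(pop0$empirical_r), 0.3)

  cfg7 <- small_config(seed = 22, n_subjects = 200L, trait_corr = 0.7)
  pop7 <- simulate_population(cfg7)
  expect_gt(pop7$empirical_r, 0.6)
  expect_lt(pop7$empirical_r, 0.8)
  expect_true(all(pop7$table$slow_gamma_freq >= 35 & pop7$table$slow_gamma_freq <= 57))
  expect_true(all(pop7$table$sici_ratio > 0 & pop7$table$sici_ratio < 1.5))

  cfg2 <- small_config(seed = 23)
  cfg2$n_subjects <- 2L
  expect_error(simulate_population(cfg2), "n_subjects >= 5")
})

test_that("population latent correlation is unbiased across replicates", {
  rs <- vapply(1:100, function(s) {
    cfg <- small_config(seed = 3000 + s, n_subjects = 50L, trait_corr = 0.65)
    simulate_population(cfg)$empirical_r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.65), 0.05)
})

test_that("MEP trial simulation follows the protocol designs", {
  cfg <- small_config(seed = 31)
  t15 <- simulate_mep_trials(cfg, "spMEP_early", 15L, 1)
  expect_equal(nrow(t15), 15)
  t13 <- simulate_mep_trials(cfg, "SICI2.5ms", 13L, 2)
  expect_equal(nrow(t13), 13)
  expect_true(all(t13$conditioned))
  expect_error(simulate_mep_trials(cfg, "nope", 15L, 1), "unknown protocol")
  expect_error(simulate_mep_trials(cfg, "spMEP", 0L, 1), "at least 1")

  # zero contamination: nothing for the precontraction rule to reject
  cfg$mep_model$precontraction_prob <- 0
  cfg$mep_model$subthreshold_prob <- 0
  tt <- do.call(rbind, lapply(c("spMEP", "SICI2.5ms"), function(p)
    simulate_mep_trials(cfg, p, 15L, 3)))
  rej <- reject_mep_trials(tt)
  expect_false(any(grepl("precontraction", rej$reason)))
})

test_that("sequence-learning sessions respect the block design", {
  expect_equal(sort(as.vector(table(ml1_sequence()))), c(2L, 2L, 3L, 3L))
  cfg <- small_config(seed = 41)
  s <- simulate_ml1(cfg, 7)
  expect_equal(nrow(s), 15 * 30)
  expect_equal(unique(s$block_type[s$block %in% c(1, 15)]), "random")
  expect_equal(unique(s$block_type[s$block %in% 2:14]), "sequence")
  expect_equal(sum(s$block == 1), 30)
  for (b in 2:14) {
    expect_equal(as.vector(table(s$cue[s$block == b])), c(9L, 9L, 6L, 6L))
  }
  # zero learning rate: flat curve, score near zero
  cfg$learning_model$ml1$asymptote_ms <- cfg$learning_model$ml1$initial_ms
  sc <- ml1_score(simulate_ml1(cfg, 8))
  expect_lt(abs(sc$value), 3)
})

test_that("tracing-task sessions decay monotonically in expectation", {
  cfg <- small_config(seed = 51)
  det <- ml2_expected_series(cfg$learning_model$ml2)
  expect_true(all(diff(det$mt_s) < 0))
  expect_true(all(diff(det$error_deg) < 0))
  s <- simulate_ml2(cfg, 9)
  expect_equal(nrow(s), cfg$learning_model$ml2$n_trials)
  expect_true(all(s$mt_s > 0) && all(s$error_deg >= 0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(sampling_rate = 150), "twice the highest band edge")
  expect_error(sim_config(snr = 0), "snr")
  expect_error(sim_config(trait_corr = 1.2), "trait_corr")
  bt <- sim_config()$band_truth
  bt$slow_gamma$freq <- 75
  expect_error(sim_config(band_truth = bt), "outside its band")
})
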