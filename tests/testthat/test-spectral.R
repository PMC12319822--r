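toy_epochs <- function(make_trial, n_tr = 3, n_loc = 1, fs = 250,
                       window = c(-2, 2)) {
  n_s <- round((window[2] - window[1]) * fs)
  tms <- (seq_len(n_s) - 1) / fs + window[1]
  ep <- array(0, c(n_tr, n_loc, n_s))
  for (tr in seq_len(n_tr)) for (l in seq_len(n_loc)) {
    ep[tr, l, ] <- make_trial(tms, tr, l)
  }
  attr(ep, "times") <- tms
  ep
}

test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  h <- dpss_tapers(400, 4, 7)
  expect_equal(dim(h), c(400, 7))
  expect_equal(crossprod(h), diag(7), tolerance = 1e-8)
  # leading taper concentrates its energy inside the design band
  H <- Mod(fft(c(h[, 1], numeric(3600))))^2
  w <- 4 / 400
  inband <- ((seq_len(4000) - 1) / 4000) <= w | ((seq_len(4000) - 1) / 4000) >= 1 - w
  expect_gt(sum(H[inband]) / sum(H), 0.999)
  expect_error(dpss_tapers(400, 0.4, 0), "at least one taper")
})

test_that("a pure tone peaks at its own frequency in every time bin", {
  ep <- toy_epochs(function(tms, tr, l) sin(2 * pi * 40 * tms))
  tf <- multitaper_tf(ep, 250, freq_range = c(30, 60))
  expect_equal(tf$freqs, 30:60)
  peak_by_time <- apply(tf$power[1, , , 1], 2, which.max)
  expect_true(all(tf$freqs[peak_by_time] == 40))
  # time stamps are window centres on the 200 ms grid
  expect_equal(diff(tf$times), rep(0.2, length(tf$times) - 1))
})

test_that("a confined burst is localised in time to within the taper window", {
  ep <- toy_epochs(function(tms, tr, l)
    sin(2 * pi * 40 * tms) * (tms >= 0 & tms <= 0.5) + 1e-6 * sin(2 * pi * 35 * tms))
  tf <- multitaper_tf(ep, 250, freq_range = c(30, 60))
  p40 <- tf$power[1, tf$freqs == 40, , 1]
  tmax <- tf$times[which.max(p40)]
  expect_gte(tmax, 0 - 0.8)
  expect_lte(tmax, 0.5 + 0.8)
  # power well away from the burst is far below the burst peak
  far <- abs(tf$times - 0.25) > 1.2
  expect_lt(max(p40[far]) / max(p40), 0.05)
})

test_that("white noise gives a flat band spectrum within 3 dB", {
  ep <- toy_epochs(function(tms, tr, l) rnorm(length(tms)), n_tr = 30)
  withr::with_seed(21, {
    ep[] <- rnorm(length(ep))
  })
  tf <- multitaper_tf(ep, 250, freq_range = c(20, 90))
  spec <- apply(tf$power[, , , 1], 2, mean)          # average trials x times
  expect_lt(10 * log10(max(spec) / min(spec)), 3)
})

test_that("baseline correction yields zero-mean relative power over the baseline", {
  ep <- toy_epochs(function(tms, tr, l) sin(2 * pi * 25 * tms), n_tr = 12)
  withr::with_seed(31, ep[] <- ep[] + 0.1 * rnorm(length(ep)))
  tf <- multitaper_tf(ep, 250, freq_range = c(13, 30))
  rel <- baseline_correct(tf, c(-1, -0.5))
  expect_true(rel$relative)
  bsel <- rel$times >= -1 & rel$times <= -0.5
  bmean <- apply(rel$power[, , bsel, , drop = FALSE], 2, mean)
  expect_true(all(abs(bmean) < 1e-10))
  # stationary signal: trial-averaged corrected power near zero everywhere
  # (bound ~ 4 sd of the 3-taper, 12-trial relative-power estimator)
  avg <- apply(rel$power, c(2, 3), mean)
  expect_lt(max(abs(avg)), 0.7)
  expect_error(baseline_correct(rel), "already")
})

test_that("power doubling against baseline gives a relative change of one", {
  tf <- structure(list(
    power = array(1, c(2, 3, 5, 1)), freqs = 30:32,
    times = seq(-1.2, -0.4, by = 0.2), fs = 250, relative = FALSE),
    class = "tf_power")
  tf$power[, , 4:5, ] <- 2                           # doubling after baseline
  rel <- baseline_correct(tf, c(-1.2, -0.8))
  expect_equal(rel$power[1, 1, 4, 1], 1)
  expect_equal(rel$power[2, 3, 1, 1], 0)
})

test_that("band peaks report the extremum with deterministic tie-breaking", {
  base <- structure(list(
    power = array(0, c(2, 5, 4, 3)), freqs = 38:42,
    times = c(0, 0.2, 0.4, 0.6), fs = 250, relative = TRUE),
    class = "tf_power")
  win <- data.frame(from = c(0, 0), to = c(0.6, 0.6))

  tf <- base
  tf$power[, 3, , 2] <- 2                            # 40 Hz, location 2
  pk <- extract_band_peak(tf, win, c(38, 42), "max")
  expect_equal(pk$peak_frequency, 40)
  expect_equal(pk$peak_location, 2)
  expect_equal(pk$power, 2)

  # two equal maxima: lowest frequency wins, then lowest location
  tf2 <- base
  tf2$power[, 2, , 3] <- 5                           # 39 Hz loc 3
  tf2$power[, 4, , 1] <- 5                           # 41 Hz loc 1
  pk2 <- extract_band_peak(tf2, win, c(38, 42), "max")
  expect_equal(pk2$peak_frequency, 39)
  expect_equal(pk2$peak_location, 3)

  # mode = min finds a suppressed bin in uniform power
  tf3 <- base
  tf3$power[] <- 1
  tf3$power[, 4, , 2] <- -0.5
  pk3 <- extract_band_peak(tf3, win, c(38, 42), "min")
  expect_equal(pk3$peak_frequency, 41)
  expect_equal(pk3$peak_location, 2)

  # region of interest masks locations out of the search
  pk_roi <- extract_band_peak(tf2, win, c(38, 42), "max", roi = c(1, 2))
  expect_equal(pk_roi$peak_location, 1)
  expect_error(extract_band_peak(tf2, win, c(38, 42), "max", roi = integer(0)),
               "empty")
})

test_that("peak extraction is invariant to trial order", {
  withr::with_seed(41, {
    tf <- structure(list(
      power = array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3)), freqs = 38:42,
      times = c(0, 0.2, 0.4, 0.6), fs = 250, relative = TRUE),
      class = "tf_power")
  })
  win <- data.frame(from = rep(0, 6), to = seq(0.2, 0.7, by = 0.1))
  pk <- extract_band_peak(tf, win, c(38, 42), "max")
  perm <- c(4, 1, 6, 2, 5, 3)
  tfp <- tf
  tfp$power <- tf$power[perm, , , , drop = FALSE]
  pkp <- extract_band_peak(tfp, win[perm, ], c(38, 42), "max")
  expect_equal(pkp$peak_frequency, pk$peak_frequency)
  expect_equal(pkp$peak_location, pk$peak_location)
  expect_equal(pkp$power, pk$power)
})

test_that("power maps agree with the band peak and flatten uniform data", {
  withr::with_seed(51, {
    tf <- structure(list(
      power = array(rnorm(4 * 5 * 4 * 6), c(4, 5, 4, 6)), freqs = 38:42,
      times = c(0, 0.2, 0.4, 0.6), fs = 250, relative = TRUE),
      class = "tf_power")
  })
  win <- data.frame(from = rep(0, 4), to = rep(0.6, 4))
  pk <- extract_band_peak(tf, win, c(38, 42), "max")
  pm <- power_map(tf, win, pk$peak_frequency)
  expect_length(pm, 6)
  expect_equal(which.max(pm), pk$peak_location)

  tfu <- tf
  tfu$power[] <- 3
  expect_equal(power_map(tfu, win, 40), rep(3, 6))
  expect_error(power_map(tf, win, 55.5), "not on the grid")
})

test_that("peak frequencies are recovered to the 1 Hz grid across subjects", {
  errs <- vapply(1:8, function(s) {
    f0 <- 35 + (s - 1) * 3                           # spread over 35-56 Hz
    cfg <- small_config(seed = 800 + s)
    cfg$band_truth$slow_gamma$freq <- f0
    res <- run_subject_features(cfg, experiment_template("experiment1"),
                                seed = 900 + s, bands = "slow_gamma",
                                rank = 8, max_trials = 25)
    abs(res$features$peak_freq_hz - f0)
  }, numeric(1))
  expect_lte(stats::median(errs), 1)
})
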