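#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode the
#' task designs the analysis chain targets: a cued Go/NoGo reaction task
#' ("MA1", 70 trials with 20\% NoGo), its Go-only variant ("MA1-exp3",
#' 140 Go trials), and a continuous 1 Hz paced button-press task ("MA2").
#'
#' @param seed Base RNG seed; all per-subject and per-stage seeds derive from
#'   it deterministically.
#' @param n_subjects Number of subjects for population-level simulation.
#' @param sampling_rate Acquisition rate in Hz; must exceed twice the highest
#'   analysis band edge (90 Hz).
#' @param n_channels Named integer vector of sensor counts per channel group
#'   (an EMG channel is always added).
#' @param grid_dims 3-D source grid dimensions.
#' @param grid_spacing Grid spacing in mm (default 8).
#' @param band_truth Named list per band with elements `freq` (true peak
#'   frequency, Hz, inside the band), `amplitude` (source amplitude),
#'   `tonic` (fraction of amplitude present outside the response window),
#'   plus for beta `erd_depth` (fractional amplitude drop during movement)
#'   and `ers_gain` (fractional amplitude rise in the first second after
#'   movement offset).
#' @param snr Ratio of clean-sensor RMS to additive noise RMS (> 0).
#' @param source_background_rms RMS of ongoing pink background activity per
#'   source (same units as the band amplitudes). This emulates the broadband
#'   brain activity that dominates real sensor variance, so task responses
#'   modulate only a modest fraction of it.
#' @param noise_pink_fraction Fraction of noise variance carried by 1/f
#'   ("pink") noise; the rest is white.
#' @param line_hz,line_rel Mains frequency (Hz) and line amplitude relative
#'   to the noise RMS.
#' @param task_id One of `"MA1"`, `"MA1-exp3"`, `"MA2"`.
#' @param rt_mean_s,rt_sd_s,mt_mean_s,mt_sd_s True reaction/movement time
#'   distribution (s) used for ground-truth movement onsets and offsets.
#' @param emg_burst_gain EMG burst RMS as a multiple of EMG baseline RMS
#'   (default 10).
#' @param trial_amp_sd Log-SD of per-trial amplitude jitter of the injected
#'   band responses (within-subject trial-to-trial variability; exposed as a
#'   free parameter).
#' @param mep_model List: `base_mv` (unconditioned median MEP, mV),
#'   `sici_ratio` (true conditioned/unconditioned ratio), `log_sd`,
#'   `precontraction_prob`, `subthreshold_prob`, `block_size`.
#' @param learning_model List with `ml1` (fields `initial_ms`, `asymptote_ms`,
#'   `rate`, `sd_ms`, `anticipatory_prob`, `error_prob`) and `ml2` (fields
#'   `n_trials`, `initial_mt_s`, `asymptote_mt_s`, `mt_decay`,
#'   `initial_error_deg`, `asymptote_error_deg`, `error_decay`, `mt_sd_s`,
#'   `error_sd_deg`).
#' @param trait_corr Target Pearson correlation between the two latent
#'   subject traits (slow-gamma peak frequency and SICI ratio).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 20L,
                       sampling_rate = 1000,
                       n_channels = c(MAG = 8L, GRAD = 8L),
                       grid_dims = c(3L, 3L, 3L),
                       grid_spacing = 8,
                       band_truth = list(
                         beta       = list(freq = 19, amplitude = 1.0, tonic = 1.0,
                                           erd_depth = 0.8, ers_gain = 1.2),
                         slow_gamma = list(freq = 43, amplitude = 1.0, tonic = 0.15),
                         mid_gamma  = list(freq = 71, amplitude = 0.8, tonic = 0.15)
                       ),
                       snr = 5,
                       source_background_rms = 1.0,
                       noise_pink_fraction = 0.5,
                       line_hz = 50,
                       line_rel = 0.5,
                       task_id = c("MA1", "MA1-exp3", "MA2"),
                       rt_mean_s = 0.25, rt_sd_s = 0.04,
                       mt_mean_s = 0.40, mt_sd_s = 0.06,
                       emg_burst_gain = 10,
                       trial_amp_sd = 0.2,
                       mep_model = list(base_mv = 1.0, sici_ratio = 0.5,
                                        log_sd = 0.2, precontraction_prob = 0.05,
                                        subthreshold_prob = 0.02, block_size = 15L),
                       learning_model = list(
                         ml1 = list(initial_ms = 400, asymptote_ms = 320,
                                    rate = 0.35, sd_ms = 30,
                                    anticipatory_prob = 0.01, error_prob = 0.03),
                         ml2 = list(n_trials = 60L, initial_mt_s = 12,
                                    asymptote_mt_s = 8, mt_decay = 0.004,
                                    initial_error_deg = 12,
                                    asymptote_error_deg = 4, error_decay = 0.004,
                                    mt_sd_s = 0.5, error_sd_deg = 1.5)
                       ),
                       trait_corr = 0.65) {
  task_id <- match.arg(task_id)
  assert_that(sampling_rate > 2 * 90,
              "sampling_rate must exceed twice the highest band edge (180 Hz)")
  assert_that(snr > 0, "`snr` must be positive")
  assert_that(abs(trait_corr) <= 1, "|trait_corr| must not exceed 1")
  assert_that(all(n_channels >= 2), "each sensor group needs >= 2 channels")
  for (b in names(band_truth)) {
    edges <- analysis_bands()[[b]]
    if (!is.null(edges)) {
      f <- band_truth[[b]]$freq
      assert_that(f >= edges[1] && f <= edges[2],
                  "true %s peak %g Hz lies outside its band [%g, %g]",
                  b, f, edges[1], edges[2])
    }
  }
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         sampling_rate = sampling_rate, n_channels = n_channels,
         grid_dims = grid_dims, grid_spacing = grid_spacing,
         band_truth = band_truth, snr = snr,
         source_background_rms = source_background_rms,
         noise_pink_fraction = noise_pink_fraction,
         line_hz = line_hz, line_rel = line_rel, task_id = task_id,
         rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
         mt_mean_s = mt_mean_s, mt_sd_s = mt_sd_s,
         emg_burst_gain = emg_burst_gain, trial_amp_sd = trial_amp_sd,
         mep_model = mep_model, learning_model = learning_model,
         trait_corr = trait_corr),
    class = "sim_config"
  )
}

#' Generate a trial schedule for one of the task designs
#'
#' `"MA1"`: 70 trials, 20\% NoGo; each trial is a 200 ms cue, a 1 s
#' cue-stimulus interval, a 200 ms Go/NoGo stimulus, then an inter-trial
#' interval drawn uniformly from 2-4 s. `"MA1-exp3"`: 140 Go-only trials with
#' the inter-trial interval drawn from \{2.7, 3.2, 3.7, 4.2, 4.7\} s.
#' `"MA2"`: four digits cued at 1 Hz, eight flashes per digit, the 32-flash
#' cycle repeated eight times (256 paced presses).
#'
#' @param task_id `"MA1"`, `"MA1-exp3"` or `"MA2"`.
#' @param seed RNG seed.
#' @return Data frame of class `trial_schedule` with columns `trial`,
#'   `label` (`"cue"`, `"go"`, `"nogo"`, `"flash"`), `time_s` and, for MA2,
#'   `digit`. Attribute `task_id` records the design.
#' @export
make_trial_schedule <- function(task_id, seed = 1L) {
  assert_that(task_id %in% c("MA1", "MA1-exp3", "MA2"),
              "unknown task_id '%s'", task_id)
  ev <- with_seed(seed, {
    if (task_id == "MA1") {
      n <- 70L
      n_nogo <- round(0.2 * n)
      is_nogo <- logical(n)
      is_nogo[sample.int(n, n_nogo)] <- TRUE
      t <- 1   # lead-in
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        cue_t <- t
        stim_t <- cue_t + 0.2 + 1.0          # 200 ms cue, 1 s cue-stimulus interval
        rows[[i]] <- data.frame(
          trial = i, label = c("cue", if (is_nogo[i]) "nogo" else "go"),
          time_s = c(cue_t, stim_t))
        t <- stim_t + 0.2 + runif(1, 2, 4)   # 200 ms stimulus, then ITI
      }
      do.call(rbind, rows)
    } else if (task_id == "MA1-exp3") {
      n <- 140L
      itis <- sample(c(2.7, 3.2, 3.7, 4.2, 4.7), n, replace = TRUE)
      t <- 1
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        cue_t <- t
        stim_t <- cue_t + 0.2 + 1.0
        rows[[i]] <- data.frame(trial = i, label = c("cue", "go"),
                                time_s = c(cue_t, stim_t))
        t <- stim_t + 0.2 + itis[i]
      }
      do.call(rbind, rows)
    } else {                                  # MA2: paced presses at 1 Hz
      n_rep <- 8L; flashes_per_digit <- 8L; digits <- c("D2", "D3", "D4", "D5")
      ord <- rep(rep(digits, each = flashes_per_digit), n_rep)
      n <- length(ord)                        # 256 flashes
      data.frame(trial = seq_len(n), label = "flash",
                 time_s = 1 + seq_len(n) - 1, digit = ord)
    }
  })
  attr(ev, "task_id") <- task_id
  class(ev) <- c("trial_schedule", class(ev))
  ev
}

#' Ground-truth subject and trial parameters for a schedule
#'
#' Draws the per-trial true movement onset/offset (for Go/flash events) and
#' fixes the subject's true band peak frequencies and source locations.
#'
#' @param config A [sim_config()].
#' @param schedule A [make_trial_schedule()] table.
#' @param seed RNG seed.
#' @return List with `bands` (per band: `freq`, `source`), `trials` (data
#'   frame: `trial`, `go_time_s`, `onset_s`, `offset_s` in absolute recording
#'   time, plus `rt_s`, `mt_s`), and `duration_s`.
#' @export
make_ground_truth <- function(config, schedule, seed = 1L) {
  go <- schedule[schedule$label %in% c("go", "flash"), , drop = FALSE]
  n_src <- prod(config$grid_dims)
  with_seed(seed, {
    rt <- pmax(0.1, rnorm(nrow(go), config$rt_mean_s, config$rt_sd_s))
    mt <- pmax(0.15, rnorm(nrow(go), config$mt_mean_s, config$mt_sd_s))
    bands <- lapply(config$band_truth, function(bt) {
      list(freq = bt$freq, source = sample.int(n_src, 1))
    })
    trials <- data.frame(
      trial = go$trial, go_time_s = go$time_s,
      onset_s = go$time_s + rt, offset_s = go$time_s + rt + mt,
      rt_s = rt, mt_s = mt)
    list(bands = bands, trials = trials,
         duration_s = max(schedule$time_s) + 4)
  })
}

#' Synthetic source-space leadfield on a regular grid
#'
#' Sensors sit on a sphere around the grid; the gain from source to sensor
#' falls off smoothly with distance, with a small seeded perturbation to
#' break grid symmetries and a group-specific scale (GRAD channels twice the
#' gain of MAG). Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return List with `gain` (sources x channels), `coords` (sources x 3, mm)
#'   and `channel_groups` (no EMG channel: leadfields describe sensors only).
#' @export
make_leadfield <- function(config) {
  dims <- config$grid_dims; sp <- config$grid_spacing
  coords <- as.matrix(expand.grid(
    x = (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp,
    y = (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp,
    z = (seq_len(dims[3]) - (dims[3] + 1) / 2) * sp))
  n_src <- nrow(coords)
  groups <- rep(names(config$n_channels), config$n_channels)
  n_ch <- length(groups)
  radius <- max(sp * max(dims), 40)
  with_seed(child_seed(config$seed, 104729), {
    # sensors spread on a sphere (seeded but fixed per config)
    u <- matrix(rnorm(n_ch * 3), n_ch)
    u <- u / sqrt(rowSums(u^2)) * radius
    d <- as.matrix(dist(rbind(coords, u)))[seq_len(n_src), n_src + seq_len(n_ch)]
    gain <- 1 / (1 + (d / (2 * sp))^2)
    gain <- gain * (1 + 0.05 * matrix(rnorm(n_src * n_ch), n_src))
    scale <- ifelse(groups == "GRAD", 2, 1)
    gain <- sweep(gain, 2, scale, "*")
    list(gain = gain, coords = coords, channel_groups = groups)
  })
}

# Hann-tapered boxcar envelope evaluated on a sample grid (absolute seconds)
#' @noRd
hann_env <- function(t, from, to) {
  env <- numeric(length(t))
  inside <- t >= from & t <= to
  if (any(inside)) {
    u <- (t[inside] - from) / (to - from)
    env[inside] <- 0.5 - 0.5 * cos(2 * pi * u)
  }
  env
}

# Asymmetric Hann ramp: rises over [from, peak], falls over [peak, to]
#' @noRd
hann_peak_env <- function(t, from, peak, to) {
  env <- numeric(length(t))
  up <- t >= from & t <= peak
  if (any(up)) env[up] <- 0.5 - 0.5 * cos(pi * (t[up] - from) / (peak - from))
  dn <- t > peak & t <= to
  if (any(dn)) env[dn] <- 0.5 + 0.5 * cos(pi * (t[dn] - peak) / (to - peak))
  env
}

#' @noRd
pink_noise <- function(n) {
  # spectrally shaped 1/sqrt(f) amplitude noise, unit variance; computed at
  # a highly composite FFT length and truncated (mixed-radix FFTs degrade
  # badly on near-prime lengths)
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  spec <- fft(white)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)                      # mirror for negative freqs
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

#' Simulate a continuous movement-task recording
#'
#' Sensor data are `t(gain) \%*\% sources` plus a white/pink noise mixture at
#' the configured SNR and a mains-frequency sinusoid. Each Go (or paced
#' press) trial injects, at its band's true source: a beta-band power drop
#' from just before movement onset to movement offset followed by a rebound
#' lasting about 1 s after offset; a slow-gamma burst ramping up from onset
#' and peaking at movement offset; and a mid-gamma burst between onset and
#' offset. The EMG channel carries a broadband burst from the true onset to
#' the true offset at `emg_burst_gain` times its baseline RMS.
#'
#' @param config A [sim_config()].
#' @param schedule A [make_trial_schedule()] table.
#' @param truth Output of [make_ground_truth()]; generated if `NULL`.
#' @param seed RNG seed for noise and per-trial jitter.
#' @return A [recording()]; the ground truth is attached as attribute
#'   `"truth"` and the leadfield as attribute `"leadfield"`.
#' @export
simulate_recording <- function(config, schedule, truth = NULL, seed = 1L) {
  assert_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  assert_that(nrow(schedule) > 0, "schedule is empty")
  assert_that(config$snr > 0, "`snr` must be positive")
  if (is.null(truth)) truth <- make_ground_truth(config, schedule, seed)
  fs <- config$sampling_rate
  n <- ceiling(truth$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  lf <- make_leadfield(config)
  n_src <- nrow(lf$gain)
  src <- matrix(0, n_src, n)
  tr <- truth$trials

  with_seed(child_seed(seed, 1L), {
    for (b in names(config$band_truth)) {
      bt <- config$band_truth[[b]]
      gt <- truth$bands[[b]]
      f0 <- gt$freq
      amp_env <- rep(bt$tonic, n)
      for (i in seq_len(nrow(tr))) {
        jit <- exp(rnorm(1, 0, config$trial_amp_sd))
        on <- tr$onset_s[i]; off <- tr$offset_s[i]
        if (b == "beta") {
          amp_env <- amp_env - bt$erd_depth * jit * hann_env(t, on - 0.2, off) +
            bt$ers_gain * jit * hann_env(t, off, off + 1)
        } else if (b == "slow_gamma") {
          amp_env <- amp_env + jit * hann_peak_env(t, on, off, off + 0.5)
        } else {
          amp_env <- amp_env + jit * hann_env(t, on, off)
        }
      }
      amp_env <- pmax(amp_env, 0)
      phase <- runif(1, 0, 2 * pi)
      src[gt$source, ] <- src[gt$source, ] +
        bt$amplitude * amp_env * sin(2 * pi * f0 * t + phase)
    }
    if (config$source_background_rms > 0) {
      for (s in seq_len(n_src)) {
        src[s, ] <- src[s, ] + config$source_background_rms * pink_noise(n)
      }
    }
  })

  sensors <- t(lf$gain) %*% src
  sig_rms <- rms(as.vector(sensors))
  if (sig_rms == 0) sig_rms <- 1
  noise_rms <- sig_rms / config$snr
  with_seed(child_seed(seed, 2L), {
    for (ch in seq_len(nrow(sensors))) {
      w <- rnorm(n)
      p <- pink_noise(n)
      mix <- sqrt(1 - config$noise_pink_fraction) * w +
        sqrt(config$noise_pink_fraction) * p
      sensors[ch, ] <- sensors[ch, ] + noise_rms * mix +
        config$line_rel * noise_rms * sin(2 * pi * config$line_hz * t + ch)
    }
  })

  emg <- with_seed(child_seed(seed, 3L), {
    base_sd <- 1
    x <- rnorm(n, sd = base_sd)
    for (i in seq_len(nrow(tr))) {
      idx <- t >= tr$onset_s[i] & t <= tr$offset_s[i]
      # flat-top burst with linear 10 ms edge ramps
      ramp <- pmax(0, pmin(1, (t[idx] - tr$onset_s[i]) / 0.01,
                           (tr$offset_s[i] - t[idx]) / 0.01))
      x[idx] <- x[idx] * (1 + (config$emg_burst_gain - 1) * ramp)
    }
    x
  })

  data <- rbind(sensors, emg)
  groups <- c(lf$channel_groups, "EMG")
  ev <- data.frame(sample = pmin(round(schedule$time_s * fs), n - 1),
                   label = schedule$label, trial = schedule$trial)
  rec <- recording(data, groups, fs, ev)
  attr(rec, "truth") <- truth
  attr(rec, "leadfield") <- lf
  rec
}

#' Draw a correlated population of subject traits
#'
#' Latent trait pairs come from a standard bivariate normal with correlation
#' `trait_corr`; they are mapped by monotone affine clamps onto the subject's
#' slow-gamma peak frequency (35-57 Hz) and true SICI ratio (0.05-1.45).
#'
#' @param config A [sim_config()] with `n_subjects >= 5`.
#' @return List with `table` (data frame: `subject`, `z1`, `z2`,
#'   `slow_gamma_freq`, `sici_ratio`, `subject_seed`), `empirical_r` (sample
#'   correlation of the latents) and `configs` (per-subject [sim_config()]s
#'   with the mapped truths installed).
#' @export
simulate_population <- function(config) {
  assert_that(inherits(config, "sim_config"), "`config` must be a sim_config")
  assert_that(abs(config$trait_corr) <= 1, "|trait_corr| must not exceed 1")
  assert_that(config$n_subjects >= 5,
              "population simulation needs n_subjects >= 5 (got %d)",
              config$n_subjects)
  n <- config$n_subjects
  z <- with_seed(config$seed, {
    sigma <- matrix(c(1, config$trait_corr, config$trait_corr, 1), 2)
    MASS::mvrnorm(n, mu = c(0, 0), Sigma = sigma)
  })
  freq <- pmin(pmax(46 + 5.5 * z[, 1], 35), 57)
  sici <- pmin(pmax(0.55 + 0.2 * z[, 2], 0.05), 1.45)
  tab <- data.frame(subject = seq_len(n), z1 = z[, 1], z2 = z[, 2],
                    slow_gamma_freq = freq, sici_ratio = sici,
                    subject_seed = vapply(seq_len(n), function(i)
                      child_seed(config$seed, 1000 + i), integer(1)))
  configs <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$band_truth$slow_gamma$freq <- freq[i]
    cfg$mep_model$sici_ratio <- sici[i]
    cfg$seed <- tab$subject_seed[i]
    cfg
  })
  list(table = tab, empirical_r = cor(z[, 1], z[, 2]), configs = configs)
}

#' Simulate TMS motor-evoked-potential trials
#'
#' Peak-to-peak amplitudes are log-normal with a protocol-specific median:
#' single-pulse protocols use `mep_model$base_mv`, conditioned (SICI)
#' protocols `base_mv * sici_ratio`. A configurable fraction of trials gets
#' pre-pulse EMG contamination (> 0.1 mV in the 80 ms before the pulse) and a
#' fraction of sub-threshold responses, to exercise the rejection rules.
#'
#' @param config A [sim_config()].
#' @param protocol One of `"spMEP"`, `"SICI1ms"`, `"SICI2.5ms"`,
#'   `"spMEP_early"`, `"spMEP_late"`, `"SICI_early"`, `"SICI_late"`.
#' @param n_trials Trials for this protocol (15 for the pre-movement
#'   protocols of the first design; 13 per condition in the rest-SICI
#'   design).
#' @param seed RNG seed.
#' @return Data frame with columns `protocol`, `block`, `trial`, `p2p_mv`,
#'   `prepulse_mv`, `conditioned`.
#' @export
simulate_mep_trials <- function(config, protocol, n_trials = 15L, seed = 1L) {
  protos <- c("spMEP", "SICI1ms", "SICI2.5ms", "spMEP_early", "spMEP_late",
              "SICI_early", "SICI_late")
  assert_that(protocol %in% protos, "unknown protocol '%s'", protocol)
  assert_that(n_trials >= 1, "`n_trials` must be at least 1")
  mm <- config$mep_model
  conditioned <- grepl("^SICI", protocol)
  meanlog <- log(if (conditioned) mm$base_mv * mm$sici_ratio else mm$base_mv)
  with_seed(seed, {
    p2p <- rlnorm(n_trials, meanlog, mm$log_sd)
    sub <- runif(n_trials) < mm$subthreshold_prob
    p2p[sub] <- runif(sum(sub), 0.01, 0.09)
    pre <- abs(rnorm(n_trials, 0, 0.02))
    contam <- runif(n_trials) < mm$precontraction_prob
    pre[contam] <- runif(sum(contam), 0.11, 0.4)
    data.frame(protocol = protocol,
               block = rep(seq_len(ceiling(n_trials / mm$block_size)),
                           each = mm$block_size)[seq_len(n_trials)],
               trial = seq_len(n_trials), p2p_mv = p2p, prepulse_mv = pre,
               conditioned = conditioned)
  })
}

#' Simulate a single MEP EMG trace
#'
#' Biphasic response with an exact programmed peak-to-peak amplitude at
#' about 22 ms latency, plus white measurement noise.
#'
#' @param p2p_mv Programmed peak-to-peak amplitude (mV).
#' @param fs Sampling rate (Hz, default 5000).
#' @param duration_s Trace length (s, default 0.1).
#' @param noise_sd Noise SD in mV (default 0.01).
#' @param seed RNG seed.
#' @return List with `trace` (mV), `fs` and `response_window` (s).
#' @export
simulate_mep_trace <- function(p2p_mv, fs = 5000, duration_s = 0.1,
                               noise_sd = 0.01, seed = 1L) {
  t <- seq(0, duration_s, by = 1 / fs)
  lat <- 0.022; width <- 0.008
  shape <- sin(2 * pi * (t - lat) / (2 * width)) *
    exp(-((t - lat - width) / width)^2)
  shape[t < lat] <- 0
  shape <- shape / (max(shape) - min(shape)) * p2p_mv
  noise <- with_seed(seed, rnorm(length(t), 0, noise_sd))
  list(trace = shape + noise, fs = fs, response_window = c(0.015, 0.055))
}

#' The fixed 10-item cue sequence of the sequence-learning task
#'
#' Ten cues over four keys with per-key counts 3, 3, 2, 2.
#' @return Integer vector of key indices (1-4).
#' @export
ml1_sequence <- function() c(1L, 2L, 3L, 1L, 4L, 2L, 1L, 3L, 2L, 4L)

#' Simulate a session of the cued sequence-learning task
#'
#' Fifteen blocks of 30 cues: blocks 1 and 15 are random, blocks 2-14 are
#' three repeats of the fixed 10-item sequence ([ml1_sequence()]). Reaction
#' times follow an exponential learning curve across sequence blocks with a
#' sequence-specific advantage absent in random blocks, plus Gaussian noise;
#' a small fraction of trials is anticipatory (negative RT) or incorrect.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return Data frame with columns `block`, `trial`, `cue`, `rt_ms`,
#'   `correct`, `block_type` (`"random"`/`"sequence"`).
#' @export
simulate_ml1 <- function(config, seed = 1L) {
  lm1 <- config$learning_model$ml1
  with_seed(seed, {
    rows <- vector("list", 15)
    for (b in 1:15) {
      seqb <- b >= 2 && b <= 14
      cues <- if (seqb) rep(ml1_sequence(), 3) else sample(rep(1:4, c(8, 8, 7, 7)))
      mean_rt <- if (seqb) ml1_block_mean(lm1, b) else lm1$initial_ms
      rt <- rnorm(30, mean_rt, lm1$sd_ms)
      ant <- runif(30) < lm1$anticipatory_prob
      rt[ant] <- -runif(sum(ant), 50, 150)
      rows[[b]] <- data.frame(
        block = b, trial = seq_len(30), cue = cues, rt_ms = rt,
        correct = runif(30) >= lm1$error_prob,
        block_type = if (seqb) "sequence" else "random")
    }
    do.call(rbind, rows)
  })
}

#' Expected block-mean RT of the simulated sequence-learning curve
#' @param lm1 The `ml1` learning model list of a [sim_config()].
#' @param block Block number (2-14).
#' @return Expected mean RT in ms.
#' @export
ml1_block_mean <- function(lm1, block) {
  lm1$asymptote_ms + (lm1$initial_ms - lm1$asymptote_ms) *
    exp(-lm1$rate * (block - 2))
}

#' Closed-form expected learning score of the simulated curve
#' @param lm1 The `ml1` learning model list of a [sim_config()].
#' @return Expected percentage-change score (negative = learning).
#' @export
ml1_expected_score <- function(lm1) {
  b2 <- ml1_block_mean(lm1, 2)
  plateau <- mean(vapply(10:14, function(b) ml1_block_mean(lm1, b), numeric(1)))
  100 * (plateau - b2) / b2
}

#' Simulate a session of the continuous tracing task
#'
#' Trial-wise movement time and absolute angular error decay exponentially
#' with cumulative time-on-task towards their asymptotes, plus truncated
#' Gaussian noise.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @return Data frame with columns `trial`, `mt_s`, `error_deg`.
#' @export
simulate_ml2 <- function(config, seed = 1L) {
  lm2 <- config$learning_model$ml2
  det <- ml2_expected_series(lm2)
  with_seed(seed, {
    mt <- pmax(1, det$mt_s + rnorm(lm2$n_trials, 0, lm2$mt_sd_s))
    err <- pmax(0, det$error_deg + rnorm(lm2$n_trials, 0, lm2$error_sd_deg))
    data.frame(trial = seq_len(lm2$n_trials), mt_s = mt, error_deg = err)
  })
}

#' Noise-free expected trial series of the tracing task
#' @param lm2 The `ml2` learning model list of a [sim_config()].
#' @return Data frame `trial`, `mt_s`, `error_deg` (deterministic).
#' @export
ml2_expected_series <- function(lm2) {
  n <- lm2$n_trials
  mt <- numeric(n); err <- numeric(n); ct <- 0
  for (i in seq_len(n)) {
    mt[i] <- lm2$asymptote_mt_s +
      (lm2$initial_mt_s - lm2$asymptote_mt_s) * exp(-lm2$mt_decay * ct)
    err[i] <- lm2$asymptote_error_deg +
      (lm2$initial_error_deg - lm2$asymptote_error_deg) * exp(-lm2$error_decay * ct)
    ct <- ct + mt[i]
  }
  data.frame(trial = seq_len(n), mt_s = mt, error_deg = err)
}
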