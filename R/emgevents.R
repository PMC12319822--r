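#' Default EMG movement-detection parameters
#'
#' High-pass at 10 Hz, an 80 ms root-mean-square envelope, a forward
#' non-overlapping 24 ms onset search, a backward non-overlapping 120 ms
#' offset search, and a threshold of 3 SDs of the EMG activity between
#' -600 and -200 ms relative to the Go stimulus.
#'
#' @return Named list of parameters (seconds / multiples).
#' @export
emg_params <- function() {
  list(highpass_hz = 10, rms_window_s = 0.080,
       onset_window_s = 0.024, offset_window_s = 0.120,
       baseline_s = c(-0.6, -0.2), threshold_sd = 3,
       epoch_s = c(-1, 3))
}

#' @noRd
rms_envelope <- function(x, fs, window_s) {
  # causal (trailing-window) moving RMS: the envelope at sample i uses only
  # samples up to i, so the envelope rise stays aligned with burst onset
  w <- max(1L, round(window_s * fs))
  xs <- c(rep(x[1], w - 1), x)^2
  ma <- as.numeric(stats::filter(xs, rep(1 / w, w), sides = 1))
  sqrt(ma[w:(w + length(x) - 1)])
}

#' Detect EMG movement onset and offset within a trial
#'
#' The trial is assumed segmented from -1 to +3 s around the Go stimulus.
#' The EMG is high-pass filtered at 10 Hz and its causal RMS envelope (80 ms
#' trailing window) computed. The threshold is 3 SDs of the EMG activity in
#' the [-600, -200] ms baseline window. The
#' onset is the start of the first forward non-overlapping 24 ms window
#' (searching from the Go stimulus) in which the envelope exceeds the
#' threshold; the offset is the start of the first such backward 120 ms
#' window (searching from the trial end). A detection with offset <= onset
#' is discarded. If no window crosses, both are `NA` ("no movement
#' detected"), never an error.
#'
#' @param emg Numeric vector, one trial of EMG.
#' @param fs Sampling rate in Hz.
#' @param params See [emg_params()].
#' @return List with `onset_s`, `offset_s` (seconds relative to Go, `NA` if
#'   undetected), `envelope_peak` and `threshold`.
#' @export
detect_onset_offset <- function(emg, fs, params = emg_params()) {
  ep <- params$epoch_s
  n <- length(emg)
  expected <- round((ep[2] - ep[1]) * fs)
  assert_that(abs(n - expected) <= 1,
              "trial length %d does not match the %g..%g s epoch at %g Hz",
              n, ep[1], ep[2], fs)
  t0 <- -ep[1]                                 # Go stimulus position (s into trial)
  hp <- signal::butter(4, params$highpass_hz / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, emg)
  env <- rms_envelope(x, fs, params$rms_window_s)
  bidx <- which((seq_len(n) - 1) / fs - t0 >= params$baseline_s[1] &
                  (seq_len(n) - 1) / fs - t0 < params$baseline_s[2])
  # threshold: three SDs of the baseline EMG activity itself (the smoothed
  # envelope has too little variance to give a stable exceedance criterion)
  thr <- params$threshold_sd * sd(x[bidx])

  go_i <- round(t0 * fs) + 1L
  w_on <- max(1L, round(params$onset_window_s * fs))
  onset <- NA_real_
  s <- go_i
  while (s + w_on - 1 <= n) {
    if (max(env[s:(s + w_on - 1)]) > thr) {
      onset <- (s - 1) / fs - t0
      break
    }
    s <- s + w_on
  }
  w_off <- max(1L, round(params$offset_window_s * fs))
  offset <- NA_real_
  s <- n - w_off + 1L
  while (s >= go_i) {
    if (max(env[s:(s + w_off - 1)]) > thr) {
      offset <- (s - 1) / fs - t0
      break
    }
    s <- s - w_off
  }
  if (!is.na(onset) && !is.na(offset) && offset <= onset) offset <- NA_real_
  list(onset_s = onset, offset_s = offset,
       envelope_peak = max(env[go_i:n]), threshold = thr)
}

#' Movement marks for every Go trial of a recording
#'
#' Segments the EMG channel from -1 to +3 s around each Go (or paced press)
#' event and runs [detect_onset_offset()] per trial.
#'
#' @param rec A [recording()] with one EMG channel and Go events.
#' @param params See [emg_params()].
#' @return Data frame of class `movement_marks`: `trial`, `go_sample`,
#'   `onset_s`, `offset_s`, `rt_s`, `mt_s`, `envelope_peak`, `excluded`,
#'   `reason`.
#' @export
detect_movements <- function(rec, params = emg_params()) {
  emg_ch <- which(rec$channel_groups == "EMG")
  assert_that(length(emg_ch) == 1, "recording must carry exactly one EMG channel")
  go <- rec$events[rec$events$label %in% c("go", "flash"), , drop = FALSE]
  assert_that(nrow(go) > 0, "no Go events in recording")
  fs <- rec$sampling_rate
  pre <- round(-params$epoch_s[1] * fs); post <- round(params$epoch_s[2] * fs)
  rows <- lapply(seq_len(nrow(go)), function(i) {
    g <- go$sample[i] + 1L                    # events are 0-based
    lo <- g - pre; hi <- g + post - 1L
    if (lo < 1 || hi > n_samples(rec)) {
      return(data.frame(trial = go$trial[i], go_sample = go$sample[i],
                        onset_s = NA_real_, offset_s = NA_real_,
                        rt_s = NA_real_, mt_s = NA_real_,
                        envelope_peak = NA_real_, excluded = TRUE,
                        reason = "incomplete epoch"))
    }
    d <- detect_onset_offset(rec$data[emg_ch, lo:hi], fs, params)
    no_move <- is.na(d$onset_s) || is.na(d$offset_s)
    data.frame(trial = go$trial[i], go_sample = go$sample[i],
               onset_s = d$onset_s, offset_s = d$offset_s,
               rt_s = d$onset_s, mt_s = d$offset_s - d$onset_s,
               envelope_peak = d$envelope_peak,
               excluded = no_move,
               reason = if (no_move) "no movement detected" else "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("movement_marks", class(out))
  out
}

#' Exclude trials whose EMG metrics are outliers
#'
#' Applies [gesd()] independently to the envelope peak, the reaction time and
#' the movement time across detectable trials; the union of flagged trials is
#' excluded, with the reason listing every metric that flagged the trial.
#'
#' @param marks A `movement_marks` table from [detect_movements()].
#' @param alpha GESD significance level (default 0.05).
#' @param max_outlier_fraction Passed to [gesd()] (default 0.2).
#' @return The `movement_marks` table with updated `excluded`/`reason`.
#' @export
exclude_trials <- function(marks, alpha = 0.05, max_outlier_fraction = 0.2) {
  ok <- which(!marks$excluded)
  assert_that(length(ok) >= 3, "need at least 3 detectable trials (got %d)",
              length(ok))
  metrics <- list(envelope = marks$envelope_peak[ok],
                  rt = marks$rt_s[ok], mt = marks$mt_s[ok])
  for (m in names(metrics)) {
    hit <- gesd(metrics[[m]], alpha = alpha,
                max_outlier_fraction = max_outlier_fraction)
    for (i in ok[hit]) {
      marks$excluded[i] <- TRUE
      marks$reason[i] <- if (nzchar(marks$reason[i]))
        paste(marks$reason[i], m, sep = ",") else paste0("outlier:", m)
    }
  }
  marks
}
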