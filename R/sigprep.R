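#' Zero-phase spectral filter application
#'
#' Multiplies the spectrum of `x` by a real, non-negative transfer function
#' after reflection padding (to suppress wrap-around transients). Real
#' transfer functions have zero phase by construction, so event latencies
#' are untouched.
#'
#' @noRd
apply_fd_filter <- function(x, fs, shape) {
  n <- length(x)
  pad <- min(n, 2 * round(fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1]))
  m <- stats::nextn(length(xp), c(2, 3, 5))
  xp <- c(xp, numeric(m - length(xp)))
  f <- (seq_len(m) - 1) * fs / m
  f <- pmin(f, fs - f)                           # two-sided spectrum
  H <- shape(f)
  y <- Re(fft(fft(xp) * H, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

# raised-cosine step from 0 (at f0) to 1 (at f1); vectorised over f
#' @noRd
rc_rise <- function(f, f0, f1) {
  out <- numeric(length(f))
  out[f >= f1] <- 1
  tr <- f > f0 & f < f1
  out[tr] <- 0.5 - 0.5 * cos(pi * (f[tr] - f0) / (f1 - f0))
  out
}

#' @noRd
band_transfer <- function(low_hz, high_hz, notches, nyq, transition_hz) {
  force(low_hz); force(high_hz); force(notches); force(transition_hz)
  function(f) {
    H <- rc_rise(f, max(low_hz - transition_hz, 0), low_hz) *
      (1 - rc_rise(f, high_hz, min(high_hz + transition_hz, nyq)))
    for (nt in notches) {
      H <- H * (1 - rc_rise(f, nt[1] - transition_hz, nt[1]) *
                  (1 - rc_rise(f, nt[2], nt[2] + transition_hz)))
    }
    H
  }
}

#' Anti-aliased resampling of a recording
#'
#' Integer-factor downsampling applies a zero-phase spectral anti-aliasing
#' low-pass (flat to 0.8 of the new Nyquist, raised-cosine roll-off reaching
#' zero at the new Nyquist) and keeps every q-th sample; non-integer ratios
#' fall back to polyphase resampling ([signal::resample()]). Event sample
#' indices are rescaled with round-half-away-from-zero, so an event at
#' sample 1000 of a 1000 Hz recording lands on sample 500 at 500 Hz.
#'
#' @param rec A [recording()].
#' @param target_rate New sampling rate in Hz; must not exceed the current
#'   rate (this is a downsampling step).
#' @return A [recording()] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  assert_that(is.numeric(target_rate) && target_rate > 0,
              "`target_rate` must be positive")
  assert_that(target_rate <= rec$sampling_rate,
              "target rate %g exceeds current rate %g", target_rate, rec$sampling_rate)
  if (target_rate == rec$sampling_rate) return(rec)
  q <- rec$sampling_rate / target_rate
  if (abs(q - round(q)) < 1e-9) {
    q <- round(q)
    new_nyq <- target_rate / 2
    shape <- function(f) 1 - rc_rise(f, 0.8 * new_nyq, new_nyq)
    keep <- seq(1, ncol(rec$data), by = q)
    out <- t(apply(rec$data, 1, function(x)
      apply_fd_filter(x, rec$sampling_rate, shape)[keep]))
  } else {
    g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
    p <- round(target_rate); qq <- round(rec$sampling_rate)
    d <- g(p, qq)
    out <- t(apply(rec$data, 1, function(x)
      signal::resample(x, p / d, qq / d)))
  }
  ratio <- target_rate / rec$sampling_rate
  ev <- rec$events
  if (nrow(ev) > 0) {
    ev$sample <- pmin(round_half_away(ev$sample * ratio), ncol(out) - 1)
  }
  recording(out, rec$channel_groups, target_rate, ev)
}

#' Zero-phase band-pass and notch filtering
#'
#' Filters in the frequency domain with a real (zero-phase) transfer
#' function: unit gain across the pass-band, raised-cosine transitions of
#' width `transition_hz`, and full suppression inside each notch interval.
#' A flat pass-band makes repeated application idempotent there, and zero
#' phase leaves event latencies untouched. Reflection padding suppresses
#' edge transients.
#'
#' @param rec A [recording()].
#' @param low_hz,high_hz Band-pass corner frequencies in Hz
#'   (`0 < low_hz < high_hz < Nyquist`); gain is 1 on `[low_hz, high_hz]`.
#' @param notches List of length-2 numeric vectors, each a notch interval in
#'   Hz, e.g. `list(c(49, 55), c(99, 101))`; gain is 0 inside each interval.
#'   Intervals at or above Nyquist are rejected.
#' @param channels Channel indices to filter; defaults to all channels.
#' @param transition_hz Width of the raised-cosine transitions (default 1).
#' @return The filtered [recording()].
#' @export
filter_band <- function(rec, low_hz, high_hz, notches = list(), channels = NULL,
                        transition_hz = 1) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  nyq <- rec$sampling_rate / 2
  assert_that(low_hz > 0 && low_hz < high_hz, "need 0 < low_hz < high_hz")
  assert_that(high_hz < nyq, "high corner %g Hz must lie below Nyquist (%g Hz)",
              high_hz, nyq)
  for (nt in notches) {
    assert_that(length(nt) == 2 && nt[1] < nt[2] && nt[1] > 0 && nt[2] < nyq,
                "notch interval must lie strictly inside (0, Nyquist)")
  }
  if (is.null(channels)) channels <- seq_len(nrow(rec$data))
  shape <- band_transfer(low_hz, high_hz, notches, nyq, transition_hz)
  dat <- rec$data
  for (ch in channels) {
    dat[ch, ] <- apply_fd_filter(dat[ch, ], rec$sampling_rate, shape)
  }
  recording(dat, rec$channel_groups, rec$sampling_rate, rec$events)
}

#' Split a recording into the canonical analysis bands
#'
#' Convenience wrapper producing one zero-phase band-filtered copy per band
#' (beta 13-30 Hz, slow gamma 30-60 Hz, mid gamma 60-90 Hz by default).
#'
#' @param rec A [recording()], already band-passed/notched.
#' @param bands Named list of `c(low, high)` band edges in Hz.
#' @param channels Channel indices to filter (default: non-EMG channels).
#' @return Named list of band-filtered [recording()]s.
#' @export
split_bands <- function(rec, bands = analysis_bands(), channels = channels_in(rec)) {
  lapply(bands, function(bd)
    filter_band(rec, bd[1], bd[2], channels = channels))
}

#' Canonical frequency bands
#'
#' @return Named list with band edges in Hz: beta 13-30, slow gamma 30-60,
#'   mid gamma 60-90.
#' @export
analysis_bands <- function() {
  list(beta = c(13, 30), slow_gamma = c(30, 60), mid_gamma = c(60, 90))
}

#' Generalised extreme studentised deviate (GESD) outlier detection
#'
#' Rosner's sequential ESD test for up to `k_max = floor(max_outlier_fraction
#' * n)` outliers (at least one), so the flagged fraction never exceeds the
#' cap. At step i the most extreme remaining value (largest
#' absolute deviation from the current mean; ties broken by lowest index) is
#' removed and the studentised statistic R_i compared with the critical value
#' lambda_i derived from the t distribution at significance `alpha`. The
#' flagged set corresponds to the largest i with R_i > lambda_i.
#'
#' @param values Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @param max_outlier_fraction Upper bound on the fraction of points that may
#'   be flagged (default 0.2).
#' @return Integer vector of flagged indices into `values` (possibly empty).
#' @export
#' @examples
#' gesd(c(rnorm(20), 25))
gesd <- function(values, alpha = 0.05, max_outlier_fraction = 0.2) {
  n <- length(values)
  assert_that(n >= 3, "GESD needs at least 3 values (got %d)", n)
  assert_that(alpha > 0 && alpha < 1, "`alpha` must lie in (0, 1)")
  assert_that(max_outlier_fraction > 0 && max_outlier_fraction <= 0.5,
              "`max_outlier_fraction` must lie in (0, 0.5]")
  k_max <- max(1L, floor(max_outlier_fraction * n))
  remaining <- seq_len(n)
  x <- values
  removed <- integer(0)
  R <- lambda <- numeric(k_max)
  for (i in seq_len(k_max)) {
    m <- mean(x); s <- sd(x)
    if (!is.finite(s) || s == 0) { k_max <- i - 1L; break }
    dev <- abs(x - m)
    j <- which.max(dev)           # which.max returns the first (lowest) index on ties
    R[i] <- dev[j] / s
    ni <- length(x)
    p <- 1 - alpha / (2 * ni)
    tcrit <- qt(p, ni - 2)
    lambda[i] <- (ni - 1) * tcrit / sqrt((ni - 2 + tcrit^2) * ni)
    removed <- c(removed, remaining[j])
    remaining <- remaining[-j]
    x <- x[-j]
  }
  if (k_max == 0) return(integer(0))
  hits <- which(R[seq_len(k_max)] > lambda[seq_len(k_max)])
  if (length(hits) == 0) return(integer(0))
  sort(removed[seq_len(max(hits))])
}

#' Detect artefactual time segments from windowed channel variability
#'
#' Splits the recording into non-overlapping windows (1 s by default),
#' computes the standard deviation of the signal pooled across all non-EMG
#' channels per window, and applies [gesd()] to the resulting series. EMG
#' channels are exempt: EMG bursts are signal, not artefact.
#'
#' @param rec A [recording()].
#' @param window Window length in seconds (default 1).
#' @param alpha GESD significance level (default 0.05).
#' @param max_fraction Maximum fraction of windows that may be flagged
#'   (default 0.2).
#' @return A `segment_mask` list with `window_s`, `n_windows`, `flagged`
#'   (integer 1-based window indices) and `coverage_fraction`.
#' @export
detect_bad_segments <- function(rec, window = 1, alpha = 0.05, max_fraction = 0.2) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  wlen <- round(window * rec$sampling_rate)
  n_win <- floor(n_samples(rec) / wlen)
  assert_that(n_win >= 3, "recording must span at least 3 windows (%d found)", n_win)
  ch <- channels_in(rec)                      # non-EMG
  metric <- vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    sd(as.vector(rec$data[ch, idx, drop = FALSE]))
  }, numeric(1))
  flagged <- gesd(metric, alpha = alpha, max_outlier_fraction = max_fraction)
  structure(
    list(window_s = window, n_windows = n_win, flagged = flagged,
         coverage_fraction = length(flagged) / n_win),
    class = "segment_mask"
  )
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment_mask> %d/%d windows of %g s flagged (%.1f%%)\n",
              length(x$flagged), x$n_windows, x$window_s,
              100 * x$coverage_fraction))
  invisible(x)
}

#' Sample indices covered by flagged segments
#' @param mask A `segment_mask` from [detect_bad_segments()].
#' @param sampling_rate Sampling rate of the recording the mask refers to.
#' @return Integer vector of 1-based sample indices.
#' @export
mask_samples <- function(mask, sampling_rate) {
  wlen <- round(mask$window_s * sampling_rate)
  if (length(mask$flagged) == 0) return(integer(0))
  unlist(lapply(mask$flagged, function(w) ((w - 1) * wlen + 1):(w * wlen)))
}
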