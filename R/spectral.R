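.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computed as eigenvectors of the symmetric tridiagonal Slepian matrix,
#' ordered by decreasing eigenvalue and normalised to unit energy. Results
#' are cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product.
#' @param k Number of tapers (usually `2 * nw - 1`).
#' @return `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  assert_that(k >= 1, "need at least one taper; increase the half-bandwidth")
  assert_that(k <= n, "cannot compute %d tapers of length %d", k, n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  es <- eigen(A, symmetric = TRUE)
  tapers <- es$vectors[, seq_len(k), drop = FALSE]
  tapers <- apply(tapers, 2, function(h) {
    h <- h / sqrt(sum(h^2))
    if (sum(h) != 0) h * sign(sum(h)) else h * sign(h[2] - h[1])
  })
  .taper_cache[[key]] <- tapers
  tapers
}

#' Cut continuous data into event-locked epochs
#'
#' @param x Rows-by-samples matrix (channels or sources).
#' @param fs Sampling rate (Hz).
#' @param lock_samples 1-based sample index of the lock event per trial.
#' @param window Epoch window in seconds relative to the lock event
#'   (default `c(-2, 2)`).
#' @param bad_samples Optional 1-based sample indices to avoid: epochs
#'   overlapping any are dropped.
#' @return Array `trials x rows x samples` with attributes `times` (seconds
#'   relative to lock) and `kept` (indices of retained trials). Trials whose
#'   window leaves the recording are dropped.
#' @export
epoch_data <- function(x, fs, lock_samples, window = c(-2, 2), bad_samples = NULL) {
  pre <- round(-window[1] * fs); post <- round(window[2] * fs)
  len <- pre + post
  keep <- integer(0); slices <- list()
  bad <- if (is.null(bad_samples)) integer(0) else bad_samples
  for (i in seq_along(lock_samples)) {
    lo <- lock_samples[i] - pre; hi <- lock_samples[i] + post - 1L
    if (lo < 1 || hi > ncol(x)) next
    if (length(bad) > 0 && any(bad >= lo & bad <= hi)) next
    keep <- c(keep, i)
    slices[[length(slices) + 1L]] <- x[, lo:hi, drop = FALSE]
  }
  assert_that(length(keep) > 0, "no epoch fits inside the recording")
  out <- array(0, c(length(keep), nrow(x), len))
  for (j in seq_along(slices)) out[j, , ] <- slices[[j]]
  attr(out, "times") <- (seq_len(len) - 1 - pre) / fs
  attr(out, "kept") <- keep
  out
}

#' DPSS multitaper time-frequency decomposition
#'
#' Slides a 1.6 s window in 200 ms steps (defaults) across each epoch and
#' location, averaging DPSS-tapered periodograms across tapers. The output
#' frequency grid has 1 Hz spacing (zero-padded grid spacing); each time
#' bin is stamped with its window centre. Only windows fully contained in
#' the epoch are computed.
#'
#' @param epochs `trials x locations x samples` array with a `times`
#'   attribute (as from [epoch_data()]), or a matrix `locations x samples`
#'   for a single trial.
#' @param fs Sampling rate (Hz).
#' @param window Taper window length in seconds (default 1.6).
#' @param step Window step in seconds (default 0.2).
#' @param freq_range Analysis frequency range `c(min, max)` in Hz.
#' @param freq_step Output frequency spacing in Hz (default 1).
#' @param half_bandwidth Spectral half-bandwidth in Hz (default 1.5, giving
#'   `nw = 2.4` and 3 tapers for a 1.6 s window). Peak frequencies are read
#'   off a 1 Hz grid, so the concentration band is kept comparable to that
#'   grid; wider bandwidths smooth spectral tilt into the peak estimate.
#' @return A `tf_power` list: `power` (`trials x freqs x times x locations`,
#'   absolute power), `freqs`, `times`, `fs`, `relative = FALSE`.
#' @export
multitaper_tf <- function(epochs, fs, window = 1.6, step = 0.2,
                          freq_range = c(1, 95), freq_step = 1,
                          half_bandwidth = 1.5) {
  if (is.matrix(epochs)) {
    tms <- attr(epochs, "times")
    epochs <- array(epochs, c(1, dim(epochs)))
    attr(epochs, "times") <- tms
  }
  times <- attr(epochs, "times")
  assert_that(!is.null(times), "epochs need a `times` attribute")
  n_tr <- dim(epochs)[1]; n_loc <- dim(epochs)[2]; n_s <- dim(epochs)[3]
  win_n <- round(window * fs)
  assert_that(win_n <= n_s, "epoch (%d samples) shorter than taper window (%d)",
              n_s, win_n)
  nw <- half_bandwidth * window
  k <- max(1L, floor(2 * nw) - 1L)
  assert_that(2 * nw >= 2, "half-bandwidth too small for at least one taper")
  tapers <- dpss_tapers(win_n, nw, k)
  pad_mult <- ceiling(win_n / fs)
  nfft <- as.integer(pad_mult * fs / freq_step) * 1L
  nfft <- max(nfft, win_n)
  df <- fs / nfft
  freqs <- seq(ceiling(freq_range[1]), floor(freq_range[2]), by = freq_step)
  fidx <- round(freqs / df) + 1L
  assert_that(max(abs(fidx - (freqs / df + 1))) < 1e-9,
              "frequency grid is not commensurate with the FFT length")

  t0 <- times[1]; t1 <- times[n_s]
  centers <- seq(ceiling((t0 + window / 2) / step) * step,
                 floor((t1 - window / 2) / step + 1e-9) * step, by = step)
  assert_that(length(centers) > 0, "no taper window fits inside the epoch")
  n_f <- length(freqs); n_t <- length(centers)
  out <- array(0, c(n_tr, n_f, n_t, n_loc))
  zero_pad <- matrix(0, nfft - win_n, n_tr * n_loc)
  for (ti in seq_len(n_t)) {
    s0 <- round((centers[ti] - window / 2 - t0) * fs) + 1L
    seg <- epochs[, , s0:(s0 + win_n - 1), drop = FALSE]
    # samples x (trial*loc)
    M <- matrix(aperm(seg, c(3, 1, 2)), nrow = win_n)
    acc <- matrix(0, n_f, n_tr * n_loc)
    for (kk in seq_len(k)) {
      X <- mvfft(rbind(M * tapers[, kk], zero_pad))
      acc <- acc + abs(X[fidx, , drop = FALSE])^2
    }
    acc <- acc * (2 / (k * fs))
    out[, , ti, ] <- aperm(array(t(acc), c(n_tr, n_loc, n_f)), c(1, 3, 2))
  }
  structure(list(power = out, freqs = freqs, times = centers, fs = fs,
                 relative = FALSE),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_power> %d trials x %d freqs (%g-%g Hz) x %d times (%g..%g s) x %d locations%s\n",
              d[1], d[2], min(x$freqs), max(x$freqs), d[3],
              min(x$times), max(x$times), d[4],
              if (x$relative) ", baseline-corrected" else ""))
  invisible(x)
}

#' Baseline-correct a time-frequency decomposition
#'
#' Per frequency and location, the baseline `B` is the mean absolute power
#' over the baseline time bins *and over all trials*; the output is the
#' relative change `(P - B) / B`.
#'
#' @param tf A `tf_power` from [multitaper_tf()] (absolute power).
#' @param baseline_window `c(from, to)` in seconds relative to the lock
#'   event; bins whose centre falls inside (inclusive) are baseline bins.
#' @return A `tf_power` with `relative = TRUE`.
#' @export
baseline_correct <- function(tf, baseline_window = c(-1, -0.5)) {
  assert_that(inherits(tf, "tf_power"), "`tf` must be a tf_power")
  assert_that(!tf$relative, "tf is already baseline-corrected")
  bsel <- which(tf$times >= baseline_window[1] & tf$times <= baseline_window[2])
  assert_that(length(bsel) > 0, "baseline window [%g, %g] contains no time bin",
              baseline_window[1], baseline_window[2])
  d <- dim(tf$power)
  B <- apply(tf$power[, , bsel, , drop = FALSE], c(2, 4), mean)
  assert_that(all(B > 0), "baseline power must be strictly positive")
  Bfull <- aperm(array(B, c(d[2], d[4], d[1], d[3])), c(3, 1, 4, 2))
  tf$power <- (tf$power - Bfull) / Bfull
  tf$relative <- TRUE
  tf
}

#' @noRd
trial_time_average <- function(tf, windows) {
  d <- dim(tf$power)
  assert_that(nrow(windows) == d[1],
              "need one averaging window per trial (%d != %d)", nrow(windows), d[1])
  out <- array(0, c(d[1], d[2], d[4]))
  for (i in seq_len(d[1])) {
    sel <- which(tf$times >= windows$from[i] & tf$times <= windows$to[i])
    if (length(sel) == 0) {
      sel <- which.min(abs(tf$times - (windows$from[i] + windows$to[i]) / 2))
    }
    out[i, , ] <- apply(tf$power[i, , sel, , drop = FALSE], c(2, 4), mean)
  }
  out
}

#' Extract the band peak (power, frequency, location)
#'
#' Power is averaged over each trial's own averaging window (onset to offset
#' for movement-locked responses; offset to offset + 1 s for the post-
#' movement beta rebound, with epochs locked to offset), then across trials,
#' leaving a frequency-by-location matrix. Its maximum (`mode = "max"`, ERS)
#' or minimum (`mode = "min"`, ERD) within the band and the region of
#' interest defines the subject's power, peak frequency and peak location.
#' Ties are broken towards the lowest frequency, then the lowest location
#' index.
#'
#' @param tf A baseline-corrected `tf_power`.
#' @param windows Data frame with columns `from`, `to`: per-trial averaging
#'   window in seconds on the epoch time axis (one row per trial in `tf`).
#' @param band `c(low, high)` band edges in Hz.
#' @param mode `"max"` for ERS, `"min"` for ERD.
#' @param roi Integer location indices to consider (default: all).
#' @return A `band_peak` list: `power`, `peak_frequency`, `peak_location`,
#'   `band`, `mode`.
#' @export
extract_band_peak <- function(tf, windows, band, mode = c("max", "min"),
                              roi = NULL) {
  mode <- match.arg(mode)
  assert_that(inherits(tf, "tf_power"), "`tf` must be a tf_power")
  d <- dim(tf$power)
  if (is.null(roi)) roi <- seq_len(d[4])
  assert_that(length(roi) > 0, "region of interest is empty")
  per_trial <- trial_time_average(tf, windows)        # trials x freq x loc
  fl <- apply(per_trial, c(2, 3), mean)               # freq x loc
  fsel <- which(tf$freqs >= band[1] & tf$freqs <= band[2])
  assert_that(length(fsel) > 0, "band [%g, %g] not covered by the frequency grid",
              band[1], band[2])
  sub <- fl[fsel, roi, drop = FALSE]
  target <- if (mode == "max") max(sub) else min(sub)
  hits <- which(sub == target, arr.ind = TRUE)
  # ties: lowest frequency, then lowest location index
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  structure(list(power = target,
                 peak_frequency = tf$freqs[fsel[hits[1, 1]]],
                 peak_location = roi[hits[1, 2]],
                 band = band, mode = mode),
            class = "band_peak")
}

#' @export
print.band_peak <- function(x, ...) {
  cat(sprintf("<band_peak> %s in [%g, %g] Hz: power %.3f at %g Hz, location %d\n",
              x$mode, x$band[1], x$band[2], x$power, x$peak_frequency,
              x$peak_location))
  invisible(x)
}

#' Movement-related power map at a fixed frequency
#'
#' Same averaging as [extract_band_peak()] (per-trial window, then across
#' trials) restricted to one frequency, yielding one value per location.
#'
#' @inheritParams extract_band_peak
#' @param frequency Frequency in Hz; must be on the grid of `tf`.
#' @return Numeric vector, one power value per location.
#' @export
power_map <- function(tf, windows, frequency) {
  assert_that(inherits(tf, "tf_power"), "`tf` must be a tf_power")
  fi <- which(abs(tf$freqs - frequency) < 1e-9)
  assert_that(length(fi) == 1, "frequency %g Hz is not on the grid", frequency)
  per_trial <- trial_time_average(tf, windows)
  colMeans(matrix(per_trial[, fi, ], nrow = dim(per_trial)[1]))
}

#' Per-trial averaging windows from movement marks
#'
#' For onset-locked epochs the window runs from movement onset (0 s) to each
#' trial's movement offset; for offset-locked epochs (post-movement beta
#' rebound) it runs from the offset (0 s) to offset + 1 s.
#'
#' @param marks Retained rows of a `movement_marks` table (one per epoch).
#' @param lock `"onset"` or `"offset"`.
#' @return Data frame with columns `from`, `to` (seconds on the epoch axis).
#' @export
mark_windows <- function(marks, lock = c("onset", "offset")) {
  lock <- match.arg(lock)
  if (lock == "onset") data.frame(from = rep(0, nrow(marks)), to = marks$mt_s)
  else data.frame(from = rep(0, nrow(marks)), to = rep(1, nrow(marks)))
}
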