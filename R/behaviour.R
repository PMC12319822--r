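#' Learning score of the cued sequence task
#'
#' Drops incorrect presses and anticipatory reaction times (RT <= 0, i.e.
#' responses initiated before the cue), then discards RTs outside the mean
#' +/- 2 SD within each block (one pass). The score is the percentage change
#' from the first sequence block (block 2) to the plateau blocks 10-14:
#' `100 * (mean RT blocks 10-14 - mean RT block 2) / mean RT block 2`.
#' More negative scores mean more learning.
#'
#' @param session Data frame with columns `block`, `rt_ms`, `correct` (as
#'   from [simulate_ml1()]).
#' @param sd_mult Outlier spread multiplier (default 2).
#' @return A `learning_score` list: `task = "ml1"`, `value` (percent),
#'   `block2_mean_ms`, `plateau_mean_ms`, `n_used`.
#' @export
ml1_score <- function(session, sd_mult = 2) {
  assert_that(all(c("block", "rt_ms", "correct") %in% names(session)),
              "`session` needs columns block, rt_ms, correct")
  keep <- session$correct & session$rt_ms > 0
  s <- session[keep, , drop = FALSE]
  retained <- logical(nrow(s))
  for (b in unique(s$block)) {
    i <- which(s$block == b)
    m <- mean(s$rt_ms[i]); sdv <- sd(s$rt_ms[i])
    retained[i] <- abs(s$rt_ms[i] - m) <= sd_mult * sdv
  }
  s <- s[retained, , drop = FALSE]
  b2 <- s$rt_ms[s$block == 2]
  plat <- s$rt_ms[s$block %in% 10:14]
  assert_that(length(b2) >= 1, "block 2 retains no reaction times")
  assert_that(all(10:14 %in% s$block), "blocks 10-14 must each retain RTs")
  value <- 100 * (mean(plat) - mean(b2)) / mean(b2)
  structure(list(task = "ml1", value = value,
                 block2_mean_ms = mean(b2), plateau_mean_ms = mean(plat),
                 n_used = nrow(s)),
            class = "learning_score")
}

#' Assign tracing-task trials to bins of equal movement time
#'
#' The cumulative movement time is partitioned at multiples of
#' `MT_total / n_bins`; each trial goes to the bin containing its cumulative-
#' time midpoint, so a trial straddling a boundary joins the bin holding the
#' majority of it.
#'
#' @param session Data frame with column `mt_s` (as from [simulate_ml2()]).
#' @param n_bins Number of bins (default 6).
#' @return Integer vector of bin indices (1..n_bins), one per trial; errors
#'   if any bin would be empty.
#' @export
ml2_bin <- function(session, n_bins = 6) {
  assert_that(all(session$mt_s > 0), "movement times must be positive")
  n <- nrow(session)
  assert_that(n >= n_bins, "need at least %d trials (got %d)", n_bins, n)
  total <- sum(session$mt_s)
  cum <- cumsum(session$mt_s)
  mid <- cum - session$mt_s / 2
  bin <- pmin(floor(mid / (total / n_bins)) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  assert_that(all(counts > 0),
              "bin(s) %s contain no trial; reduce n_bins or supply more trials",
              paste(which(counts == 0), collapse = ", "))
  bin
}

#' Learning score of the continuous tracing task
#'
#' Trials are split into `n_bins` bins of equal movement time ([ml2_bin()]);
#' the score is the last-bin minus first-bin mean of the trial-wise movement
#' time and of the absolute angular error. Negative values mean learning.
#'
#' @param session Data frame with columns `mt_s`, `error_deg`.
#' @param n_bins Number of bins (default 6).
#' @return A `learning_score` list: `task = "ml2"`, `value` (named vector
#'   `delta_mt_s`, `delta_error_deg`), `bin_mt_s`, `bin_error_deg` (per-bin
#'   means), `n_used`.
#' @export
ml2_score <- function(session, n_bins = 6) {
  assert_that(all(c("mt_s", "error_deg") %in% names(session)),
              "`session` needs columns mt_s and error_deg")
  bin <- ml2_bin(session, n_bins)
  bin_mt <- tapply(session$mt_s, bin, mean)
  bin_err <- tapply(session$error_deg, bin, mean)
  structure(list(task = "ml2",
                 value = c(delta_mt_s = unname(bin_mt[n_bins] - bin_mt[1]),
                           delta_error_deg = unname(bin_err[n_bins] - bin_err[1])),
                 bin_mt_s = as.numeric(bin_mt),
                 bin_error_deg = as.numeric(bin_err),
                 n_used = nrow(session)),
            class = "learning_score")
}

#' @export
print.learning_score <- function(x, ...) {
  if (x$task == "ml1") {
    cat(sprintf("<learning_score> ml1: %.2f%% (block 2: %.0f ms -> plateau: %.0f ms)\n",
                x$value, x$block2_mean_ms, x$plateau_mean_ms))
  } else {
    cat(sprintf("<learning_score> ml2: delta MT %.2f s, delta error %.2f deg\n",
                x$value["delta_mt_s"], x$value["delta_error_deg"]))
  }
  invisible(x)
}
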