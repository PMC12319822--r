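#' Peak-to-peak amplitude of an MEP trace
#'
#' @param trace Numeric EMG trace (mV).
#' @param fs Sampling rate (Hz).
#' @param response_window `c(from, to)` in seconds within the trace.
#' @return Peak-to-peak amplitude (max minus min) inside the window, in the
#'   units of `trace`.
#' @export
peak_to_peak <- function(trace, fs, response_window) {
  idx <- which((seq_along(trace) - 1) / fs >= response_window[1] &
                 (seq_along(trace) - 1) / fs <= response_window[2])
  assert_that(length(idx) > 0, "response window [%g, %g] s is empty",
              response_window[1], response_window[2])
  max(trace[idx]) - min(trace[idx])
}

#' @noRd
grubbs_critical <- function(n, alpha = 0.05) {
  tcrit <- qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Single two-sided Grubbs' test iteration
#'
#' Flags the most extreme value (largest studentised absolute deviation) if
#' its statistic exceeds the two-sided critical value at level `alpha`.
#'
#' @param x Numeric vector, length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return Index of the rejected value, or `integer(0)` if none.
#' @export
grubbs_once <- function(x, alpha = 0.05) {
  n <- length(x)
  assert_that(n >= 3, "Grubbs' test needs at least 3 values (got %d)", n)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(integer(0))
  dev <- abs(x - mean(x))
  j <- which.max(dev)
  if (dev[j] / s > grubbs_critical(n, alpha)) j else integer(0)
}

#' Rule-based rejection of MEP trials
#'
#' Applies, in order: (1) reject trials whose test-pulse amplitude is below
#' `min_mep_mv` (no reliable MEP) — applied to unconditioned trials only when
#' a `conditioned` column is present, since a small conditioned response may
#' be genuine inhibition; (2) reject trials with pre-pulse EMG above
#' `max_prepulse_mv` in the 80 ms before the pulse (precontraction); (3) per
#' protocol and block, reject amplitudes outside the survivors' mean +/- 2 SD
#' (SD recomputed on rule-1/2 survivors, candidate included); (4) per
#' protocol, one iteration of two-sided Grubbs' test at `alpha` on the
#' remaining trials, rejecting at most one trial per protocol.
#'
#' @param trials Data frame with columns `protocol`, `block`, `trial`,
#'   `p2p_mv`, `prepulse_mv` (as from [simulate_mep_trials()]).
#' @param min_mep_mv Reliability threshold in mV (default 0.1).
#' @param max_prepulse_mv Precontraction threshold in mV (default 0.1).
#' @param sd_mult Spread multiplier of rule 3 (default 2).
#' @param alpha Grubbs significance level (default 0.05).
#' @return `trials` with added logical `rejected` and character `reason`;
#'   protocols left without usable trials are recorded in attribute
#'   `"unusable_protocols"`.
#' @export
reject_mep_trials <- function(trials, min_mep_mv = 0.1, max_prepulse_mv = 0.1,
                              sd_mult = 2, alpha = 0.05) {
  needed <- c("protocol", "block", "p2p_mv", "prepulse_mv")
  assert_that(all(needed %in% names(trials)),
              "`trials` needs columns %s", paste(needed, collapse = ", "))
  for (p in unique(trials$protocol)) {
    assert_that(sum(trials$protocol == p) >= 3,
                "protocol '%s' has fewer than 3 trials", p)
  }
  trials$rejected <- FALSE
  trials$reason <- ""
  flag <- function(i, why) {
    trials$rejected[i] <<- TRUE
    trials$reason[i] <<- ifelse(nzchar(trials$reason[i]),
                                paste(trials$reason[i], why, sep = ";"), why)
  }
  # rule 1 targets the test pulse alone: conditioned (paired-pulse) trials
  # with small responses may reflect genuine inhibition and are kept
  uncond <- if (is.null(trials$conditioned)) rep(TRUE, nrow(trials))
            else !trials$conditioned
  flag(which(uncond & trials$p2p_mv < min_mep_mv), "no reliable MEP")
  flag(which(!trials$rejected & trials$prepulse_mv > max_prepulse_mv),
       "precontraction")
  # rule 3: mean +/- 2 SD per protocol x block on survivors
  for (p in unique(trials$protocol)) {
    for (b in unique(trials$block[trials$protocol == p])) {
      i <- which(trials$protocol == p & trials$block == b & !trials$rejected)
      if (length(i) < 3) next
      m <- mean(trials$p2p_mv[i]); s <- sd(trials$p2p_mv[i])
      out <- i[abs(trials$p2p_mv[i] - m) > sd_mult * s]
      flag(out, "outside mean +/- 2 SD")
    }
  }
  # rule 4: single Grubbs iteration per protocol
  for (p in unique(trials$protocol)) {
    i <- which(trials$protocol == p & !trials$rejected)
    if (length(i) < 3) next
    hit <- grubbs_once(trials$p2p_mv[i], alpha)
    if (length(hit) == 1) flag(i[hit], "Grubbs outlier")
  }
  unusable <- vapply(unique(trials$protocol), function(p)
    all(trials$rejected[trials$protocol == p]), logical(1))
  attr(trials, "unusable_protocols") <- unique(trials$protocol)[unusable]
  trials
}

#' Short-interval intracortical inhibition (SICI) ratio
#'
#' SICI is the ratio of the mean conditioned (paired-pulse) MEP amplitude to
#' the mean unconditioned (single-pulse) MEP amplitude, computed on retained
#' trials; values below 1 indicate inhibition.
#'
#' @param trials Data frame with `protocol`, `p2p_mv` and (after
#'   [reject_mep_trials()]) `rejected`; trials without a `rejected` column
#'   are all treated as retained.
#' @param conditioned_label Protocol label of the conditioned trials.
#' @param unconditioned_label Protocol label of the unconditioned trials.
#' @return A `sici_measure` list: `conditioned_mean`, `unconditioned_mean`,
#'   `ratio`, `n_used` (named vector).
#' @export
sici <- function(trials, conditioned_label, unconditioned_label) {
  if (is.null(trials$rejected)) trials$rejected <- FALSE
  cond <- trials[trials$protocol == conditioned_label & !trials$rejected, ]
  unco <- trials[trials$protocol == unconditioned_label & !trials$rejected, ]
  assert_that(nrow(cond) >= 1, "no retained conditioned trials ('%s')",
              conditioned_label)
  assert_that(nrow(unco) >= 1, "no retained unconditioned trials ('%s')",
              unconditioned_label)
  cm <- mean(cond$p2p_mv); um <- mean(unco$p2p_mv)
  assert_that(um > 0, "unconditioned mean amplitude is not positive")
  structure(list(conditioned_mean = cm, unconditioned_mean = um,
                 ratio = cm / um,
                 n_used = c(conditioned = nrow(cond),
                            unconditioned = nrow(unco))),
            class = "sici_measure")
}

#' @export
print.sici_measure <- function(x, ...) {
  cat(sprintf("<sici_measure> ratio %.3f (conditioned %.3f / unconditioned %.3f mV; n = %d/%d)\n",
              x$ratio, x$conditioned_mean, x$unconditioned_mean,
              x$n_used["conditioned"], x$n_used["unconditioned"]))
  invisible(x)
}
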