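#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible child seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#' @noRd
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483587)
}

#' Evaluate an expression with a local RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Round half away from zero
#'
#' Used when rescaling event sample indices so that the mapping is
#' independent of the IEEE round-to-even rule.
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Root mean square
#' @noRd
rms <- function(x) sqrt(mean(x^2))
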