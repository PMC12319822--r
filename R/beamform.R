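#' Eigenvalue normalisation of sensor groups
#'
#' For each channel group (coil type), computes the eigenvalues of the
#' within-group data covariance and divides the group's data by the smallest
#' eigenvalue, equalising the noise floors of heterogeneous sensor types
#' before they enter a common beamformer.
#'
#' @param rec A [recording()]; EMG channels are left untouched.
#' @param groups Group labels to normalise (default: all non-EMG groups).
#' @param tol Relative tolerance below which the smallest eigenvalue is
#'   treated as numerically zero.
#' @return The rescaled [recording()]; the scale factors are attached as
#'   attribute `"eigen_scales"`.
#' @export
eigen_normalize <- function(rec, groups = NULL, tol = 1e-12) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  if (is.null(groups)) groups <- setdiff(unique(rec$channel_groups), "EMG")
  dat <- rec$data
  scales <- setNames(numeric(length(groups)), groups)
  for (g in groups) {
    ch <- which(rec$channel_groups == g)
    assert_that(length(ch) >= 2, "group '%s' needs >= 2 channels", g)
    C <- tcrossprod(dat[ch, , drop = FALSE]) / ncol(dat)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    lmin <- min(ev)
    assert_that(lmin > tol * max(ev),
      "group '%s' is rank deficient (smallest eigenvalue %.3g); remove redundant channels or reduce the group",
      g, lmin)
    dat[ch, ] <- dat[ch, , drop = FALSE] / lmin
    scales[g] <- lmin
  }
  out <- recording(dat, rec$channel_groups, rec$sampling_rate, rec$events)
  attr(out, "eigen_scales") <- scales
  out
}

#' LCMV beamformer weights with PCA rank reduction
#'
#' The sensor covariance is inverted on its leading principal subspace
#' (pseudo-inverse truncated to `rank` dimensions, with eigenvalues floored
#' at `1e-12` times the largest). For each source with leadfield column
#' `l`, the weight vector is `w = (l' C^-1 l)^-1 l' C^-1`, which satisfies
#' the unit-gain constraint `w %*% l == 1`.
#'
#' @param covariance Symmetric channels-by-channels covariance matrix.
#' @param leadfield Leadfield list as from [make_leadfield()], or a plain
#'   sources-by-channels gain matrix.
#' @param rank PCA rank (default 50); clipped with a warning if it exceeds
#'   the number of channels.
#' @param tol Sources with projected leadfield power `l' C^-1 l` at or below
#'   `tol` are flagged unresolvable (weights `NA`).
#' @return Sources-by-channels weight matrix; attribute `"unresolvable"`
#'   lists flagged source indices.
#' @export
lcmv_weights <- function(covariance, leadfield, rank = 50, tol = 1e-12) {
  gain <- if (is.list(leadfield)) leadfield$gain else leadfield
  assert_that(is.matrix(covariance) && nrow(covariance) == ncol(covariance),
              "`covariance` must be square")
  assert_that(max(abs(covariance - t(covariance))) <
                1e-8 * max(abs(covariance)), "`covariance` must be symmetric")
  assert_that(ncol(gain) == nrow(covariance),
              "leadfield has %d channels but covariance %d",
              ncol(gain), nrow(covariance))
  n_ch <- nrow(covariance)
  if (rank > n_ch) {
    warning(sprintf("rank %d exceeds %d channels; clipped", rank, n_ch))
    rank <- n_ch
  }
  es <- eigen(covariance, symmetric = TRUE)
  keep <- which(es$values > 1e-12 * es$values[1])
  keep <- keep[seq_len(min(rank, length(keep)))]
  Cinv <- es$vectors[, keep, drop = FALSE] %*%
    (t(es$vectors[, keep, drop = FALSE]) / es$values[keep])
  CL <- Cinv %*% t(gain)                       # channels x sources
  denom <- colSums(t(gain) * CL)               # l' C^-1 l per source
  bad <- which(!is.finite(denom) | denom <= tol)
  denom[bad] <- NA_real_
  W <- t(CL) / denom                           # sources x channels
  attr(W, "unresolvable") <- bad
  W
}

#' Project sensor data onto source space
#'
#' Applies beamformer weights to continuous data or to an epochs array.
#'
#' @param x Either a channels-by-samples matrix, a [recording()] (non-EMG
#'   channels are projected), or a 3-D array `trials x channels x samples`.
#' @param weights Sources-by-channels matrix from [lcmv_weights()].
#' @return Sources-by-samples matrix, or `trials x sources x samples` array
#'   for epoch input.
#' @export
project_sources <- function(x, weights) {
  if (inherits(x, "recording")) x <- x$data[channels_in(x), , drop = FALSE]
  if (is.matrix(x)) {
    assert_that(ncol(weights) == nrow(x),
                "weights expect %d channels, data has %d", ncol(weights), nrow(x))
    return(weights %*% x)
  }
  assert_that(length(dim(x)) == 3, "epochs must be a trials x channels x samples array")
  assert_that(ncol(weights) == dim(x)[2],
              "weights expect %d channels, epochs have %d", ncol(weights), dim(x)[2])
  out <- array(0, c(dim(x)[1], nrow(weights), dim(x)[3]))
  for (tr in seq_len(dim(x)[1])) {
    out[tr, , ] <- weights %*% x[tr, , ]
  }
  out
}

#' Sensor covariance over retained samples
#'
#' Covariance across the whole time course of the given channels, excluding
#' samples covered by a bad-segment mask.
#'
#' @param rec A [recording()].
#' @param mask Optional `segment_mask` from [detect_bad_segments()].
#' @param channels Channel indices (default: non-EMG).
#' @return Channels-by-channels covariance matrix.
#' @export
sensor_covariance <- function(rec, mask = NULL, channels = channels_in(rec)) {
  dat <- rec$data[channels, , drop = FALSE]
  if (!is.null(mask)) {
    drop <- mask_samples(mask, rec$sampling_rate)
    if (length(drop) > 0) dat <- dat[, -drop, drop = FALSE]
  }
  tcrossprod(dat - rowMeans(dat)) / (ncol(dat) - 1)
}
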