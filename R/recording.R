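#' Construct a continuous multichannel recording
#'
#' A `recording` bundles a channels-by-samples data matrix with per-channel
#' group labels (e.g. `"MAG"`, `"GRAD"`, `"EEG"`, `"EMG"`), the sampling rate
#' in Hz, and an event table giving stimulus/trigger positions in samples.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channel_groups Character vector, one group label per channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param events Data frame with at least columns `sample` (0-based sample
#'   index) and `label`; may carry extra columns such as `trial`.
#'
#' @return An object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(200), 2), c("EEG", "EMG"), 100)
recording <- function(data, channel_groups, sampling_rate,
                      events = data.frame(sample = integer(), label = character())) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  assert_that(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  assert_that(nrow(data) >= 1, "recording needs at least one channel")
  assert_that(length(channel_groups) == nrow(data),
              "`channel_groups` must have one label per channel (%d != %d)",
              length(channel_groups), nrow(data))
  assert_that(is.numeric(sampling_rate) && sampling_rate > 0,
              "`sampling_rate` must be a positive number")
  assert_that(all(c("sample", "label") %in% names(events)),
              "`events` needs columns `sample` and `label`")
  if (nrow(events) > 0) {
    assert_that(all(events$sample >= 0 & events$sample < ncol(data)),
                "event sample indices must lie within [0, n_samples)")
  }
  structure(
    list(data = data, channel_groups = as.character(channel_groups),
         sampling_rate = sampling_rate, events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  grp <- table(x$channel_groups)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("  events: %d\n", nrow(x$events)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A [recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Indices of channels belonging to given groups
#' @param rec A [recording()].
#' @param groups Character vector of group labels; `NULL` selects all
#'   channels that are not EMG.
#' @return Integer channel indices.
#' @export
channels_in <- function(rec, groups = NULL) {
  if (is.null(groups)) which(rec$channel_groups != "EMG")
  else which(rec$channel_groups %in% groups)
}

#' Read or write a recording on disk
#'
#' Recordings are serialised as a directory holding the raw sample matrix
#' (RDS), the event table (CSV) and a JSON header with the sampling rate and
#' channel groups, so the event table and metadata stay human-readable.
#'
#' @param rec A [recording()].
#' @param path Directory to write to / read from (created if missing).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  assert_that(inherits(rec, "recording"), "`rec` must be a recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(rec$data, file.path(path, "data.rds"))
  utils::write.csv(rec$events, file.path(path, "events.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, channel_groups = rec$channel_groups),
    file.path(path, "header.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  ev <- utils::read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  recording(readRDS(file.path(path, "data.rds")), hdr$channel_groups,
            hdr$sampling_rate, ev)
}
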