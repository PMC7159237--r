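#' Multichannel recording container
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel names (length `nrow(data)`).
#' @param events Data frame with integer column `sample` (1-based, strictly
#'   increasing, within range) and character column `code`.
#' @param meta Optional list (montage, block boundaries, provenance).
#' @return An object of class `fpvs_recording`.
#' @export
recording <- function(data, fs, labels = NULL, events = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("labels must match channel count")
  if (fs <= 0) stop("fs must be > 0")
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = character(0))
  if (nrow(events)) {
    if (is.unsorted(events$sample, strictly = TRUE))
      stop("event samples must be strictly increasing")
    if (any(events$sample < 1L | events$sample > ncol(data)))
      stop("event samples out of range")
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 events = events, meta = meta),
            class = "fpvs_recording")
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf("<fpvs_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Epoch container
#'
#' A fixed-duration slice of a recording, time-locked to a stimulation
#' onset trigger.
#'
#' @param data Channels x samples matrix in microvolts.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to stimulation
#'   onset (negative for pre-stimulus baseline).
#' @param labels Channel names.
#' @param meta List: condition, sequence id, provenance.
#' @return An object of class `fpvs_epoch`.
#' @export
epoch <- function(data, fs, t0, labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(data)))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, t0 = t0, labels = labels, meta = meta),
            class = "fpvs_epoch")
}

#' @export
print.fpvs_epoch <- function(x, ...) {
  cat(sprintf("<fpvs_epoch> %d channels x %d samples @ %g Hz, t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0))
  invisible(x)
}

epoch_duration <- function(ep) ncol(ep$data) / ep$fs
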