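#' Align recording blocks to remove inter-block voltage jumps
#'
#' Each block (delimited by `block_boundaries`, the 1-based first sample of
#' every block after the first) is offset per channel by a constant so that
#' its first sample matches the last sample of the preceding block; the
#' first block is unchanged. Corrects DC jumps caused by voltage drift
#' during pauses between trials.
#'
#' @param rec An `fpvs_recording`.
#' @param block_boundaries Sorted sample indices where new blocks start;
#'   an empty vector returns `rec` unchanged.
#' @return The aligned `fpvs_recording`.
#' @export
align_blocks <- function(rec, block_boundaries) {
  block_boundaries <- block_boundaries[block_boundaries > 1L]
  if (length(block_boundaries) == 0L) return(rec)
  if (is.unsorted(block_boundaries, strictly = TRUE))
    stop("block boundaries must be strictly increasing")
  n <- ncol(rec$data)
  if (any(block_boundaries > n)) stop("block boundary out of range")
  x <- rec$data
  bounds <- c(block_boundaries, n + 1L)
  for (i in seq_along(block_boundaries)) {
    b <- block_boundaries[i]
    # preceding block is already aligned, so this jump is the total shift
    offset <- x[, b] - x[, b - 1L]
    idx <- b:(bounds[i + 1L] - 1L)
    x[, idx] <- x[, idx, drop = FALSE] - offset
  }
  rec$data <- x
  rec
}

# |H(e^{-iw})|^2 of a digital filter given its (b, a) coefficients,
# evaluated at frequencies f (Hz) for sampling rate fs.
iir_mag2 <- function(flt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  num <- 0i; den <- 0i
  b <- flt$b; a <- flt$a
  for (k in seq_along(b)) num <- num + b[k] * z^(k - 1)
  for (k in seq_along(a)) den <- den + a[k] * z^(k - 1)
  Mod(num / den)^2
}

# Zero-phase filtering: multiply the spectrum of every channel by a real
# gain (the squared design magnitude, i.e. the forward-backward response).
zero_phase_apply <- function(data, fs, gain) {
  n <- ncol(data)
  nf <- n %/% 2L + 1L
  g <- gain((0:(nf - 1L)) * fs / n)
  full <- if (n %% 2L == 0L) c(g, rev(g[2:(nf - 1L)])) else c(g, rev(g[2:nf]))
  X <- stats::mvfft(t(data)) * full
  out <- t(Re(stats::mvfft(X, inverse = TRUE))) / n
  rownames(out) <- rownames(data)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-`order` high-pass and low-pass Butterworth designs applied with
#' zero phase: the squared design magnitude (the response of a
#' forward-backward pass, effective magnitude order `2 * order`) is
#' applied in the frequency domain, which is exact, free of the numerical
#' instability of narrow time-domain recursions at the 0.1 Hz edge, and
#' leaves peak latencies of symmetric transients unchanged.
#'
#' @param rec An `fpvs_recording`.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Design order of each Butterworth section.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 100, order = 4) {
  nyq <- rec$fs / 2
  if (low <= 0 || high <= low || high >= nyq)
    stop("invalid band: need 0 < low < high < fs/2")
  hp <- signal::butter(order, low / nyq, "high")
  lp <- signal::butter(order, high / nyq, "low")
  rec$data <- zero_phase_apply(rec$data, rec$fs, function(f)
    iir_mag2(hp, f, rec$fs) * iir_mag2(lp, f, rec$fs))
  rec
}

#' Zero-phase multi-notch filter for mains noise
#'
#' Band-stop Butterworth designs of total width `width` centered on the
#' mains frequency and its harmonics, applied with zero phase (squared
#' design magnitude, as in [bandpass_filter()]).
#'
#' @param rec An `fpvs_recording`.
#' @param line Mains frequency in Hz.
#' @param n_freqs Number of notched frequencies (fundamental plus
#'   `n_freqs - 1` higher harmonics; the default notches 50, 100, 150 and
#'   200 Hz).
#' @param width Total stop-band width in Hz.
#' @param order Design order of each band-stop section.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, line = 50, n_freqs = 4, width = 0.5, order = 2) {
  nyq <- rec$fs / 2
  freqs <- line * seq_len(n_freqs)
  if (any(freqs + width / 2 >= nyq))
    stop(sprintf("notch at %g Hz is at or above Nyquist (%g Hz)",
                 max(freqs), nyq))
  filters <- lapply(freqs, function(f0)
    signal::butter(order, c(f0 - width / 2, f0 + width / 2) / nyq, "stop"))
  rec$data <- zero_phase_apply(rec$data, rec$fs, function(f) {
    g <- rep(1, length(f))
    for (flt in filters) g <- g * iir_mag2(flt, f, rec$fs)
    g
  })
  rec
}

#' Downsample a recording
#'
#' Fourier-domain resampling by an integer factor: the spectrum is
#' truncated at the target Nyquist frequency (ideal anti-aliasing, zero
#' phase) and the inverse transform is taken at the target rate. Event
#' sample indices are rescaled by `target_fs / fs` and rounded to the
#' nearest sample (ties round half up); trailing samples are dropped if
#' the length is not a multiple of the decimation factor.
#'
#' @param rec An `fpvs_recording`.
#' @param target_fs Target rate in Hz; must divide `fs`.
#' @return The downsampled recording.
#' @export
resample_recording <- function(rec, target_fs = 256) {
  if (target_fs > rec$fs) stop("upsampling is not supported")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("target_fs must divide fs")
  q <- as.integer(round(q))
  n <- (ncol(rec$data) %/% q) * q
  new_n <- n %/% q
  X <- stats::mvfft(t(rec$data[, seq_len(n), drop = FALSE]))
  keep <- new_n %/% 2L
  Y <- matrix(0i, new_n, nrow(rec$data))
  Y[1:(keep + 1L), ] <- X[1:(keep + 1L), ]
  if (new_n %% 2L == 0L) Y[keep + 1L, ] <- 0i  # drop the new Nyquist bin
  Y[(new_n - keep + if (new_n %% 2L == 0L) 2L else 1L):new_n, ] <-
    X[(n - keep + if (new_n %% 2L == 0L) 2L else 1L):n, ]
  data <- t(Re(stats::mvfft(Y, inverse = TRUE))) / n
  rownames(data) <- rec$labels
  ev <- rec$events
  if (nrow(ev))
    ev$sample <- as.integer(floor((ev$sample - 1L) / q + 0.5)) + 1L
  meta <- rec$meta
  if (!is.null(meta$block_starts))
    meta$block_starts <- as.integer(floor((meta$block_starts - 1L) / q + 0.5)) + 1L
  recording(data, target_fs, rec$labels, ev, meta)
}

#' Cut a recording into fixed-window epochs around triggers
#'
#' One epoch per matching trigger, spanning `t_min` to `t_max` seconds
#' relative to the trigger sample. Triggers too close to the recording
#' edge are skipped with a warning.
#'
#' @param rec An `fpvs_recording`.
#' @param code Trigger code(s) to epoch on (default: all events).
#' @param t_min,t_max Epoch window in seconds relative to the trigger.
#' @return List of `fpvs_epoch` objects; each carries the trigger code as
#'   `meta$condition` and its ordinal as `meta$sequence`.
#' @export
segment_epochs <- function(rec, code = NULL, t_min = -2, t_max = 66) {
  ev <- rec$events
  if (!is.null(code)) ev <- ev[ev$code %in% code, , drop = FALSE]
  n <- ncol(rec$data)
  n_pre <- as.integer(round(-t_min * rec$fs))
  n_len <- as.integer(round((t_max - t_min) * rec$fs))
  out <- list()
  for (i in seq_len(nrow(ev))) {
    start <- ev$sample[i] - n_pre
    stop_ <- start + n_len - 1L
    if (start < 1L || stop_ > n) {
      warning(sprintf("trigger at sample %d too close to recording edge; epoch skipped",
                      ev$sample[i]))
      next
    }
    out[[length(out) + 1L]] <-
      epoch(rec$data[, start:stop_, drop = FALSE], rec$fs, t0 = t_min,
            labels = rec$labels,
            meta = list(condition = ev$code[i], sequence = i,
                        eog_channels = rec$meta$eog_channels,
                        fade_duration = rec$meta$fade_duration,
                        seq_duration = rec$meta$seq_duration))
  }
  out
}

#' Blink rate of an epoch
#'
#' Blinks are counted as excursions of the vertical EOG difference signal
#' (first minus second EOG channel) beyond `amp_threshold`, with a
#' refractory separation of at least `refractory` seconds between counted
#' events. The epoch is flagged when the rate exceeds `threshold_rate`.
#'
#' @param ep An `fpvs_epoch`.
#' @param eog_channels Two vertical EOG channel labels (upper, lower); a
#'   single label uses that channel directly.
#' @param threshold_rate Flagging threshold in blinks per second.
#' @param amp_threshold Excursion amplitude threshold in muV.
#' @param refractory Minimum separation between blinks in seconds.
#' @return List with `n_blinks`, `rate` (per second) and `flagged`.
#' @export
blink_rate <- function(ep, eog_channels, threshold_rate = 0.15,
                       amp_threshold = 100, refractory = 0.2) {
  miss <- setdiff(eog_channels, ep$labels)
  if (length(miss)) stop("missing EOG channel(s): ", paste(miss, collapse = ", "))
  v <- if (length(eog_channels) >= 2)
    ep$data[eog_channels[1], ] - ep$data[eog_channels[2], ]
  else ep$data[eog_channels[1], ]
  above <- abs(v) > amp_threshold
  idx <- which(above)
  n_blinks <- 0L
  last <- -Inf
  gap <- refractory * ep$fs
  for (i in idx) {
    if (i - last >= gap) {
      n_blinks <- n_blinks + 1L
      last <- i
    } else last <- i  # extend the ongoing excursion
  }
  rate <- n_blinks / epoch_duration(ep)
  list(n_blinks = n_blinks, rate = rate, flagged = rate > threshold_rate)
}

#' Regress EOG activity out of EEG channels
#'
#' Replaces every non-EOG channel by its residual after least-squares
#' projection onto the EOG channels (plus intercept). A deterministic
#' ocular-correction step for epochs flagged by [blink_rate()]; the EOG
#' channels themselves are untouched.
#'
#' @param ep An `fpvs_epoch`.
#' @param eog_channels EOG channel labels.
#' @return The corrected epoch.
#' @export
regress_out_eog <- function(ep, eog_channels) {
  miss <- setdiff(eog_channels, ep$labels)
  if (length(miss)) stop("missing EOG channel(s): ", paste(miss, collapse = ", "))
  X <- cbind(1, t(ep$data[eog_channels, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("EOG channels are rank deficient")
  eeg <- setdiff(ep$labels, eog_channels)
  Y <- t(ep$data[eeg, , drop = FALSE])
  resid <- Y - X %*% qr.coef(qx, Y)
  ep$data[eeg, ] <- t(resid)
  ep
}

#' Interpolate bad channels from pooled neighbors
#'
#' Each bad channel is replaced by the unweighted mean of its 3-6
#' designated neighbor channels. Refuses when more than 5 % of channels
#' are bad, or when a neighbor is itself bad.
#'
#' @param ep An `fpvs_epoch`.
#' @param bad Labels of bad channels.
#' @param neighbors Named list: for each bad channel, its neighbor labels.
#' @return The interpolated epoch.
#' @export
interpolate_channels <- function(ep, bad, neighbors) {
  if (length(bad) == 0) return(ep)
  if (length(bad) / length(ep$labels) > 0.05)
    stop(sprintf("%d of %d channels bad (> 5%%); refusing to interpolate",
                 length(bad), length(ep$labels)))
  for (b in bad) {
    nb <- neighbors[[b]]
    if (is.null(nb) || length(nb) < 3 || length(nb) > 6)
      stop("each bad channel needs 3 to 6 designated neighbors: ", b)
    if (any(nb %in% bad)) stop("neighbor of ", b, " is itself bad")
    miss <- setdiff(nb, ep$labels)
    if (length(miss)) stop("unknown neighbor channel(s): ",
                           paste(miss, collapse = ", "))
    ep$data[b, ] <- colMeans(ep$data[nb, , drop = FALSE])
  }
  ep
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over all included channels;
#' excluded channels (typically EOG) are untouched. Idempotent.
#'
#' @param ep An `fpvs_epoch`.
#' @param exclude Channel labels excluded from the average (and left
#'   unchanged).
#' @return The re-referenced epoch.
#' @export
rereference_common_average <- function(ep, exclude = character(0)) {
  incl <- setdiff(ep$labels, exclude)
  if (length(incl) < 2) return(ep)  # single-channel (SEEG) path: identity
  avg <- colMeans(ep$data[incl, , drop = FALSE])
  ep$data[incl, ] <- sweep(ep$data[incl, , drop = FALSE], 2, avg)
  ep
}
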