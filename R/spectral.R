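#' Crop an epoch to an integer number of cycles of a target frequency
#'
#' Starting `t_start` seconds after stimulation onset (default: the end of
#' the contrast fade-in), keeps `floor(available * f_target)` full cycles
#' of `f_target`, so that `f_target` and all its harmonics fall on exact
#' FFT bins of the cropped segment. With the default 60-s stimulation and
#' the 4/7 Hz oddball rate this yields 34 cycles = 59.5 s.
#'
#' @param ep An `fpvs_epoch` (with `t0` relative to stimulation onset).
#' @param f_target Frequency whose cycles define the crop (Hz).
#' @param t_start Crop start in seconds after stimulation onset.
#' @param available Usable duration in seconds from `t_start`; defaults to
#'   the epoch's recorded full-contrast stimulation span
#'   (`meta$seq_duration`) and otherwise to the remaining epoch length.
#' @return The cropped `fpvs_epoch` (`t0 = t_start`), with the cycle count
#'   in `meta$n_cycles`.
#' @export
crop_integer_cycles <- function(ep, f_target, t_start = 2, available = NULL) {
  if (is.null(available)) {
    available <- if (!is.null(ep$meta$seq_duration)) ep$meta$seq_duration
                 else epoch_duration(ep) + ep$t0 - t_start
  }
  available <- min(available, epoch_duration(ep) + ep$t0 - t_start)
  n_cycles <- floor(available * f_target + 1e-9)
  if (n_cycles < 1) stop("epoch does not cover one full cycle of f_target")
  dur <- n_cycles / f_target
  n_samp <- round(dur * ep$fs)
  if (abs(n_samp - dur * ep$fs) > 1e-6)
    stop("crop duration is not an integer number of samples at this fs")
  first <- as.integer(round((t_start - ep$t0) * ep$fs)) + 1L
  if (first < 1L || first + n_samp - 1L > ncol(ep$data))
    stop("crop window exceeds the epoch")
  out <- epoch(ep$data[, first:(first + n_samp - 1L), drop = FALSE],
               ep$fs, t0 = t_start, labels = ep$labels, meta = ep$meta)
  out$meta$n_cycles <- n_cycles
  out$meta$f_target <- f_target
  out
}

#' Average epochs in the time domain
#'
#' Per-sample arithmetic mean across epochs of identical shape, sampling
#' rate and channel set; improves signal-to-noise ratio before the FFT.
#'
#' @param epochs List of `fpvs_epoch` objects.
#' @return The averaged `fpvs_epoch`.
#' @export
average_epochs <- function(epochs) {
  if (length(epochs) == 0) stop("no epochs to average")
  ref <- epochs[[1]]
  for (ep in epochs[-1]) {
    if (!identical(dim(ep$data), dim(ref$data)) || ep$fs != ref$fs ||
        !identical(ep$labels, ref$labels))
      stop("epochs differ in shape, rate or channels")
  }
  acc <- Reduce(`+`, lapply(epochs, `[[`, "data"))
  out <- ref
  out$data <- acc / length(epochs)
  out$meta$n_averaged <- length(epochs)
  out
}

#' Single-sided amplitude spectrum
#'
#' FFT amplitude spectrum calibrated as `2 * |X_b| / N` for bins `b > 0`
#' (and `|X_0| / N` at DC), so that a unit-amplitude sinusoid at an exact
#' bin frequency reads 1.0. No window or detrending is applied: spectra
#' are meant to be computed on integer-cycle crops, where the frequencies
#' of interest are leakage-free by construction.
#'
#' @param ep An `fpvs_epoch`.
#' @return An object of class `fpvs_spectrum`: `amps` (channels x bins,
#'   muV), `df` (bin width in Hz), `n_time_samples`, `labels`,
#'   `normalization`.
#' @export
amplitude_spectrum <- function(ep) {
  if (!all(is.finite(ep$data))) stop("non-finite samples in epoch")
  n <- ncol(ep$data)
  n_bins <- n %/% 2L + 1L
  amps <- t(apply(ep$data, 1, function(ch) {
    a <- Mod(stats::fft(ch))[1:n_bins] / n
    a[2:n_bins] <- 2 * a[2:n_bins]
    a
  }))
  if (nrow(ep$data) == 1L) amps <- matrix(amps, nrow = 1L)
  rownames(amps) <- ep$labels
  structure(list(amps = amps, df = ep$fs / n, n_time_samples = n,
                 labels = ep$labels, normalization = "2/N single-sided",
                 meta = ep$meta),
            class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum> %d channels x %d bins, df = %.6g Hz (%s)\n",
              nrow(x$amps), ncol(x$amps), x$df, x$normalization))
  invisible(x)
}

#' Map a frequency to a spectrum bin
#'
#' @param spec An `fpvs_spectrum` (or any object with `df`).
#' @param f Frequency in Hz (0 to Nyquist).
#' @param require_exact Error unless `f` lies on a bin center to within
#'   `df * 1e-6`.
#' @return 1-based bin index (DC = 1).
#' @export
freq_to_bin <- function(spec, f, require_exact = FALSE) {
  if (f < 0) stop("negative frequency")
  b <- f / spec$df
  if (require_exact && abs(b - round(b)) > 1e-6)
    stop(sprintf("frequency %.6g Hz does not fall on an exact bin (df = %.6g Hz)",
                 f, spec$df))
  idx <- as.integer(round(b)) + 1L
  if (idx > ncol(spec$amps)) stop("frequency above Nyquist")
  idx
}

#' Frequencies of spectrum bins
#' @param spec An `fpvs_spectrum`.
#' @return Numeric vector of bin-center frequencies in Hz.
#' @export
bin_freqs <- function(spec) (seq_len(ncol(spec$amps)) - 1L) * spec$df
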