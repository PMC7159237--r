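#' Condition-wise amplitude spectra via the scalp preprocessing chain
#'
#' Applies the full scalp path to a recording: block alignment, zero-phase
#' 0.1-100 Hz Butterworth band-pass, multi-notch at the mains harmonics,
#' downsampling to 256 Hz, epoching (-2 to 66 s around each sequence
#' onset), EOG regression on epochs whose blink rate exceeds 0.15/s,
#' optional bad-channel interpolation, common-average re-reference,
#' integer-cycle cropping from the end of the fade-in, time-domain
#' averaging per condition, and FFT.
#'
#' @param rec An `fpvs_recording` with sequence-onset events (codes =
#'   condition names) and, optionally, `meta$block_starts` and
#'   `meta$eog_channels`.
#' @param f_target Oddball frequency whose cycles define the crop (Hz).
#' @param conditions Conditions to analyse (default: unique event codes).
#' @param target_fs Analysis rate after downsampling (Hz).
#' @param t_crop Crop start after stimulation onset (s; the fade-in
#'   length).
#' @param bad_channels,neighbors Optional interpolation arguments.
#' @param notch_n Number of notched mains harmonics.
#' @return Named list of `fpvs_spectrum` objects, one per condition, plus
#'   a `log` attribute describing the applied chain.
#' @export
scalp_spectra <- function(rec, f_target = 4 / 7, conditions = NULL,
                          target_fs = 256, t_crop = 2,
                          bad_channels = character(0), neighbors = list(),
                          notch_n = 4) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  if (!is.null(rec$meta$block_starts) && length(rec$meta$block_starts) > 1) {
    rec <- align_blocks(rec, rec$meta$block_starts[-1])
    note("align_blocks: %d boundaries", length(rec$meta$block_starts) - 1)
  }
  # band-pass and multi-notch composed into one zero-phase pass
  # (identical to bandpass_filter followed by notch_filter)
  nyq <- rec$fs / 2
  hp <- signal::butter(4, 0.1 / nyq, "high")
  lp <- signal::butter(4, 100 / nyq, "low")
  notches <- lapply(50 * seq_len(notch_n), function(f0)
    signal::butter(2, c(f0 - 0.25, f0 + 0.25) / nyq, "stop"))
  rec$data <- zero_phase_apply(rec$data, rec$fs, function(f) {
    g <- iir_mag2(hp, f, rec$fs) * iir_mag2(lp, f, rec$fs)
    for (flt in notches) g <- g * iir_mag2(flt, f, rec$fs)
    g
  })
  note("bandpass 0.1-100 Hz order-4 zero-phase Butterworth")
  note("multi-notch 50 Hz x %d, width 0.5 Hz", notch_n)
  rec <- resample_recording(rec, target_fs)
  note("resampled to %g Hz", target_fs)
  eog <- rec$meta$eog_channels
  epochs <- segment_epochs(rec, t_min = -2,
                           t_max = 2 * (rec$meta$fade_duration %||% 2) +
                                   (rec$meta$seq_duration %||% 60) + 2)
  note("%d epochs", length(epochs))
  if (length(eog) >= 1) {
    epochs <- lapply(epochs, function(ep) {
      br <- blink_rate(ep, eog)
      if (br$flagged) ep <- regress_out_eog(ep, eog)
      ep
    })
  }
  if (length(bad_channels))
    epochs <- lapply(epochs, interpolate_channels, bad = bad_channels,
                     neighbors = neighbors)
  epochs <- lapply(epochs, rereference_common_average, exclude = eog)
  if (is.null(conditions))
    conditions <- unique(vapply(epochs, function(e) e$meta$condition, character(1)))
  out <- lapply(stats::setNames(conditions, conditions), function(cond) {
    eps <- Filter(function(e) identical(e$meta$condition, cond), epochs)
    if (length(eps) == 0) stop("no epochs for condition ", cond)
    eps <- lapply(eps, crop_integer_cycles, f_target = f_target,
                  t_start = t_crop)
    amplitude_spectrum(average_epochs(eps))
  })
  attr(out, "log") <- log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition-wise amplitude spectra via the SEEG minimal path
#'
#' No filtering, resampling or re-referencing: epochs are extracted at the
#' native rate, cropped to an integer number of oddball cycles after the
#' fade-in, averaged per condition in the time domain, and transformed
#' into amplitude spectra.
#'
#' @inheritParams scalp_spectra
#' @return Named list of `fpvs_spectrum` objects per condition.
#' @export
seeg_spectra <- function(rec, f_target = 4 / 7, conditions = NULL,
                         t_crop = 2) {
  epochs <- segment_epochs(rec, t_min = -2,
                           t_max = 2 * (rec$meta$fade_duration %||% 2) +
                                   (rec$meta$seq_duration %||% 60) + 2)
  if (is.null(conditions))
    conditions <- unique(vapply(epochs, function(e) e$meta$condition, character(1)))
  lapply(stats::setNames(conditions, conditions), function(cond) {
    eps <- Filter(function(e) identical(e$meta$condition, cond), epochs)
    if (length(eps) == 0) stop("no epochs for condition ", cond)
    eps <- lapply(eps, crop_integer_cycles, f_target = f_target,
                  t_start = t_crop)
    amplitude_spectrum(average_epochs(eps))
  })
}

#' ROI quantification and integration fraction for a three-condition session
#'
#' Quantifies each condition's pooled-harmonic response per ROI
#' ([oddball_bc_sum()], scalp order: chunks summed, then
#' baseline-corrected), forms the unimodal sum by adding the uncorrected
#' FO and NO spectra and correcting the result, and computes the
#' crossmodal integration fraction `100 * (1 - (FO + NO) / FN)` per ROI.
#'
#' @param spectra Named list with elements `FN`, `FO`, `NO`
#'   (`fpvs_spectrum`).
#' @param rois Named list of channel-label vectors (default: the
#'   5-electrode occipito-temporal sets).
#' @param f_target Oddball frequency (Hz).
#' @param harmonics Multiples to sum.
#' @return Data frame: one row per ROI with the three condition
#'   amplitudes (muV), the corrected summed-control amplitude
#'   `fo_plus_no`, and the integration fraction in percent.
#' @export
roi_integration <- function(spectra, rois = scalp_rois("exp2"),
                            f_target = 4 / 7, harmonics = 1:6) {
  bc <- lapply(spectra[c("FN", "FO", "NO")], oddball_bc_sum,
               f_target = f_target, harmonics = harmonics, variant = "scalp")
  bc$sum <- oddball_bc_sum(spectra_add(spectra$FO, spectra$NO), f_target,
                           harmonics, "scalp")
  rows <- lapply(names(rois), function(rn) {
    amp <- vapply(bc, function(v) {
      miss <- setdiff(rois[[rn]], names(v))
      if (length(miss)) stop("unknown ROI channel(s): ",
                             paste(miss, collapse = ", "))
      mean(v[rois[[rn]]])
    }, numeric(1))
    data.frame(roi = rn, fn = amp["FN"], fo = amp["FO"], no = amp["NO"],
               fo_plus_no = amp["sum"],
               integration_pct = 100 * (1 - amp["sum"] / amp["FN"]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify every contact of an SEEG session
#'
#' Runs [seeg_spectra()] and [classify_contact()] per channel.
#'
#' @param rec Single- or multi-channel SEEG `fpvs_recording` with FN, FO
#'   and NO sequence events.
#' @param f_target Oddball frequency (Hz).
#' @param harmonics Multiples to pool.
#' @param z_sig,z_diff Significance cutoffs.
#' @return Data frame: one row per contact with the label and component
#'   z-scores; full classification objects in the `classifications`
#'   attribute.
#' @export
classify_seeg_recording <- function(rec, f_target = 4 / 7, harmonics = 1:6,
                                    z_sig = 3.1, z_diff = 1.65) {
  spectra <- seeg_spectra(rec, f_target)
  need <- c("FN", "FO", "NO")
  if (!all(need %in% names(spectra)))
    stop("recording lacks conditions: ",
         paste(setdiff(need, names(spectra)), collapse = ", "))
  one_channel <- function(spec, ch) {
    spec$amps <- spec$amps[ch, , drop = FALSE]
    spec$labels <- spec$labels[ch]
    spec
  }
  cls <- lapply(seq_along(rec$labels), function(ch)
    classify_contact(one_channel(spectra$FN, ch), one_channel(spectra$FO, ch),
                     one_channel(spectra$NO, ch), f_target, harmonics,
                     z_sig, z_diff))
  rows <- lapply(seq_along(cls), function(i) {
    x <- cls[[i]]
    z <- vapply(x$detections, function(d) d$z[1], numeric(1))
    data.frame(contact = rec$labels[i], label = x$label,
               z_fn = z["FN"], z_fo = z["FO"], z_no = z["NO"],
               z_diff = if (is.null(x$subtraction)) NA_real_
                        else x$subtraction$z[1],
               bc_sum_fn = x$detections$FN$bc_sum[1],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "classifications") <- cls
  out
}

#' Run a configured analysis end to end
#'
#' Declarative front end tying the modules together. `config` is a list
#' (or the path of a YAML file with the same structure) with fields:
#' `analysis` (`"scalp"` or `"seeg"`), `seed`, optional `simulate` block
#' (response/noise parameters for the built-in simulator; without it,
#' `input` must name a recording file readable by [read_recording()]),
#' and optional `out_dir` for delimited-text exports. Re-running with the
#' same config and seed reproduces all outputs exactly.
#'
#' @param config List or YAML path.
#' @return A result bundle: `spectra`, and `roi` (scalp) or
#'   `classification` (SEEG), plus the resolved config and a log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::yaml.load_file(config)
  }
  analysis <- match.arg(config$analysis, c("scalp", "seeg"))
  seed <- as.integer(config$seed %||% 1L)
  sim <- config$simulate
  if (!is.null(sim)) {
    noise <- do.call(noise_spec, sim$noise %||% list())
    if (analysis == "seeg") {
      sess <- simulate_seeg_contact(sim$profile %||% "pure_FN",
                                    amp = sim$amp %||% 1,
                                    noise = noise,
                                    n_sequences_per_condition = sim$n_sequences %||% 2,
                                    seed = seed)
    } else {
      resp <- do.call(response_spec, sim$response %||% list())
      sess <- simulate_session(spec = resp, noise = noise,
                               n_sequences_per_condition = sim$n_sequences %||% 2,
                               seed = seed)
    }
    rec <- sess$recording
  } else {
    if (is.null(config$input)) stop("config needs either a simulate block or an input path")
    rec <- read_recording(config$input)
  }
  if (analysis == "scalp") {
    rois <- config$rois %||% scalp_rois("exp2")
    for (rn in names(rois)) {
      miss <- setdiff(rois[[rn]], rec$labels)
      if (length(miss))
        stop("unknown ROI channel(s) in ", rn, ": ", paste(miss, collapse = ", "))
    }
    spectra <- scalp_spectra(rec)
    roi <- roi_integration(spectra, rois)
    out <- list(analysis = "scalp", spectra = spectra, roi = roi,
                config = config, log = attr(spectra, "log"))
  } else {
    classification <- classify_seeg_recording(rec)
    out <- list(analysis = "seeg", spectra = seeg_spectra(rec),
                classification = classification, config = config)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in names(out$spectra))
      write_spectrum_table(out$spectra[[cond]],
                           file.path(config$out_dir,
                                     sprintf("spectrum_%s.tsv", cond)))
    tab <- if (analysis == "scalp") out$roi else out$classification
    utils::write.table(tab, file.path(config$out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Estimate the local noise floor of a simulated null contact
#'
#' Median, over seeds, of the local noise standard deviation of the summed
#' chunk at the oddball frequency for response-free SEEG contacts; used to
#' express simulated response amplitudes in noise-SD units.
#'
#' @param noise An [noise_spec()].
#' @param n_sequences_per_condition Sequences per condition.
#' @param seeds Integer seeds to average over.
#' @return Median noise SD in muV.
#' @export
estimate_contact_noise_sd <- function(noise = noise_spec(),
                                      n_sequences_per_condition = 2,
                                      seeds = 1:5) {
  sds <- vapply(seeds, function(s) {
    sess <- simulate_seeg_contact("null", amp = 0, noise = noise,
                                  n_sequences_per_condition = n_sequences_per_condition,
                                  seed = s)
    spec <- seeg_spectra(sess$recording)$FN
    det <- detect_response(spec, 4 / 7, 1:6, "seeg")
    det$noise_sd[1]
  }, numeric(1))
  stats::median(sds)
}
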