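#' Spectrum-neighborhood specification
#'
#' Defines which surrounding bins form the local noise estimate of a bin
#' of interest: `n_per_side` bins on each side, minus `skip_adjacent` bins
#' immediately next to the center on each side (guarding against residual
#' spectral leakage), optionally minus the single maximum and single
#' minimum amplitude bin among the remainder (guarding against signal
#' projected into neighbors).
#'
#' @param n_per_side Bins considered on each side of the center.
#' @param skip_adjacent Bins immediately adjacent to the center excluded
#'   per side.
#' @param drop_extrema Drop the max and min amplitude bins among the
#'   remaining neighbors (ties: lowest index).
#' @return An object of class `fpvs_nb_spec`.
#' @export
neighborhood_spec <- function(n_per_side, skip_adjacent = 0,
                              drop_extrema = FALSE) {
  if (n_per_side <= skip_adjacent)
    stop("n_per_side must exceed skip_adjacent")
  n_used <- 2 * (n_per_side - skip_adjacent) - if (drop_extrema) 2 else 0
  if (n_used < 4) stop("fewer than 4 neighborhood bins would remain")
  structure(list(n_per_side = n_per_side, skip_adjacent = skip_adjacent,
                 drop_extrema = drop_extrema, n_used = n_used),
            class = "fpvs_nb_spec")
}

#' Published neighborhood presets
#'
#' * `scalp_baseline`: 12 bins/side, skip 1 adjacent/side, drop the max
#'   and min of the remaining 22 — 20 bins used (baseline subtraction,
#'   scalp).
#' * `scalp_z`: 11 bins/side, no exclusions — 22 bins (Z-scores, scalp).
#' * `seeg_baseline` and `seeg_z`: 12 bins/side, skip 1 adjacent/side, no
#'   extrema exclusion — 22 bins (SEEG baseline subtraction and Z-scores).
#'
#' @param name Preset name.
#' @return An `fpvs_nb_spec`.
#' @export
neighborhood_preset <- function(name = c("scalp_baseline", "scalp_z",
                                         "seeg_baseline", "seeg_z")) {
  switch(match.arg(name),
    scalp_baseline = neighborhood_spec(12, 1, TRUE),
    scalp_z        = neighborhood_spec(11, 0, FALSE),
    seeg_baseline  = neighborhood_spec(12, 1, FALSE),
    seeg_z         = neighborhood_spec(12, 1, FALSE))
}

#' Select the neighborhood bins of a center bin
#'
#' @param center 1-based index of the bin of interest.
#' @param nb An [neighborhood_spec()].
#' @param amps Numeric vector: one spectrum row.
#' @return Integer indices of the selected neighbor bins.
#' @export
neighborhood <- function(center, nb, amps) {
  lo <- center - nb$n_per_side
  hi <- center + nb$n_per_side
  if (lo < 1L || hi > length(amps))
    stop("center bin too close to the spectrum edge for this neighborhood")
  idx <- c(lo:(center - nb$skip_adjacent - 1L),
           (center + nb$skip_adjacent + 1L):hi)
  if (nb$drop_extrema) {
    vals <- amps[idx]
    idx <- idx[-c(which.max(vals), {
      i_min <- which.min(vals)
      # guard: if max and min coincide (flat), drop two distinct bins
      if (i_min == which.max(vals)) i_min + 1L else i_min
    })]
  }
  idx
}

#' Baseline-subtracted amplitudes
#'
#' For every interior bin, amplitude minus the mean amplitude of its
#' neighborhood; estimates the response above the local noise floor in
#' muV (values may be negative). Edge bins without a full neighborhood
#' are `NA`.
#'
#' @param spec An `fpvs_spectrum`.
#' @param nb An [neighborhood_spec()] (default: the scalp baseline
#'   preset).
#' @return An object of class `fpvs_bc`: signed `values` on the same
#'   channel x bin grid, plus `df` and `labels`.
#' @export
baseline_correct <- function(spec, nb = neighborhood_preset("scalp_baseline")) {
  amps <- spec$amps
  n_bins <- ncol(amps)
  values <- matrix(NA_real_, nrow(amps), n_bins, dimnames = dimnames(amps))
  rng <- (nb$n_per_side + 1L):(n_bins - nb$n_per_side)
  for (ch in seq_len(nrow(amps))) {
    row <- amps[ch, ]
    for (b in rng)
      values[ch, b] <- row[b] - mean(row[neighborhood(b, nb, row)])
  }
  structure(list(values = values, df = spec$df, labels = spec$labels,
                 nb = nb), class = "fpvs_bc")
}

#' Local-noise Z-score of a bin
#'
#' `z = (amp(bin) - mean(neighborhood)) / sd(neighborhood)` with the
#' sample (n-1) standard deviation; the detection statistic referenced to
#' a standard normal with one-tailed cutoffs 1.65 (p < 0.05) and 3.1
#' (p < 0.001).
#'
#' @param x An `fpvs_spectrum` (returns one z per channel) or a numeric
#'   vector (one spectrum row).
#' @param bin 1-based center bin index.
#' @param nb An [neighborhood_spec()].
#' @return Named numeric vector of z-scores (or a scalar for a vector
#'   input).
#' @export
local_z <- function(x, bin, nb = neighborhood_preset("scalp_z")) {
  rows <- if (inherits(x, "fpvs_spectrum")) x$amps else rbind(x)
  z <- apply(rows, 1, function(row) {
    idx <- neighborhood(bin, nb, row)
    s <- stats::sd(row[idx])
    if (s == 0) stop("zero neighborhood standard deviation (degenerate input)")
    (row[bin] - mean(row[idx])) / s
  })
  if (inherits(x, "fpvs_spectrum")) stats::setNames(z, x$labels) else unname(z)
}

#' Local noise standard deviation around a bin
#'
#' Sample standard deviation (muV) of the neighborhood amplitudes; the
#' denominator of the local Z-score and the noise measure used to compare
#' recording sites.
#'
#' @inheritParams local_z
#' @return Named numeric vector (or scalar for a vector input).
#' @export
noise_sd <- function(x, bin, nb = neighborhood_preset("scalp_z")) {
  rows <- if (inherits(x, "fpvs_spectrum")) x$amps else rbind(x)
  s <- apply(rows, 1, function(row) stats::sd(row[neighborhood(bin, nb, row)]))
  if (inherits(x, "fpvs_spectrum")) stats::setNames(s, x$labels) else unname(s)
}

#' Chunk-and-sum harmonic pooling
#'
#' Extracts, for each requested harmonic `m` of `f_target`, a chunk of
#' `2 * half_width_bins + 1` bins centered on the harmonic bin, and sums
#' the chunks element-wise, pooling response energy across harmonics
#' before detection. Harmonics coinciding with a harmonic of `base_freq`
#' are rejected (their bins carry the general visual response, not the
#' oddball response).
#'
#' @param spec An `fpvs_spectrum` (or signed spectrum from
#'   [spectra_subtract()]).
#' @param f_target Fundamental of the harmonic series (Hz), e.g. the
#'   4/7 Hz oddball rate.
#' @param harmonics Integer multiples to pool (default 1..6).
#' @param half_width_bins Bins on each side of the harmonic bin.
#' @param base_freq If non-NULL, error when a pooled harmonic coincides
#'   with a multiple of this frequency.
#' @return An object of class `fpvs_chunk`: `values` (channels x
#'   `2 * half_width_bins + 1`), `center` (index of the harmonic
#'   position), `harmonics`, `df`.
#' @export
chunk_sum <- function(spec, f_target, harmonics = 1:6, half_width_bins = 15,
                      base_freq = NULL) {
  if (length(harmonics) == 0) stop("harmonics must be non-empty")
  if (!is.null(base_freq)) {
    ratio <- harmonics * f_target / base_freq
    hit <- abs(ratio - round(ratio)) < 1e-9 & ratio > 1e-9
    if (any(hit))
      stop("harmonic multiple(s) ", paste(harmonics[hit], collapse = ", "),
           " coincide with a base-rate harmonic")
  }
  n_bins <- ncol(spec$amps)
  width <- 2L * half_width_bins + 1L
  acc <- matrix(0, nrow(spec$amps), width)
  for (m in harmonics) {
    b <- freq_to_bin(spec, m * f_target, require_exact = TRUE)
    if (b - half_width_bins < 1L || b + half_width_bins > n_bins)
      stop(sprintf("harmonic %d lacks a %d-bin margin in the spectrum", m,
                   half_width_bins))
    acc <- acc + spec$amps[, (b - half_width_bins):(b + half_width_bins),
                           drop = FALSE]
  }
  rownames(acc) <- spec$labels
  structure(list(values = acc, center = half_width_bins + 1L,
                 harmonics = harmonics, half_width_bins = half_width_bins,
                 df = spec$df, labels = spec$labels),
            class = "fpvs_chunk")
}

variant_presets <- function(variant) {
  switch(variant,
    scalp = list(z = neighborhood_preset("scalp_z"),
                 baseline = neighborhood_preset("scalp_baseline"),
                 z_threshold = 1.65),
    seeg  = list(z = neighborhood_preset("seeg_z"),
                 baseline = neighborhood_preset("seeg_baseline"),
                 z_threshold = 3.1),
    stop("unknown variant: ", variant))
}

seeg_half_width <- function(spec, segment_hz = 0.8) {
  max(13L, as.integer(round(segment_hz / 2 / spec$df)))
}

#' Baseline-corrected summed oddball amplitude
#'
#' Quantifies the response pooled over harmonics, in muV. Two published
#' orders are implemented: the scalp order sums the per-harmonic chunks
#' first and baseline-corrects the summed chunk at its center; the SEEG
#' order baseline-corrects the full spectrum and sums the corrected
#' amplitudes at the harmonic bins. The orders agree exactly when no
#' extrema are excluded from the baseline neighborhood.
#'
#' @param spec An `fpvs_spectrum`.
#' @param f_target Fundamental frequency (Hz).
#' @param harmonics Multiples to pool.
#' @param variant `"scalp"` (sum chunks, then correct) or `"seeg"`
#'   (correct, then sum).
#' @param half_width_bins Chunk half width (scalp default 15; SEEG default
#'   spans 0.8 Hz).
#' @param base_freq Guard frequency passed to [chunk_sum()].
#' @return Named numeric vector: one summed baseline-corrected amplitude
#'   per channel (muV).
#' @export
oddball_bc_sum <- function(spec, f_target, harmonics = 1:6,
                           variant = c("scalp", "seeg"),
                           half_width_bins = NULL, base_freq = 4) {
  variant <- match.arg(variant)
  pr <- variant_presets(variant)
  if (variant == "scalp") {
    if (is.null(half_width_bins)) half_width_bins <- 15L
    ck <- chunk_sum(spec, f_target, harmonics, half_width_bins, base_freq)
    out <- apply(ck$values, 1, function(row) {
      row[ck$center] - mean(row[neighborhood(ck$center, pr$baseline, row)])
    })
  } else {
    bins <- vapply(harmonics, function(m)
      freq_to_bin(spec, m * f_target, require_exact = TRUE), integer(1))
    ratio <- harmonics * f_target / base_freq
    if (any(abs(ratio - round(ratio)) < 1e-9 & ratio > 1e-9))
      stop("harmonic coincides with a base-rate harmonic")
    # baseline-correct only at the harmonic bins (equals the full
    # baseline_correct grid restricted to those bins)
    out <- apply(spec$amps, 1, function(row) {
      sum(vapply(bins, function(b)
        row[b] - mean(row[neighborhood(b, pr$baseline, row)]), numeric(1)))
    })
  }
  stats::setNames(out, spec$labels)
}

#' Detect a periodic response pooled over harmonics
#'
#' The detection statistic of the frequency-tagging approach: per-harmonic
#' chunks of the amplitude spectrum are summed ([chunk_sum()]) and the
#' summed chunk is transformed into a local-noise Z-score at its center;
#' the response size is the baseline-corrected summed amplitude
#' ([oddball_bc_sum()]). A channel is significant when `z > z_threshold`
#' (one-tailed).
#'
#' @param spec An `fpvs_spectrum` (raw or signed subtraction spectrum).
#' @param f_target Fundamental frequency (Hz).
#' @param harmonics Multiples to pool (default 1..6).
#' @param variant `"scalp"` (31-bin chunks, Z over 22 bins with no
#'   exclusions, threshold 1.65) or `"seeg"` (0.8-Hz chunks, Z over 22
#'   bins skipping adjacents, threshold 3.1).
#' @param z_threshold Override of the variant's one-tailed cutoff.
#' @param half_width_bins Override of the variant's chunk half width.
#' @param base_freq Base stimulation rate guarding harmonic collisions.
#' @return A data frame (class `fpvs_detection`), one row per channel:
#'   `channel`, `z`, `bc_sum`, `noise_sd`, `threshold`, `significant`,
#'   plus the harmonics and variant as attributes.
#' @export
detect_response <- function(spec, f_target, harmonics = 1:6,
                            variant = c("scalp", "seeg"),
                            z_threshold = NULL, half_width_bins = NULL,
                            base_freq = 4) {
  variant <- match.arg(variant)
  pr <- variant_presets(variant)
  if (is.null(z_threshold)) z_threshold <- pr$z_threshold
  if (is.null(half_width_bins))
    half_width_bins <- if (variant == "scalp") 15L else seeg_half_width(spec)
  ck <- chunk_sum(spec, f_target, harmonics, half_width_bins, base_freq)
  z <- apply(ck$values, 1, function(row) {
    idx <- neighborhood(ck$center, pr$z, row)
    s <- stats::sd(row[idx])
    if (s == 0) stop("zero neighborhood standard deviation (degenerate input)")
    (row[ck$center] - mean(row[idx])) / s
  })
  nsd <- apply(ck$values, 1, function(row)
    stats::sd(row[neighborhood(ck$center, pr$z, row)]))
  bc <- oddball_bc_sum(spec, f_target, harmonics, variant, half_width_bins,
                       base_freq)
  out <- data.frame(channel = spec$labels, z = unname(z),
                    bc_sum = unname(bc), noise_sd = unname(nsd),
                    threshold = z_threshold,
                    significant = unname(z) > z_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "harmonics") <- harmonics
  attr(out, "variant") <- variant
  attr(out, "half_width_bins") <- half_width_bins
  class(out) <- c("fpvs_detection", class(out))
  out
}

check_same_grid <- function(a, b) {
  if (abs(a$df - b$df) > 1e-12 || !identical(dim(a$amps), dim(b$amps)) ||
      !identical(a$labels, b$labels))
    stop("spectra are not on the same grid")
}

#' Element-wise algebra on amplitude spectra
#'
#' Condition algebra is performed on raw (uncorrected) amplitudes, and
#' baseline correction or Z-scoring is applied afterwards to the result:
#' `spectra_add` forms the unimodal sum FO + NO, and `spectra_subtract`
#' the super-additivity contrast FN - (FO + NO), whose values may be
#' negative.
#'
#' @param a,b `fpvs_spectrum` objects on an identical grid.
#' @return An `fpvs_spectrum`; subtraction results are tagged
#'   `normalization = "signed difference"`.
#' @export
spectra_add <- function(a, b) {
  check_same_grid(a, b)
  a$amps <- a$amps + b$amps
  a
}

#' @rdname spectra_add
#' @export
spectra_subtract <- function(a, b) {
  check_same_grid(a, b)
  a$amps <- a$amps - b$amps
  a$normalization <- "signed difference"
  a
}

#' Classify an SEEG contact from its three condition spectra
#'
#' Per-condition detection at the conservative SEEG threshold
#' (`z > z_sig`, default 3.1, p < 0.001 one-tailed); when the Face Name
#' condition alone is significant, the super-additivity contrast
#' FN - (FO + NO) is tested at `z > z_diff` (default 1.65, p < 0.05
#' one-tailed) and decides between a pure and a non-pure crossmodal
#' response. Other significance patterns map to unimodal and mixed
#' labels.
#'
#' @param fn,fo,no Single-channel `fpvs_spectrum` objects on a common
#'   grid (Face Name, Face Only, Name Only).
#' @param f_target Oddball frequency (Hz).
#' @param harmonics Multiples to pool.
#' @param z_sig Per-condition significance cutoff.
#' @param z_diff Subtraction-contrast cutoff.
#' @param base_freq Base stimulation rate.
#' @return An object of class `fpvs_contact_classification`: `label` (one
#'   of `pure_FN`, `nonpure_FN`, `unimodal_face`, `unimodal_name`,
#'   `FN_and_face`, `FN_and_name`, `mixed_all`, `none`), per-condition
#'   `detections`, and the `subtraction` detection (NULL unless computed).
#' @export
classify_contact <- function(fn, fo, no, f_target = 4 / 7, harmonics = 1:6,
                             z_sig = 3.1, z_diff = 1.65, base_freq = 4) {
  if (nrow(fn$amps) != 1L) stop("classify_contact expects single-channel spectra")
  det <- list(
    FN = detect_response(fn, f_target, harmonics, "seeg", z_sig,
                         base_freq = base_freq),
    FO = detect_response(fo, f_target, harmonics, "seeg", z_sig,
                         base_freq = base_freq),
    NO = detect_response(no, f_target, harmonics, "seeg", z_sig,
                         base_freq = base_freq))
  s <- vapply(det, function(d) d$significant[1], logical(1))
  sub_det <- NULL
  label <- if (s["FN"] && !s["FO"] && !s["NO"]) {
    diff_spec <- spectra_subtract(fn, spectra_add(fo, no))
    sub_det <- detect_response(diff_spec, f_target, harmonics, "seeg",
                               z_diff, base_freq = base_freq)
    if (sub_det$significant[1]) "pure_FN" else "nonpure_FN"
  } else if (!s["FN"] && s["FO"] && !s["NO"]) "unimodal_face"
    else if (!s["FN"] && !s["FO"] && s["NO"]) "unimodal_name"
    else if (s["FN"] && s["FO"] && !s["NO"]) "FN_and_face"
    else if (s["FN"] && !s["FO"] && s["NO"]) "FN_and_name"
    else if (s["FN"] && s["FO"] && s["NO"]) "mixed_all"
    else if (!s["FN"] && s["FO"] && s["NO"]) "mixed_all"
    else "none"
  structure(list(label = label, detections = det, subtraction = sub_det),
            class = "fpvs_contact_classification")
}

#' @export
print.fpvs_contact_classification <- function(x, ...) {
  z <- vapply(x$detections, function(d) d$z[1], numeric(1))
  cat(sprintf("<contact> label = %s | z(FN) = %.2f, z(FO) = %.2f, z(NO) = %.2f",
              x$label, z["FN"], z["FO"], z["NO"]))
  if (!is.null(x$subtraction))
    cat(sprintf(", z(FN-(FO+NO)) = %.2f", x$subtraction$z[1]))
  cat("\n")
  invisible(x)
}

#' Determine the range of significant harmonics from a grand average
#'
#' Computes the local Z at every harmonic bin of the channel-averaged
#' spectrum and returns the contiguous range `1..M`, where `M` is the
#' largest multiple not exceeding `max_multiple` whose Z exceeds the
#' cutoff; multiples coinciding with base-rate harmonics are excluded
#' from both testing and the returned set.
#'
#' @param spec An `fpvs_spectrum` (channels are averaged).
#' @param f_target Fundamental (Hz).
#' @param max_multiple Largest multiple considered.
#' @param variant Z preset to use (`"scalp"` or `"seeg"`).
#' @param z_threshold Significance cutoff (default 1.65).
#' @param base_freq If non-NULL, multiples coinciding with its harmonics
#'   are skipped.
#' @return Integer vector of multiples (possibly empty).
#' @export
select_harmonic_range <- function(spec, f_target, max_multiple = 12,
                                  variant = c("scalp", "seeg"),
                                  z_threshold = 1.65, base_freq = NULL) {
  variant <- match.arg(variant)
  pr <- variant_presets(variant)
  row <- colMeans(spec$amps)
  keep <- seq_len(max_multiple)
  if (!is.null(base_freq)) {
    ratio <- keep * f_target / base_freq
    keep <- keep[!(abs(ratio - round(ratio)) < 1e-9 & ratio > 1e-9)]
  }
  zs <- vapply(keep, function(m) {
    b <- freq_to_bin(spec, m * f_target, require_exact = TRUE)
    local_z(row, b, pr$z)
  }, numeric(1))
  sig <- keep[zs > z_threshold]
  if (length(sig) == 0) return(integer(0))
  M <- max(sig)
  keep[keep <= M]
}

#' Published occipito-temporal ROI electrode sets
#'
#' @param version `"exp1"`: 3 electrodes per hemisphere plus a middle
#'   occipital ROI; `"exp2"`: 5 electrodes per hemisphere.
#' @return Named list of channel-label vectors (`LOT`, `ROT`, and `MID`
#'   for `"exp1"`).
#' @export
scalp_rois <- function(version = c("exp2", "exp1")) {
  switch(match.arg(version),
    exp1 = list(LOT = c("P9", "PO9", "PO11"),
                ROT = c("P10", "PO10", "PO12"),
                MID = c("Oz", "OIz", "Iz")),
    exp2 = list(LOT = c("I1", "POI1", "PO11", "PO9", "P9"),
                ROT = c("I2", "POI2", "PO12", "PO10", "P10")))
}

#' Pooled ROI response amplitude
#'
#' Mean over the ROI channels of the per-channel sum of
#' baseline-corrected amplitudes at the harmonic bins (muV).
#'
#' @param bc An `fpvs_bc` from [baseline_correct()].
#' @param roi Channel labels to pool.
#' @param f_target Fundamental (Hz).
#' @param harmonics Multiples to sum.
#' @return Scalar amplitude in muV.
#' @export
roi_quantify <- function(bc, roi, f_target = 4 / 7, harmonics = 1:6) {
  miss <- setdiff(roi, bc$labels)
  if (length(miss)) stop("unknown ROI channel(s): ", paste(miss, collapse = ", "))
  bins <- as.integer(round(harmonics * f_target / bc$df)) + 1L
  if (any(abs(harmonics * f_target / bc$df - (bins - 1L)) > 1e-6))
    stop("harmonic frequencies do not fall on exact bins")
  per_ch <- rowSums(bc$values[roi, bins, drop = FALSE])
  if (anyNA(per_ch)) stop("baseline-corrected values undefined at harmonic bins")
  mean(per_ch)
}

#' Summarise contact classification labels
#'
#' Counts and percentages per label over a set of classified contacts,
#' e.g. the proportion of contacts with a pure crossmodal response within
#' an anatomical region.
#'
#' @param labels Character vector of [classify_contact()] labels (one per
#'   contact).
#' @return Data frame with columns `label`, `n` and `pct` (percent of all
#'   contacts, one decimal as conventionally reported).
#' @export
label_proportions <- function(labels) {
  tab <- table(labels)
  data.frame(label = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(labels), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Crossmodal integration fraction
#'
#' Percentage of the Face Name response not explained by the sum of the
#' unimodal control responses: `100 * (1 - (fo + no) / fn)`. 0 under
#' perfect additivity; may be negative (sub-additivity is reported, not
#' clipped).
#'
#' @param fn_amp,fo_amp,no_amp Response amplitudes in muV (`fn_amp > 0`).
#' @return Percentage.
#' @export
integration_fraction <- function(fn_amp, fo_amp, no_amp) {
  if (fn_amp <= 0) stop("fn_amp must be > 0")
  100 * (1 - (fo_amp + no_amp) / fn_amp)
}
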