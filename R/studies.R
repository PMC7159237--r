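#' Simulate a grand-average-equivalent scalp session
#'
#' A three-condition scalp session dimensioned for quantitative recovery
#' studies. The montage carries the occipito-temporal ROI electrodes with
#' unit response gain and an equal number of fronto-central
#' counter-electrodes with gain -1 (a dipolar field pattern summing to
#' zero across the montage, so common-average referencing does not
#' attenuate the response), plus two vertical EOG channels. The noise
#' level defaults to the residual noise of a group grand average rather
#' than a single noisy subject: responses of a fixed size against a
#' per-bin noise floor about five times lower than the single-session
#' default, with mains line noise, blinks frequent enough to trigger EOG
#' regression, and inter-block DC jumps exercising the full preprocessing
#' chain.
#'
#' The condition composition is parameterized by the crossmodal
#' integration fraction `i`: summed over harmonics, the Face Name oddball
#' response is `fn_total`, the crossmodal component is `i * fn_total`,
#' and the unimodal face and name components split the remainder 4:3
#' (the face response is the larger, as observed at these recording
#' sites).
#'
#' @param seed Integer seed.
#' @param fn_total Summed Face Name oddball amplitude over the six
#'   harmonics (muV).
#' @param integration Crossmodal fraction `i` in `[0, 1)`.
#' @param n_sequences_per_condition Sequences per condition (default 4,
#'   two repetitions of two base identities).
#' @param noise An [noise_spec()]; the default is the grand-average
#'   regime described above.
#' @return An `fpvs_session`; `truth$fn_total` and `truth$integration`
#'   record the injected values.
#' @export
simulate_scalp_study <- function(seed = 1L, fn_total = 0.32,
                                 integration = 0.32,
                                 n_sequences_per_condition = 4,
                                 noise = noise_spec(pink_scale = 2e-4,
                                                    white_scale = 0.2,
                                                    line_amp = 2,
                                                    blink_rate = 0.2,
                                                    blink_amp = 200,
                                                    block_dc_jump = 20)) {
  if (integration < 0 || integration >= 1)
    stop("integration must lie in [0, 1)")
  w <- oddball_harmonic_weights()
  cross_total <- integration * fn_total
  uni_total <- fn_total - cross_total
  spec <- response_spec(face_amps = 4 / 7 * uni_total * w,
                        name_amps = 3 / 7 * uni_total * w,
                        cross_amps = cross_total * w)
  rois <- scalp_rois("exp2")
  roi_ch <- c(rois$LOT, rois$ROT)
  counter_ch <- c("AF3", "AF4", "F1", "F2", "F5", "F6",
                  "FC1", "FC2", "C1", "C2")
  gains <- stats::setNames(c(rep(1, length(roi_ch)),
                             rep(-1, length(counter_ch))),
                           c(roi_ch, counter_ch))
  sess <- simulate_session(spec = spec, noise = noise,
                           n_sequences_per_condition = n_sequences_per_condition,
                           seed = seed, channels = c(roi_ch, counter_ch),
                           gains = gains,
                           eog_channels = c("VEOGU", "VEOGL"))
  sess$truth$fn_total <- fn_total
  sess$truth$integration <- integration
  sess
}
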