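#' Steady-state response specification
#'
#' Amplitudes (microvolts) of the modeled periodic brain responses: base
#' harmonics at `k * base_freq` (general visual synchronization) and
#' oddball harmonics at `m * base_freq / oddball_period` (identity
#' discrimination). The oddball amplitude decomposes per condition as
#' `A_FN = face + name + cross`, `A_FO = face`, `A_NO = name`, so `cross`
#' is the crossmodal (super-additive) component: with `cross = 0` the
#' Face Name response is exactly the sum of the two unimodal responses.
#'
#' Defaults emulate the amplitude scale of occipito-temporal scalp
#' responses in this paradigm: summed-over-harmonics oddball amplitudes of
#' about 0.12 (face), 0.09 (name) and 0.11 (crossmodal) microvolts, with a
#' decreasing harmonic profile, and a base response an order of magnitude
#' larger.
#'
#' @param base_amps Amplitudes at base harmonics `1..K_base` (muV).
#' @param face_amps,name_amps,cross_amps Amplitudes at oddball harmonics
#'   `1..K_odd` (muV); all four vectors must be non-negative.
#' @param base_phases,odd_phases Phases in radians (recycled; default 0).
#'   Phase is a nuisance parameter: all downstream statistics read
#'   amplitude spectra.
#' @return An object of class `fpvs_response_spec`.
#' @export
response_spec <- function(base_amps = c(0.8, 0.5, 0.35, 0.25, 0.2,
                                        0.15, 0.12, 0.1, 0.08),
                          face_amps = 0.12 * oddball_harmonic_weights(),
                          name_amps = 0.09 * oddball_harmonic_weights(),
                          cross_amps = 0.11 * oddball_harmonic_weights(),
                          base_phases = 0, odd_phases = 0) {
  k_odd <- max(length(face_amps), length(name_amps), length(cross_amps))
  pad <- function(x) c(x, rep(0, k_odd - length(x)))
  face_amps <- pad(face_amps); name_amps <- pad(name_amps)
  cross_amps <- pad(cross_amps)
  if (any(c(base_amps, face_amps, name_amps, cross_amps) < 0))
    stop("amplitudes must be non-negative")
  structure(list(base_amps = base_amps, face_amps = face_amps,
                 name_amps = name_amps, cross_amps = cross_amps,
                 base_phases = rep_len(base_phases, length(base_amps)),
                 odd_phases = rep_len(odd_phases, k_odd)),
            class = "fpvs_response_spec")
}

#' Default oddball harmonic amplitude profile
#'
#' Hump-shaped weights over the first six oddball harmonics, summing to 1
#' (the first harmonic is the weakest and the response peaks around the
#' third harmonic, as observed in occipito-temporal identity-oddball
#' responses); multiply by a total summed amplitude to obtain
#' per-harmonic amplitudes.
#'
#' @return Numeric vector of length 6 summing to 1.
#' @export
oddball_harmonic_weights <- function() {
  c(0.12, 0.20, 0.23, 0.20, 0.15, 0.10)
}

condition_oddball_amps <- function(spec, condition) {
  switch(condition,
    FN = spec$face_amps + spec$name_amps + spec$cross_amps,
    FO = spec$face_amps,
    NO = spec$name_amps,
    stop("unknown condition: ", condition))
}

#' Background noise specification
#'
#' Stationary background model for simulated recordings: 1/f ("pink")
#' spectral shaping plus a white floor, optional mains line component,
#' blink transients on EOG-like channels and constant voltage offsets
#' between recording blocks.
#'
#' @param pink_exponent Spectral slope alpha in `[0, 2]`; the mean
#'   amplitude spectrum of the pink component falls off as `f^-alpha`.
#' @param pink_scale Expected per-bin spectral amplitude at 1 Hz (muV) at
#'   the generated segment length. The default white/pink balance yields a
#'   mild low-frequency rise across the 0.5-3.5 Hz analysis band,
#'   matching the near-flat local noise this detection approach assumes;
#'   a strongly 1/f-dominated band is deliberately not the default.
#' @param white_scale Standard deviation of the additive white component
#'   per sample (muV).
#' @param line_freq,line_amp Mains frequency (Hz) and amplitude (muV).
#' @param blink_rate Blink events per second on EOG-like channels.
#' @param blink_amp Peak amplitude of the blink template (muV).
#' @param block_dc_jump Constant offset magnitude (muV) added between
#'   successive recording blocks (random sign, seeded).
#' @return An object of class `fpvs_noise_spec`.
#' @export
noise_spec <- function(pink_exponent = 1, pink_scale = 0.002,
                       white_scale = 1, line_freq = 50, line_amp = 0,
                       blink_rate = 0, blink_amp = 200,
                       block_dc_jump = 0) {
  if (pink_exponent < 0 || pink_exponent > 2)
    stop("pink_exponent must lie in [0, 2]")
  if (pink_scale < 0 || white_scale < 0 || line_amp < 0 || blink_amp < 0)
    stop("scales must be non-negative")
  structure(list(pink_exponent = pink_exponent, pink_scale = pink_scale,
                 white_scale = white_scale, line_freq = line_freq,
                 line_amp = line_amp, blink_rate = blink_rate,
                 blink_amp = blink_amp, block_dc_jump = block_dc_jump),
            class = "fpvs_noise_spec")
}

#' Synthesize the noiseless steady-state response of one sequence
#'
#' Sum of sinusoids at base harmonics and at the condition-dependent
#' oddball harmonics. With `include_fades` the output covers
#' fade-in + stimulation + fade-out and a squared-sine contrast ramp is
#' applied over each fade; phases are referenced to the end of the
#' fade-in so that an integer-cycle crop starting there sees the nominal
#' phases.
#'
#' @param schedule An `fpvs_schedule` (supplies rates, durations and the
#'   condition).
#' @param spec An [response_spec()].
#' @param fs Sampling rate in Hz; must exceed twice the highest modeled
#'   harmonic frequency.
#' @param include_fades Include contrast-ramped fade segments.
#' @param duration Optional override of the full-contrast duration in
#'   seconds (defaults to the schedule's `seq_duration`).
#' @return Numeric vector of samples (muV), one channel.
#' @export
synth_steady_response <- function(schedule, spec, fs = 512,
                                  include_fades = TRUE, duration = NULL) {
  p <- schedule$params
  if (is.null(duration)) duration <- p$seq_duration
  f_base <- p$base_freq
  f_odd <- p$oddball_freq
  odd_amps <- condition_oddball_amps(spec, schedule$condition)
  f_max <- max(length(spec$base_amps) * f_base,
               length(odd_amps) * f_odd)
  if (fs <= 2 * f_max)
    stop(sprintf("fs = %g Hz cannot represent harmonics up to %g Hz", fs, f_max))
  fade <- if (include_fades) p$fade_duration else 0
  n <- round((duration + 2 * fade) * fs)
  t <- (seq_len(n) - 1) / fs - fade  # 0 at end of fade-in
  x <- numeric(n)
  for (k in seq_along(spec$base_amps)) {
    if (spec$base_amps[k] == 0) next
    x <- x + spec$base_amps[k] * sin(2 * pi * k * f_base * t + spec$base_phases[k])
  }
  for (m in seq_along(odd_amps)) {
    if (odd_amps[m] == 0) next
    x <- x + odd_amps[m] * sin(2 * pi * m * f_odd * t + spec$odd_phases[m])
  }
  if (fade > 0) {
    env <- rep(1, n)
    ramp_in <- t >= -fade & t < 0
    env[ramp_in] <- sin(pi / 2 * (t[ramp_in] + fade) / fade)^2
    ramp_out <- t >= duration
    env[ramp_out] <- sin(pi / 2 * pmax(0, duration + fade - t[ramp_out]) / fade)^2
    x <- x * env
  }
  x
}

#' Generate background noise
#'
#' Pink (1/f-shaped) plus white noise with an optional mains line
#' component; fully reproducible from `seed`.
#'
#' @param n_channels Number of channels.
#' @param duration Duration in seconds (`duration * fs` must be integer).
#' @param fs Sampling rate in Hz.
#' @param spec An [noise_spec()].
#' @param seed Integer seed.
#' @return Channels x samples matrix (muV).
#' @export
synth_noise <- function(n_channels, duration, fs, spec = noise_spec(),
                        seed = 1L) {
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop("duration * fs must be an integer")
  n <- as.integer(round(n))
  rng <- local_rng(seed)
  out <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    x <- numeric(n)
    if (spec$pink_scale > 0) {
      n_pos <- (n - 1L) %/% 2L
      f <- (1:n_pos) * fs / n
      # per-bin Rayleigh amplitudes with mean pink_scale * f^-alpha
      sigma <- spec$pink_scale * f^(-spec$pink_exponent) / sqrt(pi / 2)
      re <- rng$draw_norm(n_pos) * sigma
      im <- rng$draw_norm(n_pos) * sigma
      spec_full <- complex(real = rep(0, n), imaginary = rep(0, n))
      spec_full[2:(n_pos + 1L)] <- complex(real = re, imaginary = im) * n / 2
      spec_full[n:(n - n_pos + 1L)] <- Conj(spec_full[2:(n_pos + 1L)])
      x <- x + Re(stats::fft(spec_full, inverse = TRUE)) / n
    }
    if (spec$white_scale > 0)
      x <- x + spec$white_scale * rng$draw_norm(n)
    if (spec$line_amp > 0) {
      ph <- 2 * pi * rng$draw(1)
      x <- x + spec$line_amp * sin(2 * pi * spec$line_freq * (seq_len(n) - 1) / fs + ph)
    }
    out[ch, ] <- x
  }
  out
}

# biphasic blink template: positive lobe then smaller negative rebound
blink_template <- function(fs, amp) {
  t <- seq(0, 0.4, by = 1 / fs)
  w <- amp * (exp(-((t - 0.1) / 0.05)^2) - 0.35 * exp(-((t - 0.22) / 0.08)^2))
  w
}

#' Simulate a full stimulation session
#'
#' Builds a continuous multichannel recording: for each sequence a lead-in
#' rest gap, a contrast fade-in, the full-contrast stimulation and a
#' fade-out, with an onset trigger at the start of each fade-in. The
#' noiseless steady-state component is scaled per channel by `gains`;
#' background noise, optional blink transients on EOG channels (with
#' fractional leakage to designated frontal channels) and per-block DC
#' offsets are added per the noise specification. The ground truth (specs,
#' schedules, seed, block layout) is retained.
#'
#' @param params A [schedule_params()].
#' @param spec An [response_spec()].
#' @param noise An [noise_spec()].
#' @param conditions Conditions to simulate, e.g. `c("FN","FO","NO")`.
#' @param n_sequences_per_condition Sequences per condition.
#' @param seed Integer seed.
#' @param channels Channel labels carrying the response.
#' @param gains Named response gain per channel (default 1 for all
#'   `channels`, 0 for EOG).
#' @param eog_channels Labels of EOG-like channels appended to the montage.
#' @param frontal_channels Channels receiving 10 % blink leakage.
#' @param fs Sampling rate in Hz.
#' @param lead_in Rest gap before each fade-in (s).
#' @param base_identity Base identity label.
#' @return An object of class `fpvs_session`: list with `recording`,
#'   `schedules` and `truth`.
#' @export
simulate_session <- function(params = schedule_params(),
                             spec = response_spec(),
                             noise = noise_spec(),
                             conditions = c("FN", "FO", "NO"),
                             n_sequences_per_condition = 2,
                             seed = 1L,
                             channels = c("P9", "PO9", "PO11", "I1", "POI1",
                                          "P10", "PO10", "PO12", "I2", "POI2"),
                             gains = NULL,
                             eog_channels = c("VEOGU", "VEOGL"),
                             frontal_channels = character(0),
                             fs = 512, lead_in = 4,
                             base_identity = "BASE1") {
  all_labels <- c(channels, eog_channels)
  if (is.null(gains)) gains <- stats::setNames(rep(1, length(channels)), channels)
  g <- stats::setNames(rep(0, length(all_labels)), all_labels)
  g[names(gains)] <- gains

  cond_seq <- rep(conditions, n_sequences_per_condition)
  n_seq <- length(cond_seq)
  seg_dur <- lead_in + 2 * params$fade_duration + params$seq_duration
  seg_n <- as.integer(round(seg_dur * fs))
  total_n <- seg_n * n_seq + as.integer(round(lead_in * fs))  # trailing gap

  rng <- local_rng(seed + 1000L)
  data <- synth_noise(length(all_labels), total_n / fs, fs, noise,
                      seed = seed + 2000L)

  schedules <- vector("list", n_seq)
  onsets <- integer(n_seq)
  block_starts <- integer(n_seq)
  for (s in seq_len(n_seq)) {
    sched <- build_schedule(params, cond_seq[s], base_identity,
                            seed = seed * 1000L + s)
    schedules[[s]] <- sched
    sig <- synth_steady_response(sched, spec, fs, include_fades = TRUE)
    start <- (s - 1L) * seg_n + as.integer(round(lead_in * fs)) + 1L
    idx <- start:(start + length(sig) - 1L)
    data[, idx] <- data[, idx] + outer(g, sig)
    onsets[s] <- start
    block_starts[s] <- (s - 1L) * seg_n + 1L
  }

  if (noise$block_dc_jump > 0 && n_seq > 1) {
    for (s in 2:n_seq) {
      sgn <- if (rng$draw(1) < 0.5) -1 else 1
      from <- block_starts[s]
      data[, from:total_n] <- data[, from:total_n] + sgn * noise$block_dc_jump
    }
  }

  blink_times <- list()
  if (noise$blink_rate > 0 && length(eog_channels) > 0) {
    tmpl <- blink_template(fs, noise$blink_amp)
    n_blinks <- as.integer(round(noise$blink_rate * total_n / fs))
    pos <- sort(rng$draw_int(n_blinks, total_n - length(tmpl)))
    blink_times <- pos / fs
    eog_idx <- match(eog_channels, all_labels)
    for (p0 in pos) {
      idx <- p0:(p0 + length(tmpl) - 1L)
      for (j in seq_along(eog_idx)) {
        sgn <- if (j %% 2 == 1) 1 else -1  # above/below eye: opposite polarity
        data[eog_idx[j], idx] <- data[eog_idx[j], idx] + sgn * tmpl
      }
      for (fc in match(frontal_channels, all_labels))
        data[fc, idx] <- data[fc, idx] + 0.1 * tmpl
    }
  }

  rec <- recording(data, fs, all_labels,
                   events = data.frame(sample = onsets, code = cond_seq,
                                       stringsAsFactors = FALSE),
                   meta = list(block_starts = block_starts,
                               eog_channels = eog_channels,
                               fade_duration = params$fade_duration,
                               seq_duration = params$seq_duration))
  structure(list(recording = rec, schedules = schedules,
                 truth = list(response = spec, noise = noise, seed = seed,
                              conditions = cond_seq, gains = g,
                              blink_times = blink_times,
                              block_starts = block_starts)),
            class = "fpvs_session")
}

#' Simulate a single SEEG contact with a known response profile
#'
#' Profiles map to response presets; `amp` is the amplitude in muV of each
#' of the six modeled oddball harmonics:
#' \describe{
#'   \item{pure_FN}{crossmodal component only: `cross = amp`, no unimodal
#'     response.}
#'   \item{nonpure_FN}{sub-threshold unimodal responses summing within the
#'     Face Name sequence: `face = name = amp/4` each, `cross = 0`, so at
#'     a moderate `amp` the FN response is detectable while neither
#'     control reaches significance and the FN - (FO + NO) contrast is
#'     null. This profile is intrinsically a decision-boundary case: its
#'     recovery rate depends on where `amp` sits between the two
#'     detection cutoffs.}
#'   \item{unimodal_face}{`face = amp`; significant in FN and FO (the FN
#'     sequence carries the same face periodicity) but not NO, i.e. the
#'     expected classification is `FN_and_face`.}
#'   \item{unimodal_name}{mirror of `unimodal_face`.}
#'   \item{mixed}{`face = name = amp/2`, `cross = 0`; expected
#'     classification `mixed_all`.}
#'   \item{null}{no oddball response.}
#' }
#'
#' @param profile One of the six profile names.
#' @param amp Oddball amplitude per harmonic in muV.
#' @param noise An [noise_spec()].
#' @param n_sequences_per_condition Sequences per condition (2 = one
#'   session).
#' @param seed Integer seed.
#' @param params A [schedule_params()].
#' @param fs Sampling rate (Hz).
#' @return An `fpvs_session` (single channel `SEEG1`) with
#'   `truth$label = profile`.
#' @export
simulate_seeg_contact <- function(profile = c("pure_FN", "nonpure_FN",
                                              "unimodal_face", "unimodal_name",
                                              "mixed", "null"),
                                  amp = 1, noise = noise_spec(),
                                  n_sequences_per_condition = 2, seed = 1L,
                                  params = schedule_params(), fs = 512) {
  profile <- match.arg(profile)
  u <- rep(amp, 6)
  z <- rep(0, 6)
  amps <- switch(profile,
    pure_FN       = list(face = z, name = z, cross = u),
    nonpure_FN    = list(face = u / 4, name = u / 4, cross = z),
    unimodal_face = list(face = u, name = z, cross = z),
    unimodal_name = list(face = z, name = u, cross = z),
    mixed         = list(face = u / 2, name = u / 2, cross = z),
    null          = list(face = z, name = z, cross = z))
  spec <- response_spec(base_amps = amp * c(1, 0.6, 0.4),
                        face_amps = amps$face, name_amps = amps$name,
                        cross_amps = amps$cross)
  sess <- simulate_session(params, spec, noise,
                           conditions = c("FN", "FO", "NO"),
                           n_sequences_per_condition = n_sequences_per_condition,
                           seed = seed, channels = "SEEG1",
                           gains = c(SEEG1 = 1),
                           eog_channels = character(0), fs = fs)
  sess$truth$label <- profile
  sess$truth$amp <- amp
  sess$truth$expected_classification <- expected_contact_label(profile)
  sess
}

#' Expected classification of a simulated contact profile
#'
#' The classification the detection pipeline should assign to each
#' simulated profile at high signal-to-noise ratio. Note that unimodal
#' profiles are expected to be detected in the Face Name condition too
#' (the FN sequence carries both unimodal periodicities), and the mixed
#' profile in all three conditions.
#'
#' @param profile A profile name accepted by [simulate_seeg_contact()].
#' @return The expected `classify_contact()` label.
#' @export
expected_contact_label <- function(profile) {
  switch(profile,
    pure_FN       = "pure_FN",
    nonpure_FN    = "nonpure_FN",
    unimodal_face = "FN_and_face",
    unimodal_name = "FN_and_name",
    mixed         = "mixed_all",
    null          = "none",
    stop("unknown profile: ", profile))
}
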