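Package: fpvstag
Title: Frequency-Tagging Analysis of Fast Periodic Visual Stimulation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing and analysing fast periodic visual
    stimulation (FPVS) oddball experiments on scalp EEG and intracerebral
    (SEEG) recordings. Generates face/name stimulation schedules with a
    periodic identity oddball, simulates recordings with a known
    steady-state harmonic structure (1/f background, line noise, blinks,
    inter-block drifts), implements the preprocessing chain (block
    alignment, zero-phase Butterworth band-pass, multi-notch, resampling,
    epoching, EOG handling, channel interpolation, common-average
    reference), computes calibrated single-sided amplitude spectra on
    integer-cycle crops, and provides the frequency-domain detection
    statistics: baseline-subtracted amplitudes, local-noise Z-scores,
    harmonic chunk summation, the Face Name versus (Face Only + Name Only)
    super-additivity contrast, and SEEG contact classification into pure
    and non-pure crossmodal response profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
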