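---
title: "Frequency-tagging analysis of crossmodal face-name oddball responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagging analysis of crossmodal face-name oddball responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvstag)
```

## The paradigm and its frequency-domain model

In a fast periodic visual stimulation (FPVS) oddball experiment, stimuli —
here, highly variable photographs and written names of a famous person —
are presented at a fixed base rate $F$ (4 Hz, one stimulus every 250 ms,
with sinusoidal contrast modulation). Every seventh stimulus is a
*different* famous identity, shown either as a face or as a name, so
identity changes occur periodically at $f_{odd} = F/7 \approx 0.571$ Hz.
Because the EEG synchronizes with periodic stimulation, any neural
population that discriminates the periodic identity change contributes
energy exactly at $f_{odd}$ and its integer harmonics, while general
visual synchronization concentrates at harmonics of $F$. Detection and
quantification therefore reduce to reading calibrated amplitude spectra
at known frequencies — no component on the frequency grid needs to be
estimated.

Three conditions separate crossmodal from unimodal identity responses:

* **FN (Face Name)** — faces *and* names of the base identity alternate
  randomly; the oddball periodicity is carried by both modalities and,
  critically, by their association.
* **FO (Face Only)** — base faces are kept, base names are replaced by
  other famous names; the only systematic periodicity left is
  face-identity change.
* **NO (Name Only)** — the mirror control for names.

If the FN response were the linear sum of modality-specific responses,
then $FN = FO + NO$ at the oddball frequencies (additive null). A
super-additive residual $FN - (FO + NO) > 0$ indicates a genuinely
crossmodal (integrated) representation. The package expresses that
contrast both as a percentage — the *integration fraction*
$100\,(1 - (FO + NO)/FN)$ — and as a significance test on the subtracted
spectrum.

## Detection statistics

All statistics operate on single-sided amplitude spectra normalized as
$2\lvert X_b \rvert / N$, so a unit-amplitude sinusoid on an exact bin
reads 1.0 µV. This calibration is asserted by the test suite on every
run. Spectra are computed on epochs cropped to an *integer number of
oddball cycles* (34 cycles = 59.5 s of the 60-s stimulation, starting at
the end of the 2-s fade-in), which places $f_{odd}$, $F$, and all their
harmonics on exact bins: with the defaults the oddball frequency falls on
bin 34 (0-based) and the base rate on bin $238 = 7 \times 34$. No window
or detrending is applied — integer-cycle cropping makes the frequencies
of interest leakage-free by construction.

* **Baseline-subtracted amplitude** (`baseline_correct`,
  `oddball_bc_sum`): bin amplitude minus the mean of a defined
  neighborhood of surrounding bins, in µV. It estimates response size
  above the local noise floor and may be negative.
* **Local-noise Z-score** (`local_z`, `detect_response`): the same
  difference divided by the sample (n−1) standard deviation of the
  neighborhood, compared against one-tailed cutoffs 1.65 (p < 0.05) and
  3.1 (p < 0.001). The thresholds are kept at the conventional printed
  values rather than the exact normal quantiles (1.6449, 3.0902); they
  are configuration values.
* **Chunk-and-sum** (`chunk_sum`): fixed-width spectrum segments centered
  on each of the first six oddball harmonics are summed element-wise
  before testing, pooling response energy across harmonics. The scalp
  variant uses 31-bin chunks (the harmonic at position 16, 15 bins on
  each side); the SEEG variant uses segments spanning 0.8 Hz at the
  native frequency resolution. The seventh oddball harmonic coincides
  with the 4-Hz base rate ($7 \times 4/7 = 4$) and is always excluded,
  which is why six harmonics are used.

Four neighborhood presets reproduce the published conventions:
`scalp_baseline` (12 bins/side, skipping the immediately adjacent bin on
each side and dropping the single maximum and minimum of the remaining
22, leaving 20 — the pre-exclusion window is not uniquely determined by
the published description; this reading reconciles "20 surrounding bins"
with the stated exclusions and mirrors the 12-bins-per-side SEEG
convention), `scalp_z` (11/side, no exclusions, 22 bins),
`seeg_baseline` and `seeg_z` (12/side, skipping the adjacent bin,
22 bins). Ties when dropping extrema are broken toward the lowest bin
index — arbitrary but deterministic.

Condition algebra (`spectra_add`, `spectra_subtract`) is always performed
on raw, uncorrected amplitudes; baseline correction or Z-scoring is
applied *after* adding or subtracting, matching the published order of
operations. Two published quantification orders exist and are both
implemented: the scalp order sums the harmonic chunks first and
baseline-corrects the summed chunk; the SEEG order baseline-corrects the
spectrum and sums the corrected values at the harmonic bins. They are
algebraically identical whenever no extrema are dropped from the
neighborhood, which the tests assert.

### SEEG contact classification

A contact is classified from its three condition spectra
(`classify_contact`): per-condition detection at $z > 3.1$; when FN alone
is significant, the subtraction $FN - (FO + NO)$ is tested at $z > 1.65$
(one-tailed) and decides **pure_FN** (significant — the response cannot
be explained by summed unimodal responses) versus **nonpure_FN**. The
remaining significance patterns map to `unimodal_face`, `unimodal_name`,
`FN_and_face`, `FN_and_name`, `mixed_all`, or `none`. A significance
pattern of both controls without FN is not part of the published taxonomy
and is folded into `mixed_all`. No multiple-testing correction is applied
across contacts; the 3.1 cutoff is deliberately conservative for that
reason.

## The preprocessing chains

The scalp chain follows the standard frequency-tagging pipeline: block
alignment (constant offsets between recording blocks are removed by
matching each block's first sample to its predecessor's last), 0.1–100 Hz
fourth-order zero-phase Butterworth band-pass, multi-notch (width 0.5 Hz)
at 50/100/150/200 Hz, downsampling to 256 Hz, epoching from −2 s to 66 s
around each sequence-onset trigger, blink screening at 0.15 blinks/s per
epoch, common-average re-referencing, integer-cycle cropping, and
time-domain averaging per condition before the FFT. The SEEG chain is
deliberately minimal: segmentation, cropping, averaging, FFT at the
native 512 Hz — no filtering or re-referencing.

Numerical choices worth knowing:

* "Fourth-order zero-phase Butterworth" is read as *design order 4,
  applied forward–backward*, i.e. an effective magnitude order of 8. The
  implementation applies the squared design magnitude in the frequency
  domain, which is the exact zero-phase response of a forward–backward
  pass without its edge transients, and avoids the numerical instability
  of order-8 recursions with poles at 0.0004 of Nyquist. Peak latencies
  of symmetric transients are unchanged (asserted in the tests).
* Whether the notch set should be read as the fundamental plus three
  harmonics (50–200 Hz) or four harmonics above the fundamental is
  ambiguous in the published description; the default is
  {50, 100, 150, 200} Hz and the count is configurable.
* Downsampling is Fourier resampling (spectrum truncation at the target
  Nyquist): ideal anti-aliasing, zero phase. Event indices are rescaled
  and rounded to the nearest sample, ties rounding half up.
* Blink detection is defined operationally (the published account only
  fixes the 0.15/s epoch-rejection rate): excursions of the vertical EOG
  difference beyond 100 µV separated by at least 200 ms. The defaults
  detect the simulator's blink template with a wide margin.
* Ocular correction is a deterministic least-squares regression of each
  EEG channel on the EOG channels, applied to flagged epochs. It is an
  intentionally simple, testable stand-in for component-based artifact
  decomposition and is *not* equivalent to it; for the synthetic blink
  model (a fixed template plus fractional frontal leakage) the two
  coincide in effect.
* Bad-channel interpolation is the unweighted mean of 3–6 designated
  neighbors and refuses to run when more than 5 % of channels are bad.

## The synthetic-data generator

The generator exists so that every statistic in the package can be tested
against known ground truth. `synth_steady_response` renders each
condition's noiseless response as sinusoids at the first nine base
harmonics and the first six oddball harmonics, with squared-sine contrast
ramps over the 2-s fades. The oddball amplitude per condition implements
the condition algebra exactly: $A_{FN} = face + name + cross$,
$A_{FO} = face$, $A_{NO} = name$, so the additive null and the
super-additive alternative are reproduced by construction
(`cross = 0` makes the FN signal equal FO + NO sample by sample).

Modeling choices:

* The oddball response is modeled directly as sinusoids at oddball
  harmonics rather than as a train of time-domain transients. All
  downstream statistics read amplitude spectra, which cannot distinguish
  the two; the harmonic amplitudes *are* the ground truth of interest.
* Response phases default to zero and are configurable; amplitude
  spectra are phase-invariant, so phase is a nuisance parameter.
* The default harmonic profile is hump-shaped (weights
  0.12/0.20/0.23/0.20/0.15/0.10 across harmonics 1–6): at
  occipito-temporal sites the first oddball harmonic is the weakest of
  the six and the response peaks around the third harmonic, so a
  monotonically decreasing profile would misrepresent the data this
  analysis targets.
* Background noise is 1/f-shaped ("pink", slope $\alpha$, calibrated as
  per-bin spectral amplitude at 1 Hz for the generated segment length)
  plus a white floor, optional 50-Hz line noise, biphasic blink
  transients on EOG-like channels, and constant DC offsets between
  blocks. The default pink/white balance produces a mild low-frequency
  rise across the 0.5–3.5 Hz analysis band. This is deliberate: the
  local-noise Z statistic assumes the spectrum is locally flat around
  each harmonic, and a strongly 1/f-dominated band (as raw sub-Hz EEG
  can be) violates that assumption — the first-harmonic neighborhood
  then spans a three-fold noise gradient and detection power statements
  become meaningless. The generator therefore emulates the noise level
  *at the analysis band* of averaged, high-pass-filtered recordings, and
  explicitly does not emulate strong sub-Hz drift, alpha rhythm,
  heartbeat or muscle artifacts, non-stationarity, or channel-specific
  noise profiles. Passing tests certify the statistics under the stated
  noise model, not under every pathology of real EEG.

`simulate_seeg_contact` maps named response profiles to presets
(`amp` is the amplitude of *each* oddball harmonic): `pure_FN`
(crossmodal component only), `unimodal_face` / `unimodal_name`, `mixed`
(both unimodal at half amplitude), `null`, and `nonpure_FN` — modeled as
two sub-threshold unimodal responses (`face = name = amp/4`, no
crossmodal component) that sum within the FN sequence. The expected
classification of each profile at high SNR is exposed by
`expected_contact_label`; note that unimodal profiles are *expected* to
be significant in FN too, since the FN sequence carries both unimodal
periodicities.

### The non-pure profile is a decision boundary

The `nonpure_FN` label occupies an intrinsically narrow operating region,
and no parameterization makes its recovery reliable. The argument: with
the FN response split as $\mu_{FN} = \mu_{face} + \mu_{name} + \mu_{cross}$
(in local-noise SD units of the summed chunk), a reliably non-pure
contact needs (i) $z_{FN} > 3.1$ reliably, i.e. $\mu_{FN} \gtrsim 4.7$;
(ii) both controls reliably below 3.1, i.e.
$\mu_{face}, \mu_{name} \lesssim 1.5$; and (iii) a reliably
non-significant subtraction, i.e. $\mu_{cross} \approx 0$. Conditions
(i)–(iii) are jointly infeasible: (ii) and (iii) cap $\mu_{FN}$ at about
3, short of (i). A second, subtler effect pushes the subtraction test
toward significance at low SNR even when $cross = 0$: amplitude spectra
are Rician, $E\lvert A + n \rvert \approx \sqrt{A^2 + \sigma^2}$, so
noise inflates small amplitudes more than large ones and the subtraction
$\lvert FN \rvert - \lvert FO \rvert - \lvert NO \rvert$ acquires a small
positive bias. Both effects are properties of the published method, not
of this implementation; the package documents them instead of hiding
them. Recovery guarantees in the acceptance checks therefore cover the
five determinate profiles; the non-pure profile's behavior is
characterized, not guaranteed.

### Amplitude recovery and the grand-average regime

The same Rician identity explains a small negative bias of
baseline-subtracted amplitudes: the neighborhood mean (a full Rayleigh
mean, $1.25\sigma_g$ per harmonic) is subtracted, while the signal bin
retains its noise inside $\sqrt{A^2 + \sigma^2}$. Summed over six
harmonics the bias is about $-7.5\sigma_g$, so percent-level amplitude
recovery requires the per-bin noise to be small against the response —
the regime of grand-averaged group data rather than of a single noisy
subject. The quantitative recovery studies therefore use
`simulate_scalp_study`: a session with the ten occipito-temporal ROI
electrodes at unit gain, ten fronto-central counter-electrodes at gain −1
(a dipolar pattern summing to zero, so common-average referencing does
not attenuate the response), four sequences per condition, and a noise
floor representing the residual noise of a group average (white scale
0.2 µV, pink scale 2×10⁻⁴ µV, with 2 µV line noise, blinks at 0.2/s and
20 µV inter-block jumps to exercise the full chain). In that regime the
integration fraction carries a residual upward bias of a few points
(twice-subtracted noise baselines in the numerator), which stays within
the ±5-point recovery band asserted by the acceptance checks.

Problem sizes used by the standard checks — 20 seeds for the recovery
medians, 100 seeds per classification profile, 1000 draws for the null
calibration — were chosen as the smallest studies whose pass/fail
decisions are stable under reseeding.

## Known limitations

* The exact segment lengths of the original analyses are not recoverable
  from the published bin counts; integer-cycle alignment of the oddball
  frequency is adopted as the governing constraint because every
  downstream statistic assumes it.
* Component-based ocular correction (ICA) is out of scope; the
  regression stand-in is documented above.
* The package emits per-ROI and per-contact tables; group-level
  inferential statistics (repeated-measures ANOVA, Friedman tests,
  post-hoc machinery) are left to general-purpose tools.
* Real-data headline values (µV amplitudes, the 32 %/20 % integration
  fractions, participant counts) depend on the deposited recordings and
  are not reproduced by simulation; the package reproduces the *method*
  and its analytic constants, and recovers known injected truths.
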