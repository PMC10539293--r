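---
title: "Quantifying periodic oddball responses in FPVS EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying periodic oddball responses in FPVS EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvstag)
```

## The measurement problem

In a fast periodic visual stimulation (FPVS) experiment, stimuli appear at a
fixed base rate (6 Hz here) and a critical "oddball" stimulus appears
periodically among them — every fifth stimulus, i.e. at 6/5 = 1.2 Hz. If the
brain discriminates the oddball from the base stimuli, the EEG contains a
periodic response at exactly 1.2 Hz and its harmonics, objectively separable
from everything else in the amplitude spectrum. In the face-identity
application, each sequence shows varying natural images of one base identity
with a different identity as the periodic oddball; the oddball response then
indexes face-identity discrimination, and its modulation by familiarity
(familiar vs unfamiliar faces, two conditions of 8 sequences each in 14
participants) is the effect of interest.

`fpvstag` implements the full quantification chain for this design, plus a
seeded synthetic-data generator so that every stage is testable without any
real recordings.

## Frequency-domain quantification

Per sequence, the preprocessed EEG (`preprocess_recording()`: zero-phase
0.05–100 Hz Butterworth band-pass of order 4, 50/100/150 Hz notches of width
0.5 Hz, anti-aliased downsampling 512 → 256 Hz, segmentation −2..76 s around
the sequence onset, average reference) is cropped to an integer number of
oddball cycles starting at the end of the 2 s fade-in
(`crop_integer_cycles()`; 83 cycles ≈ 69.17 s, giving a frequency resolution
of 1/69.17 ≈ 0.0145 Hz, so every harmonic of 1.2 Hz is bin-centered). The
FFT amplitude spectrum (`amplitude_spectrum()`, single-sided, 2/N scaling so
a bin-centered sinusoid of peak amplitude A reads A µV) is averaged across
the sequences of a condition within each participant.

The noise level at any bin is estimated from its 48 neighbors (24 per side,
skipping the immediately adjacent bin against leakage; `neighbor_spec()`).
Three transforms derive from it:

* **SNR** (`snr_spectrum()`): amplitude / neighbor mean, ≈ 1 under noise;
* **SBL** (`baseline_subtract()`): amplitude − neighbor mean, a signal
  estimate in µV;
* **z** (`zscore_bin()`, `summed_zscore()`): (amplitude − neighbor mean) /
  neighbor SD (n−1).

Harmonics are selected on the grand average across participants, channels
and conditions (`select_harmonics()`): walk k = 1, 2, … and keep consecutive
harmonics with z > 2.3 (p < .01 one-tailed), skipping multiples of 6 Hz for
the oddball set; the walk stops at the first failure. On data with the
standard structure this yields {1.2, 2.4, 3.6, 4.8, 7.2} Hz for the oddball
response and {6, 12, …, 60} Hz for the base response. SBL values are summed
over the selected harmonics per channel (`summed_response()`) and averaged
over regions of interest (`roi_aggregate()`): bilateral occipito-temporal
(OT, P7/8, P9/10, PO7/8, PO9/10, PO11/12), its left/right halves, and a
middle-occipital group. Individual-level significance uses the summed
z-score over the ROI (`summed_zscore()`): the null statistics are the 48
sums over matching neighbor offsets across harmonics, and z > 1.64
(p < .05, one-tailed) counts as a detectable response.

### Properties, and what the z-score assumes

The noise-bin z-score treats the neighbor bins as exchangeable with the
tested bin under the null. That holds exactly for a locally flat (white)
spectrum, and the false-positive rate then calibrates at its nominal 5%
(verified at 1.64 over thousands of seeded white-noise simulations, both per
bin and for the summed-harmonic ROI version). On a 1/f background the local
trend across the neighbor window raises the neighbor mean above the center
bin and inflates the neighbor SD, so the test becomes *conservative* —
a property of the published method, most visible at coarse frequency
resolution and low frequencies. Baseline subtraction has the complementary
caveat: because signal and noise add in quadrature, SBL underestimates a
true amplitude by roughly the expected noise amplitude per harmonic bin;
the estimate is accurate in the strong-signal regime the paradigm targets.

## Time-domain analysis

The re-referenced segments are low-pass filtered at 30 Hz (4th-order
zero-phase Butterworth), cropped to the same 83-cycle window, and the base
response is removed with narrow notches (width 0.05 Hz) at 6–30 Hz
(`remove_base_harmonics()`), leaving the oddball waveform. Epochs of five
stimulation cycles (833 ms: one base cycle of pre-stimulus context, −167 to
0 ms, then four cycles) are cut around every complete oddball onset,
averaged, and baseline-corrected to the pre-stimulus mean
(`epoch_and_average()`). With the standard timing the oddball onsets sit at
0.5 + k·0.833 s inside the crop, so 82 complete epochs fit a 83-cycle crop;
the count is recorded on the result.

Condition differences are tested with a cluster-based permutation t-test
(`cluster_test_paired()`, `cluster_test_vs_zero()`): per-time-point paired
(or one-sample) t inside 0–667 ms, clusters = maximal runs with p < .05,
cluster mass = sum of t. The null swaps condition labels within participants
(equivalently sign-flips difference waveforms; sign flips of the waveforms
for the one-sample test), retains the signed mass of the largest-|mass|
cluster per permutation, and a cluster is significant when its mass exceeds
the 97.5th or falls below the 2.5th percentile of that null (two-tailed,
familywise-corrected). Permutations are vectorized as sign-flip matrix
algebra; 10,000 permutations is the default, and the familywise error rate
calibrates at ≈5% in seeded null simulations. p-values use the plain
percentile rule; an add-one Monte-Carlo variant is available via `add_one`.
Tests run on ROI-mean time courses (per-channel spatio-temporal clustering
is out of scope). Zero-variance time points are flagged and never
significant, rather than producing NaN.

## Stimulus image statistics

`stimstats`-style checks compare two image sets on the properties that could
confound an oddball response (`image_set_stats()`): mean luminance, RMS
contrast (SD of pixel intensities; the conventional choice where "contrast"
is otherwise unspecified), head-orientation ratio (distance nose→left pupil
over nose→right pupil; 1 = frontal), face-area fraction from a supplied
mask, and the radial average of the 2-D FFT amplitude spectrum over the
central square matching the smaller image dimension (200 px → 100
cycles/image), fitted with an ordinary least-squares line in log–log
coordinates. Set comparisons use two-tailed permutation tests on the
difference of means with the add-one p-value rule
(`permutation_test_sets()`); Monte-Carlo p agrees with exact enumeration on
small sets.

## The synthetic generator

`generate_study()` emulates the study conditions: 14 participants × 2
conditions × 8 sequences of 74 s at 512 Hz (2 s linear fade-in/out on the
signal, flanked by 2 s of noise-only context so the −2..76 s segmentation
contract is satisfiable on single-sequence records), with an event marker at
sequence onset. Each recording contains:

* a **base train**: a brief pulse projected onto the first 10 harmonics of
  6 Hz, peaking ~80 ms after stimulus onset;
* an **oddball train**: a biphasic kernel projected onto harmonics
  {1, 2, 3, 4, 6} × 1.2 Hz (no 6 Hz component), negative lobe near 242 ms
  and positive lobe near 362 ms, with a decaying amplitude profile across
  harmonics as observed for oddball responses. Kernels are normalized so
  the summed single-sided harmonic amplitude equals 1, making the amplitude
  parameters exact inject-and-recover targets;
* **1/f background noise**: amplitude spectrum ∝ f^(−α) above a 1 Hz
  low-frequency knee (flat below, as in resting EEG), synthesized
  spectrally on a doubled grid and truncated so the noise is not periodic
  over the record, independently per channel, scaled to `noise_scale` RMS;
* optional 50 Hz line noise (off by default) and a per-participant
  lognormal gain (SD 0.4) shared by both conditions.

Topographies put the oddball response on the OT channels (weight 1, with a
configurable right-hemisphere multiplier, neutral by default since no
quantitative lateralization magnitude is established) and the base response
on the middle-occipital group. The default montage has 32 channels: the 22
ROI channels plus 10 standard sites. Condition structure: the unfamiliar
oddball amplitude is `oddball_ratio` (0.29) times the familiar amplitude
(0.86 µV, the group OT magnitude reported for this paradigm).

Two numerical choices matter downstream. First, average re-referencing
subtracts the mean topography weight from every channel, so the measured OT
amplitude is (1 − mean weight) times the injected one; ratios between
conditions are unaffected, and amplitude-recovery checks are run on the
pipeline without the re-reference step. Second, `noise_scale` defaults to
0.15 µV broadband RMS, chosen so the per-bin noise floor at the oddball
harmonics (~0.02 µV at 0.0145 Hz resolution) keeps the SBL noise-floor bias
near 3% and the group familiar/unfamiliar ratio near 1/0.29 ≈ 3.45. This
makes the synthetic data *cleaner* than real EEG (real noise is larger,
spatially correlated, and non-stationary); passing calibration and recovery
on it demonstrates correctness of the quantification, not field-strength
performance on raw recordings. Individual-level significance rates for the
weaker condition are correspondingly higher than in real cohorts.

The image-set generator (`generate_face_image_set()`) produces grayscale
1/f-noise images with controlled luminance, contrast and spectral slope,
elliptical face masks (~36% area) and jittered landmark geometry. They are
synthetic stand-ins with face-like image statistics; no face content is
rendered.

## Orchestration and reproducibility

`run_study()` streams one recording at a time (the full default study would
be ~2.3 GB materialized) through preprocessing, cropping, spectra and
time-domain averaging, then computes harmonic sets, per-participant metrics,
ROI aggregates, group ratios, and cluster tests. Every recording's seed
derives deterministically from the master seed and is listed in the run log;
re-running a config writes byte-identical tables. There is no separate
shell executable: the package functions and `study_config()` are the
interface, and `scripts/acceptance.R` shows a complete scripted run.

Problem sizes used in the shipped checks: z-calibration runs 2,000
simulations of 8-sequence-averaged spectra at 64 Hz with 30-cycle (25 s)
epochs — the calibration depends on the neighbor-bin count and averaging
depth, not on the sample rate or epoch length; cluster calibration runs 200
null simulations at 1,000 permutations; the end-to-end run uses the full 14
× 2 × 8 default study.

## Numerical notes

* All filters are applied with exactly zero phase by multiplying each
  channel's FFT with the analytic Butterworth power response of the stated
  design, evaluated on the prewarped analog prototype. This equals the
  magnitude response of one forward plus one backward pass and stays
  numerically exact even for the 0.05 Hz-wide notches, where polynomial
  IIR coefficients are ill-conditioned. Circular edge effects fall in the
  discarded fades.
* Resampling uses a zero-phase Kaiser-windowed FIR anti-alias filter and
  integer-factor decimation.
* FFTs of lengths with large prime factors (e.g. the 17,707-sample default
  crop at 256 Hz) go through an in-package Bluestein chirp-z fall-back via
  power-of-two FFTs.
* Edge spectrum bins without full neighbor support are reported as NA; zero
  neighbor SD yields +Inf with a warning, never NaN.
* `n_cycles = 83` is the documented replication default; `"max"` selects
  the largest integer cycle count that fits the usable span (84 under the
  nominal timing — the one-cycle discrepancy is inherited from the original
  analysis and both options are supported).

## Known limitations

* Synthetic noise is spatially independent and stationary; real EEG is
  neither. Blink/ICA correction, bad-channel interpolation and voltage-step
  alignment across recording pauses are out of scope.
* Cluster tests operate on ROI-mean time courses only.
* EDF export quantizes to 16 bits; the internal container round-trips
  exactly.
* The image battery computes statistics from supplied masks and landmarks;
  no face detection or landmark estimation is performed.
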