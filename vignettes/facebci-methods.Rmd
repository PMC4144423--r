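---
title: "Decoding conditioned responses to neutral faces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding conditioned responses to neutral faces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facebci)
```

## The problem

A neutral face that has been paired with an aversive event (a conditioned
stimulus, CS+) evokes a different cortical response than an unpaired face
(CS−), even though the two faces look equally inexpressive. The difference is
not in the early face-processing components — the P1 (positive peak near
90 ms) and N170 (negative deflection near 140 ms) at posterior temporal
electrodes — but in a late negativity 600–700 ms after stimulus onset over
the right posterior temporal region. If a classifier can pick up that late
signature from EEG, it can drive a non-verbal communication aid: when the
system predicts that a viewed neutral face carries a negative association,
it morphs the face on screen into a negative expression, externalizing an
emotion the user cannot express.

`facebci` implements this pipeline end to end: ERP preprocessing, feature
extraction in the time and time–frequency domains, a ν-SVM classifier with
round-robin validation, and the morph trigger — plus a synthetic EEG
generator so that every stage can be exercised and tested without access to
human recordings.

## Preprocessing chain

The chain is fixed in this order: average reference → band-pass → epoch →
baseline → artifact rejection → average.

* **Average reference.** Each scalp channel is re-referenced to the mean of
  all scalp channels. Ocular channels are excluded from the reference (they
  monitor blinks, not cortex).
* **Band-pass, 1–30 Hz.** A 4th-order Butterworth band-pass applied
  forward–backward (`signal::filtfilt`), i.e. zero phase, so peak latencies
  are not shifted. At 500 Hz the filter is numerically stable and passes
  10 Hz within 0.2%, leaves < 1 µV of a 100 µV DC offset, and attenuates
  100 Hz by more than 99%.
* **Epochs** span [−100, 700) ms around stimulus onset (onset = 0 ms, sample
  index `round(t·fs/1000)`, half-open windows); at 500 Hz that is 400
  samples. **Baseline**: the mean of the −100..0 ms interval is subtracted
  from the whole epoch, per trial and channel. Subtracting from the whole
  epoch (rather than post-onset samples only) makes the invariant "pre-
  stimulus mean is zero" testable; post-onset values are identical either
  way.
* **Rejection.** A trial is discarded when (a) the peak-to-peak range on any
  ocular channel within any sliding 50-ms window exceeds 50 µV — the
  standard ocular-step criterion — or (b) any channel exceeds ±200 µV in
  absolute amplitude. Rejection runs after referencing and filtering, so
  thresholds apply to the data the averages are computed from.

P1 is the maximum in the closed 60–120 ms window and N170 the minimum in
100–200 ms, after averaging the waveform across the channels of a region of
interest (left posterior temporal P7/P9/TP9, right P8/P10/TP10, occipital
O1/O2); ties resolve to the earliest latency, and a flat window reports the
window start. Late activity is summarized as means over five 100-ms windows,
200–300 … 600–700 ms.

## Time–frequency features

The complex Morlet wavelet is

$$w(t, f_0) = \exp(-t^2/2\sigma_t^2)\,\exp(2\pi i f_0 t)\,/\,(\sigma_t\sqrt{\pi}),$$

with $\sigma_t = c/(2\pi f_0)$ for $c = f_0/\sigma_f = 6$ cycles, so
$\sigma_t\sigma_f = 1/(2\pi)$ for every center frequency. The bank spans
4–12 Hz (theta/alpha) in 0.1-Hz steps — 81 kernels. Kernels are truncated at
±4σ~t~ (< 0.05% of Gaussian mass lost) and applied by FFT convolution with
same-length output.

Two numerical points deserve note:

* **Edge handling.** At f~0~ = 4 Hz the truncated kernel is 957 samples long
  at 500 Hz — longer than the 400-sample epoch. Same-length convolution
  therefore pads by *repeated* reflection (mirror indices with period
  2n−2), which is continuous at the edges and defined for pad widths
  exceeding the signal length. The alternative — erroring on signals
  shorter than the kernel — would make the default bank unusable on the
  epochs it is designed for.
* **Scaling.** The discrete convolution is multiplied by 1/f~s~ so it
  approximates the continuous transform; a unit-amplitude sinusoid at f~0~
  then yields $|\tilde u|^2 = 0.5$ at its own frequency, which the tests
  pin down.

Signals are linearly detrended before the transform. The classifier sees
either of two representations, built per (subject, condition) from the
averaged ERP of the right posterior temporal group mean:

* **time-course**: the mean amplitude over 600–700 ms of each right
  posterior temporal channel (3 features), or
* **tfr**: the power map averaged over 2 Hz × 100 ms tiles covering
  4–12 Hz × 0–700 ms (4 × 7 = 28 features, frequency-outer ordering).

The tiling keeps the dimensionality well below the 36 available samples; it
is configurable. A per-trial variant (transform each kept trial, average the
power) is available behind the `per_trial` flag of
`make_feature_dataset()`; the default transforms the averaged ERP, matching
the 36-sample design.

## Classifier

A ν-SVM with RBF kernel $K(x_i, x_j) = \exp(-\gamma\|x_i - x_j\|^2)$.
ν ∈ (0, 1] bounds the fraction of margin errors from above and the fraction
of support vectors from below (the ν-property, asserted for every model the
tests train). The quadratic program is solved by LIBSVM via \pkg{e1071}
(termination tolerance 10^−6^); the decision function
$f(x) = \mathrm{sgn}(\sum_i \alpha_i y_i K(x_i, x) + b)$, one-vs-one voting,
per-fold rescaling, cross-validation and the kernel sweep are implemented
here. Three classes (CS+, CS−, scenery) are handled one-vs-one with majority
voting; ties — including the all-zero-scores corner — resolve to the first
class in the fixed order (CS+, CS−, scenery). An independent projected-
gradient solver for the ν-SVC dual serves as a cross-check in the test
suite: on small 2-D problems the two decision rules agree on ≥95% of a
probe grid.

**Feature rescaling.** LIBSVM's own preprocessing convention (the
`svm-scale` tool) maps each feature to [0, 1] using training-set statistics,
and that is the default here (`scale = "minmax"`), refit inside every
cross-validation fold. Per-feature z-scoring is available but interacts
badly with the usual γ grid: with d z-scored features, squared distances
concentrate near 2d, so at γ = 1 and d = 28 the kernel matrix collapses to
the identity and the decision function degenerates to its bias. Min–max
scaling keeps distances O(1) at any dimensionality, which is what lets a
single γ grid (10^−4^, 10^−2^, 1, 1/d) remain meaningful. `scale = "none"`
feeds native µV/µV² scales to the kernel.

Validation is a round robin (leave-one-out): with 12 subjects × 3
conditions, 36 rounds, each training on 35 samples with rescaling refit on
the training fold. Accuracy is reported overall and per class (recall).
Chance level for three balanced classes is 33%, which the label-permutation
utility reproduces empirically.

## Synthetic data: what it emulates, and what it does not

`synth_spec()` defines the study conditions: 12 subjects × 3 conditions ×
24 trials at 500 Hz on a compact 13-channel montage (the 8 ROI channels,
three midline fillers, two ocular channels). Each trial is a deterministic
condition template plus noise:

* **P1**: Gaussian bump, center 90 ms, σ 15 ms, 5 µV, largest occipitally;
  **N170**: center 140 ms, σ 12 ms, depth 6 µV for faces and 2 µV for
  scenery at posterior temporal channels. Both topographies sum to zero
  across scalp channels (as dipolar fields do over a full montage), so the
  average reference leaves the planted amplitudes exactly invariant.
* **CS+ late negativity**: Gaussian bump, center 650 ms, σ 40 ms, planted
  only on the right posterior temporal channels. A bump rather than a
  boxcar, so it survives the 1-Hz high-pass and carries 4–12 Hz energy.
  Because the average reference and the zero-phase filter linearly reshape
  this component, the generator's ground truth for it
  (`planted_late_difference()`) is defined as the noise-free template
  difference passed through those deterministic stages — recovery tests
  compare against that, not the raw planted ratio.
* **Noise**: 1/f (exponent 1) plus 10-Hz alpha (20% of variance), scaled to
  the per-trial σ; subjects get lognormal amplitude multipliers
  (σ~log~ = 0.2) per component. **Artifacts**: blinks as 150 µV Gaussian
  bumps (σ 25 ms) on ocular channels; movement as 400 µV 8-Hz bursts with a
  spatially heterogeneous profile (random sign and gain per channel — a
  spatially uniform artifact would be removed by the average reference
  before rejection could see it).
* **SNR presets** fix the class effect and noise: `high` (late Δ = −3 µV,
  trial σ = 5 µV), `moderate` (Δ = −1.5 µV, σ = 10 µV; the default) and
  `null` (Δ = 0 and the scenery N170 set equal to the face N170 — no class
  information at all).
* Stimulus onsets are spaced 1.5 s apart with 0–200 ms jitter. The jitter
  decorrelates the 10-Hz alpha phase across trials; the spacing itself
  carries no information used by any pipeline stage, so the generator keeps
  recordings compact.

Everything is deterministic given the seed, per subject
(`derive_seed(seed, subject)`), so datasets are reproducible sample-for-
sample.

What the generator does *not* emulate: volume-conducted spatial noise
correlations, latency jitter between subjects, non-stationary alpha,
realistic blink propagation to frontal channels, or any late face-vs-scenery
difference outside the CS+ effect. Consequences worth knowing: (i) CS− and
scenery are distinguishable only through the early N170/P1 components, so
time-course (600–700 ms) features cannot separate them even in principle;
(ii) at the `moderate` preset the CS+ late signature contributes on the
order of 0.01 µV² to the late time–frequency tiles, an order of magnitude
below the between-subject tile variability, so CS+/CS− classification sits
near chance there and overall accuracy is carried by the scenery class. A
passing test on synthetic data shows the pipeline recovers what was planted
at the stated SNR; it does not certify performance on real recordings,
where the late effect is sustained over a longer window and three times as
many trials per condition are typically available.

## Morph trigger

The output stage maps a prediction to an action: a CS+ prediction
cross-dissolves the neutral source face into its negative-expression target
over 1.5 s (the midpoint of the 1–2 s the application calls for) at 30
frames/s; CS− and scenery predictions produce nothing. Frame k of n is
`round((1−α)·src + α·dst)` with α = k/(n−1), so the endpoints reproduce the
source and target exactly and every pixel stays within its endpoint bounds.
Landmark-based warping would look better but needs landmark data; the
trigger contract — which stimulus morphs, when, and for how long — is fully
exercised by the linear blend, and `cross_dissolve()` is the single
extension point a warping implementation would replace.

## Problem sizes used by the tests and the acceptance script

All checks run on generated data at the study's own scale: 36-sample
datasets (12 subjects × 3 conditions × 24 trials), 100 label permutations
for the chance-level estimate, 36-round leave-one-out sweeps over four γ
values, and grand averages over 12 subjects. A full run of the test suite
and the acceptance script completes in a few minutes on one CPU.

## Known limitations

* The leave-one-out estimate on 36 samples has a standard deviation of
  roughly 8 percentage points; single-dataset accuracies should be read
  with that granularity (1/36 ≈ 2.8 points per held-out sample).
* EDF import covers the standard 16-bit continuous layout only (no EDF+
  discontinuous records; annotation channels are skipped, so events must
  come from a sidecar or be attached in code).
* The `null` preset zeroes class information but keeps the face-typical
  P1/N170 in all conditions; it tests the classifier's false-positive
  behavior, not the preprocessing.
* Images are handled as grayscale PNG matrices in [0, 255]; color morphing
  would need per-channel blending.
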