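---
title: "Morphological PPG analysis for hypertension risk stratification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological PPG analysis for hypertension risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppght)
```

## The problem

A fingertip photoplethysmogram (PPG) tracks beat-to-beat blood-volume change
in the peripheral microcirculation. The timing and size of the *reflected*
pressure wave relative to the main propulsion wave shift with arterial
stiffness and blood pressure: with higher BP the reflection arrives earlier
and larger, fusing with the systolic wave. `ppght` implements a screening
pipeline that turns short (≈2 s) single-channel PPG records into a
125-feature morphological description and asks how well those features
separate normotensive, prehypertensive and hypertensive subjects.

The pipeline is: quality scoring → bandpass filtering and derivative
waveforms → fiducial delineation → feature catalogue → six filter-type
feature rankings → cross-validated pairwise classification, reporting
sensitivity (SE), positive predictivity (PP) and F1 in percent.

## Signal model and preprocessing

**Quality index.** Each subject contributes three 2.1 s records; only the one
with the highest moment skewness $m_3/m_2^{3/2}$ is analysed. Clean
systolic-dominant pulses are strongly right-tailed; noise and drift pull the
skewness toward zero, so the argmax is a cheap and effective quality gate.
The estimator uses no small-sample bias correction, matching the SQI
literature.

**Filtering.** A fourth-order Chebyshev type-II bandpass with stopband edges
at 0.5 and 10 Hz (stopband attenuation 20 dB, configurable) is applied
forward–backward (zero phase), because landmark *timing* is the measurand and
a causal application would bias every fiducial. The application direction is
our choice; nothing in the protocol fixes it. An order-8 bandpass with a
0.5 Hz edge at 1 kHz is numerically unusable as a single polynomial transfer
function, so the design is factored into second-order sections and filtered
as a cascade with steady-state initial conditions and odd-reflection padding.

**Derivatives.** VPG, APG and the third derivative are central differences
scaled by $f_s$. Differentiation amplifies whatever high-frequency noise
survives the 20 dB stopband by $(2\pi f)^2$ per order; on 12-bit-quantized
records this residual exceeds the genuine APG waves. `waveform_set()`
therefore smooths each derivative stage with a ~20 ms zero-phase moving
average (the standard practice in APG delineation work). The bare
`differentiate()` operator keeps smoothing off so it meets its closed-form
calculus contract.

## Fiducial delineation

Beats are segmented at PPG minima preceding prominent VPG maxima (systolic
upslopes): candidate peaks are anchored at ≥50% of the tallest upslope so
that sub-noise maxima cannot drag the threshold down, then the half-median
rule is applied, with a 0.25 s refractory window and a 0.3 s minimum beat
length. Landmarks per beat:

* PPG: onset O, systolic peak S (global maximum), dicrotic notch N, diastolic
  peak D;
* VPG: w (global maximum = steepest upslope), then alternating x, y, z;
* APG: a, b (the two dominant early excursions), then alternating c, d, e
  before 80% of the beat.

Small waves are found with a prominence-filtered alternating-extrema walk
(2% of the in-beat waveform range for derivatives, 1% of pulse amplitude for
the notch), so quantization wiggles are never landmarks. Two conventions
matter downstream: a notch must be followed by a diastolic rise (otherwise
the pre-foot minimum of a stiff, notchless waveform would be mislabelled N —
for those beats N falls back to the APG e-wave time, and D is reported
missing); and missing landmarks propagate as missing feature values, never as
zeros. Landmark times are integer sample indices; sub-sample interpolation is
deliberately not used.

## The 125-feature catalogue

Features come in seven kernel families with fixed counts — time spans (23),
PPG amplitudes (14), VPG/APG amplitudes (10), curve areas (4), power areas
(15), ratios (43), slopes (16). The published exemplars (crest time `OS-`,
`Sc-2-`, `b-2d-2~`, `S+1c-1}/O+1O+1}`, `(b-c-d)/a`, `c-1/w`, ...) are all
present; the remaining slots are the systematic closure of the same patterns
over the landmark set (spans from O and S to each later landmark, each span
over the beat period, power areas of the major segments on each level and
their full-beat ratios). The catalogue ships as an editable JSON config
(`inst/extdata/catalogue.json`) and is loaded by `ppg_catalogue()`; notation
conventions are documented there (`-` span, `^` area, `}` power, `~` slope,
`±k` level projection).

Conventions: the per-beat baseline is the PPG value at the onset (the
filtered signal is AC-coupled, so the onset is the natural per-beat zero);
derivative levels use zero baseline. Power areas are raw sums of squared
baseline-corrected samples over closed index intervals — not divided by
$f_s$ — because their ratio features cancel the convention anyway. Beats are
aggregated per subject by the median (2.1 s yields 1–3 beats; the median
tolerates one bad beat). Z-scoring uses the sample (n−1) SD, the convention
under which the column (1, 2, 3) maps to (−1, 0, 1); zero-variance columns
become all-zero with a warning.

## Feature ranking

Six filter methods: absolute Spearman correlation against the binary class
label, ReliefF (k = 10 neighbours, every instance used once in order —
deterministic, Manhattan distance on range-normalized features,
class-prior-weighted misses), information gain, the chi-square statistic,
greedy mRMR (mutual-information difference scheme), and Gini impurity
reduction. The discretization-based scores use equal-frequency binning with
10 bins — chosen over equal-width because it is outlier-robust and makes the
scores invariant to strictly increasing transforms. Subjects missing a
feature are dropped pairwise for that feature's score; ties resolve by
catalogue order. A Table-1-style report (`correlation_report()`) correlates
each feature with SBP as a continuous target; Pearson by default with a
Spearman switch, since the original report does not state the coefficient
type.

## Classification experiments

`assign_bp_class()` applies the screening criteria (hypertensive: SBP ≥ 140
or DBP ≥ 90; else prehypertensive: SBP ≥ 120 or DBP ≥ 80; else normotensive),
with the hypertensive rule evaluated first to resolve the boundary overlap.
Three pairings are tested — norm vs pre, norm vs hyp, norm+pre vs hyp — the
positive class always being the higher-BP group so SE reads as sensitivity to
disease. Four fixed-configuration classifiers: LDA (pooled covariance with a
10⁻⁸ ridge), logistic regression (IRLS with a 10⁻⁶ L2 guard against
separation), a cubic-kernel SVM (K(u,v) = (1 + u·v/d)³, box constraint 1,
deterministic SMO), and weighted KNN (K = 10, inverse-squared-distance votes,
exact matches dominate).

Cross-validation is stratified 10-fold with a seeded shuffle (default
seed 17, recorded in the report). Imputation (training-fold median),
z-scoring and feature selection are refit inside every training fold — the
methodologically sound protocol — with a `global_selection` switch to emulate
a single whole-cohort selection. Confusion counts are pooled over folds;
SE = TP/(TP+FN), PP = TP/(TP+FP), F1 their harmonic mean, all ×100.

## The synthetic cohort: what it does and does not establish

Real deposited recordings cannot ship with the package, so `generate_cohort()`
produces a stated world with the structure the analysis assumes: 48/41/35
subjects per class, three 2.1 s records each at 1 kHz, 12-bit quantization,
SBP/DBP drawn uniformly (integer mmHg) inside each class's criteria.

Each beat is three positive Gaussian bumps — systolic (amplitude 1, σ ≈
42–52 ms, centre 0.17–0.21 s), reflected, dicrotic — plus a smooth diastolic
runoff term `runoff_amp·(1−cos(2πt/T))/2` that vanishes exactly at the beat
boundaries. The runoff is a deliberate fourth component: a bare Gaussian
mixture leaves a flat inter-beat tail on which no minimum-based onset
detector can anchor, whereas real PPG decays continuously into the foot. The
class effect lives on the reflection, mirroring the physiology of BP
formation: the reflected-wave delay falls (0.19 → 0.15 → 0.11 s) and its
relative amplitude rises (0.42 → 0.57 → 0.72) from normotensive to
hypertensive. Within-class jitter (±40 ms delay, ±0.12 amplitude ratio) is
deliberately comparable to the between-class step, because that is the
overlap structure real BP cohorts show: adjacent classes overlap heavily,
extreme classes much less. These values were fixed once, from realism
arguments, before the acceptance properties were measured. `effect = 0`
collapses all classes onto the pooled distribution — the null world used for
calibration checks. Records add Gaussian noise (σ = 0.02 a.u., scaled
per-record by 0.5–3× so the quality gate has work to do) and a slow
sinusoidal drift.

A green test on this world establishes that the *pipeline* — detection,
catalogue, ranking, CV plumbing — behaves correctly and that the qualitative
finding (severe hypertension separates more easily than prehypertension)
re-emerges under a graded class effect. It does **not** establish clinical
performance: the generator has no inter-subject morphology diversity beyond
its parameter jitter, no motion artifacts, and no device transfer function,
and the numeric F1 values on synthetic cohorts are not comparable to values
measured on real recordings. Exact reproduction of the original
cross-validation cells would require the deposited recordings, the authors'
exact catalogue and their fold assignment, and is not claimed.

## Numerical choices and degenerate inputs

* Filter: SOS cascade, zero-phase, odd-reflection padding of 3×(order)
  samples, steady-state initial conditions; inputs shorter than the padding
  are rejected.
* Skewness of a constant segment is `NA` with a warning (undefined), never a
  number.
* Ranking ties: stable sort by catalogue order. mRMR's greedy pick order *is*
  its ranking; all other methods sort scores non-increasingly.
* `fit_predict()` refuses single-class training folds; stratified folding
  prevents them, and the fold count drops to the minority class size (with a
  warning) for very small cohorts.
* Zero denominators in ratio features yield missing values, which the CV
  imputes from the training fold median.
* All randomness flows from explicit integer seeds; reruns are byte-identical.

## Known limitations

* The onset (pulse foot) is localized to a flat cosine minimum plus noise, so
  O-anchored spans carry a few tens of milliseconds of jitter; S, w, a, b, c
  are sharp and match closed-form oracles within 10 ms.
* Hypertensive (early-fusion) synthetic beats often have no dicrotic notch;
  their N falls back to the e-wave time and D is missing — downstream this is
  handled as missingness, not as a detection failure.
* The cubic SVM uses a simplified SMO adequate for n ≈ 100; it is not tuned
  for large cohorts.
* The third-derivative waveform is computed for detection support only; no
  catalogue feature uses it.
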