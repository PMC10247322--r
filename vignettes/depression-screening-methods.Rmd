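---
title: "Methods: time-domain EEG depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-domain EEG depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The screening problem

A short resting-state EEG (14 channels, 128 Hz, five minutes) is recorded
from each subject in a two-group cohort: *depressed* (PHQ9 in the severe
range, 20–27) versus *control* (PHQ9 0–4). The analysis asks whether simple
time-domain statistics of the band-filtered signal, computed on a few
seconds of data at a time, separate the groups under standard supervised
classification. `depscreen` implements that analysis end to end and, because
clinical recordings of this kind are rarely shareable, ships a synthetic
cohort generator with the statistical structure the analysis assumes, so the
whole pipeline is testable from first principles.

## Pipeline and assumptions

The pipeline is deliberately fixed as **filter → segment → features →
classify → evaluate**. Filtering the full recording before windowing means
segment boundaries see no extra filter transients beyond the two recording
ends. Segmentation uses contiguous non-overlapping windows; window `k`
covers samples `[kS, (k+1)S)` and the trailing partial window is discarded,
so a recording of `T` samples yields `floor(T/S)` segments (a 300 s
recording at 128 Hz gives 60 five-second segments of 640 samples).

The analysis treats each *segment* as one classification instance. This is
faithful to common practice in this literature, but it means segments of one
subject can appear in both training and test folds. The package therefore
carries both protocols: segment-level CV (the fidelity mode) and
subject-grouped CV (`run_grouped_cv()`, the diagnostic mode). On cohorts
with subject-level amplitude effects the first is systematically optimistic;
the package's tests assert exactly that ordering.

## Filter bank

Band-pass Butterworth designs of order 4 (the order is not dictated by the
screening design; 4 is standard EEG practice and verified stable at
128 Hz for every catalogue band — all poles strictly inside the unit
circle). Zero-phase application runs the filter forward and backward with
odd-reflection end padding of up to 3 s, so start-up transients — including
a consumer-headset-style constant offset of several thousand microvolts —
decay inside the padding and are trimmed. A causal single-pass mode is kept
for fidelity experiments. Band edges at or above the Nyquist frequency
(gamma and the full band, upper edge 64 Hz at fs = 128) are capped at
`0.99 × fs/2 = 63.36` Hz, since a digital band-pass edge at Nyquist is
undefined.

## Features

All eight features use population (1/N) moments, and the discrete
derivative is the plain first difference: any constant scaling cancels
inside mobility and complexity, and mobility is reported in radians per
sample (a pure sinusoid of frequency `f` gives `2 sin(pi f / fs)`).

Two conventions deserve note:

* **Shannon entropy.** Applied to a real-valued signal, the textbook
  `−Σ p log p` needs a definition of `p`. The default follows the
  wavelet-toolbox convention, treating squared samples as unnormalised
  energy weights: `−Σ x² ln x²`, zero samples contributing zero. A
  histogram estimator (128 equal-width bins, `p` = bin frequency) is
  available behind `method = "histogram"`; both are tested. Natural
  logarithms everywhere — the base only rescales a feature and is absorbed
  by standardisation.
* **Kurtosis.** Excess kurtosis (`m4/m2² − 3`), so a Gaussian signal scores
  0. The feature set named `"all"` omits plain variance because it equals
  Hjorth activity identically.

Zero-variance segments make four of the features ill-defined; they return 0
with a degenerate flag and `build_feature_matrix()` drops such rows with a
message. Generated cohorts cannot produce them (white noise is always
present); real flat channels would.

## Classifier presets

The ten presets fix what a point-and-click toolbox leaves implicit:

| preset | decision rule |
|---|---|
| fine / medium / coarse KNN | k = 1 / 10 / 100, Euclidean, equal votes |
| cosine KNN | k = 10, cosine distance |
| cubic KNN | k = 10, Minkowski p = 3 |
| weighted KNN | k = 10, Euclidean, squared-inverse-distance votes |
| linear / quadratic / cubic SVM | cost 1; polynomial degree 1 / 2 / 3 |
| Gaussian SVM | RBF, kernel scale `sqrt(n_features)` (gamma `1/n_features`) |

SVM regularisation and kernel scales are documented package defaults, not
properties of the screening design, and are overridable. Standardisation
(training mean/SD) is on for every preset — KNN distances are
scale-sensitive — and is computed from training rows only, so the protocols
are leak-free by construction; a test injects an extreme outlier into a
held-out fold and asserts the standardiser is untouched. KNN determinism is
pinned: distance ties resolve to the earliest training row, vote ties to the
nearest neighbour's class, then to the lowest class index.

## Evaluation protocols

*Iterated stratified k-fold CV* (default 5 folds, 25 iterations): per
iteration, rows are dealt into stratified folds (per-fold class counts
within one row of the global ratio; remainder rows land in random folds),
out-of-fold predictions are pooled into one confusion matrix, and the six
metrics are averaged over iterations. Iteration `i` reseeds at
`seed + i`, so any iteration is re-runnable in isolation and fold
assignments are identical across classifiers within an iteration (paired
comparisons).

*70/30 hold-out* (default 10 iterations): "training accuracy" is the mean
out-of-fold accuracy of a 5-fold CV inside the 70% (resubstitution accuracy
would be trivially 100% for 1-NN); the model is refit on the full 70% and
scored on the 30%. The "overall" accuracy is the sample-weighted
`0.7·training + 0.3·testing` — a reporting convention with no standard
definition, flagged as such in every report.

Undefined metric ratios (e.g. NPV with no negative predictions) are
reported missing, never zero: silently coercing to 0 would bias summaries.
F1 is `2TP/(2TP+FP+FN)`, the precision–recall harmonic mean (occasionally
mislabelled as a sensitivity–specificity mean in applied writing).

## The synthetic cohort generator

Each channel is

```
x(t) = Σ_b  a_b · m_b(subject) · g_b(group, channel) · n_b(t)  +  pink(t) + ε(t)
```

with `n_b` unit-RMS band-limited noise (white noise through the band's own
Butterworth filter — *not* sinusoids, so spectra are realistically
broadband and the entropies are meaningfully exercised), `pink` a 1/f
background (10 µV RMS), and `ε` white noise (default SD 2 µV). Base band
RMS amplitudes are `delta 20, theta 10, alpha 15, beta 8, gamma 4` µV —
eyes-closed resting-state magnitudes with dominant alpha.

* **Group effect** `g_b`: depressed subjects' band amplitudes are scaled by
  the effect's multipliers (defaults `alpha 1.4, beta 1.25, theta 1.15,
  gamma 1.1, delta 1.0`), and their *left-hemisphere alpha* is further
  raised by a fractional `asymmetry_delta` (default 0.25). The
  lateralisation makes the region sweep discriminative by construction:
  left-hemisphere features must beat right-hemisphere features on generated
  data.
* **Subject effect** `m_b`: one log-normal multiplier per subject and band
  (`subject_sd`, default 0.2, on the log scale). Log-normal keeps
  amplitudes positive and gives tunable within-subject clustering for the
  leakage experiments.
* **Metadata**: PHQ9 uniform over the group's admissible range (controls
  0–4 by default; the ceiling is configurable since screening cut-offs vary
  in practice), ages uniform 18–25, depressed group ~74% female — marginal
  realism only, no metadata feeds the signal.

One numerical subtlety: components are scaled by their *theoretical* RMS
(the filter's white-noise gain, from the energy of its impulse response),
not by each realisation's sample SD. Normalising per recording would pin
the realised component power of every recording, anti-correlating the band
power of windows within a recording and biasing null cross-validation
below chance.

The generator does **not** emulate: eye-blink/EMG artifacts, electrode
drift or re-referencing, non-stationarity across the five minutes,
physiologically coupled oscillations (phase–amplitude coupling), or any
PHQ9 item structure. Passing tests therefore demonstrate that the pipeline
is correct and calibrated on data with the assumed covariance structure —
not that the screening result transfers to clinical recordings.

## Calibration and the null

The null effect (`null_effect()`) sets all multipliers to 1 and asymmetry
to 0. Calibration tests additionally set `subject_sd = 0`: with subject
clustering present, a 1-NN under segment-level CV identifies the source
subject of a test segment and returns that subject's label, so even a
label-uninformative cohort scores far above 50% — that is precisely the
leakage phenomenon, demonstrated separately. On the exchangeable null
(10 + 10 subjects, 60 s, 240 five-second segments) every preset's mean CV
accuracy must fall inside the 99% binomial band around 50%, and mean
accuracy must be non-decreasing in the alpha multiplier across
{1.0, 1.2, 1.5, 2.0} (one inversion tolerated as Monte-Carlo noise).

## Problem sizes

The test suite and acceptance script choose sizes for statistical adequacy
at desk scale: calibration and monotonicity cohorts of 8–10 subjects per
group at 60 s; power/asymmetry checks on 20–100 short recordings; the
full screening pipeline on the study-scale cohort (19 depressed + 13
control, 300 s, 128 Hz → 1 920 five-second segments × 70 features) with 10
CV and 5 hold-out iterations. Sweep helpers default to fewer iterations
than the protocols' 25/10 defaults; both are arguments.

## Known limitations

* EDF import/export is not provided; the CSV + JSON-manifest formats are
  the source of truth (EDF is 16-bit lossy and adds nothing to the
  analysis contract).
* The command-line surface is R itself plus `scripts/acceptance.R`; there
  is no standalone shell binary.
* Artifact removal is out of scope; degenerate-segment handling is the only
  concession to dirty data.
* Sweep cells run sequentially; the cache (plain factor-level keys + cohort
  fingerprint) makes interrupted sweeps resumable but is not a provenance
  store.
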