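---
title: "Methods: scoring resting-tremor severity from wearable IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring resting-tremor severity from wearable IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorscore)
```

## The problem and the model

Resting tremor in Parkinson's disease is rated clinically on an ordinal
0–4 scale (UPDRS): 0 absent, 1 slight and infrequent, 2 mild or
intermittent, 3 moderate and present most of the time, 4 marked and
present most of the time. The two clinical axes of this ladder are
*amplitude* and *persistence*. `tremorscore` implements a pipeline that
maps a six-channel wrist/finger IMU recording (tri-axial accelerometer
and gyroscope, 125 Hz) to such a score: kinematic preprocessing, a
fixed 76-dimensional feature representation whose components capture
amplitude, rhythm and spectral concentration, feature selection,
supervised classification, and an evaluation framework built on the
absolute ordinal error. Nothing in the mathematics is specific to
125 Hz; all durations and frequencies are parameterized by the sampling
rate.

## Preprocessing

Each channel is band-pass filtered to 1–16 Hz with a fifth-order
Butterworth filter. The lower edge removes drift and slow voluntary or
postural movement; the upper edge bounds the band of interest for
pathological tremor while comfortably containing the classic 4–6 Hz
Parkinsonian resting-tremor peak and its first harmonic.

Three numerical choices here were genuinely open and are worth recording:

* **Zero-phase filtering.** The filter is applied forward and backward
  (`signal::filtfilt`), so its effective magnitude response is the square
  of the single-pass Butterworth response and its phase is identically
  zero. The temporal features below are built on peak *locations*; a
  causal filter would shift them by a frequency-dependent group delay.
  The tests compare the realized response against a direct evaluation of
  the transfer-function polynomials, squared.
* **Integration with re-filtering.** Displacement is obtained by
  integrating acceleration twice, angle by integrating angular velocity
  once (cumulative trapezoid). Time-domain integration amplifies any
  low-frequency content by 1/ω, so integrating broadband noise produces a
  random walk that dominates the result. The 1–16 Hz band-pass is
  therefore re-applied after each integration pass. On band-limited
  tones this leaves the analytic amplitude ratios 1/ω and 1/ω²
  intact to within 2% across 2–10 Hz, which is exactly what the test
  suite asserts.
* **Segmentation.** The first and last 10 s of a recording are dropped
  (device handling, settling), and a 30-s window centered in the
  remaining span is analyzed; recordings shorter than 50 s are rejected.
  Centering is deterministic and uses the most artifact-distant part of
  the recording. After cutting the window each axis is demeaned: the
  band-pass removes DC over the full record, but truncation to a finite
  window reintroduces a small offset (order RMS/(π·f·T)), which carries
  no information and is removed so processed signals are exactly
  zero-mean.

## Features

For each of the four signals — acceleration, angular velocity,
displacement, angle — 19 features are computed; 76 per recording, in a
fixed, documented column order (`feature_names()`), since selection
indices are only meaningful against a frozen ordering.

**Temporal features** are computed on the composite magnitude
`mag(t) = sqrt(x² + y² + z²)`, which measures tremor intensity
independently of sensor orientation. Positive peaks are local maxima and
negative peaks local minima of this nonnegative series. Peak detection
canonicalizes candidate extrema to strict alternation, discards extrema
whose local prominence is below 5% of the composite's interquartile
range (noise ripple), and enforces a minimum positive-peak spacing of
half the 16 Hz period (31.25 ms), since anything faster lies outside the
analysis band. Each positive peak flanked by troughs contributes the
mean of its two half-cycle amplitudes `|pp_i − np_i|` and
`|np_(i+1) − pp_i|`; the *mean amplitude* averages these over peaks. We
average over all complete peak–trough–peak triples rather than any other
reading of the peak count; the choice only matters at the window edges.
The *regularity* features are the mean and standard deviation of
successive positive-peak intervals, in seconds. Degenerate composites
(fewer than two usable peaks — e.g. a tremor-free recording whose
composite is noise around a constant) yield 0 for the peak features,
with a warning.

**Spectral features** use a Welch estimate: Hann window of 512 samples
(≈4.1 s, ≈0.244 Hz resolution at 125 Hz), 50% overlap, one-sided PSD,
averaged over segments and then across the three axes at each frequency,
giving one spectrum per signal that reflects the 3-D movement. Welch
averaging was chosen over a raw periodogram for the stability of band
powers on 30-s records; the window length trades frequency resolution
(enough to separate a 4–6 Hz tremor line from its surroundings) against
the number of averaged segments (13 at 50% overlap). From the spectrum,
restricted to (0, 16] Hz: peak frequency (argmax), mean frequency
`MF = Σ fᵢPᵢ / Σ Pᵢ`, peak power, and mean power — the PSD value at the
grid bin nearest MF (nearest-bin, not interpolated). Three *adaptive*
bands follow the patient-specific MF rather than fixed edges: low
`[0, MF−3)`, tremor `[MF−3, MF+3]`, high `(MF+3, 16]` Hz, clamped to
`[0, 16]`. Each grid bin belongs to exactly one band (half-open
assignment), so the three relative powers always sum to 1. Six log₁₀
features (mean amplitude, peak/mean power, three band powers) are
floored at ε = 10⁻¹² before the logarithm so tremor-free recordings stay
finite; the floor is far below any physically meaningful power at these
signal scales.

## Feature selection

Two reduction strategies are implemented. The *pairwise-correlation
ordering* arranges features "most unrelated first": the first two
features are the pair with the smallest absolute Pearson correlation,
and each following feature is the candidate whose largest `|r|` against
the already-selected set is smallest (minimax; a mean-`|r|` extension is
available). Absolute values are essential — a correlation of −0.9 is as
redundant as +0.9. Ties break on canonical column order, making builds
reproducible. The prefix of length *d* is the selected set. *PCA* is fit
on z-scored features (the 76 features mix seconds, metres and
log-powers; unstandardized PCA would be dominated by one unit) and
held-out rows are projected with the training loadings.

Inside cross-validation, both strategies are refit on each training fold
by default. Fitting selection on the full data first is label-free but
still lets the held-out sample influence the feature configuration used
to score it; fold-internal fitting is the honest default, and
`fit_on_all = TRUE` reproduces the optimistic variant for comparison.

## Classifiers and validation

Five families are compared: decision tree (Gini, unpruned, minimum leaf
1), SVM with linear/polynomial(3)/RBF kernels at cost 1, discriminant
analysis (LDA by default — the family is not otherwise pinned down, QDA
available), random forest (100 trees, seeded), and kNN with odd
k ∈ {1,…,11} (odd to reduce vote ties), Euclidean metric, uniform votes.
Remaining ties in kNN — equal distances or equal votes — resolve to the
lower class label, a deterministic and mildly conservative rule given
that severity underestimation is the characteristic failure mode.
Scale-sensitive learners (SVM, kNN, discriminant) see fold-internally
z-scored features; trees and forests see raw features. No class
re-weighting or resampling is applied: the clinic class distribution is
heavily imbalanced and the pipeline deliberately trains on it as-is,
which is precisely what produces the dominant-class bias the evaluation
framework is designed to expose.

Validation is leave-one-out, appropriate for a dataset with classes as
small as two recordings. A training fold may then lack a class entirely
(each fold of a singleton class); this is permitted and recorded in the
result rather than treated as an error.

## Evaluation

All metrics derive from the absolute ordinal error `e = |û − u|`:

* the error CDF, `P(e ≤ x)` for x = 0..4 — `P(e ≤ 0)` is the accuracy
  and `P(e ≤ 1)` the within-one-step probability, clinically the more
  forgiving and arguably more meaningful number;
* NAuC, the trapezoidal area under the five CDF points over [0, 4]
  divided by 4. This convention reproduces the published worked-example
  value (0.980) exactly, which is the strongest available evidence for
  it;
* per-class recall and precision with Wald 95% half-widths
  `1.96·sqrt(p(1−p)/n)`, with n the grand total of the matrix. This
  convention was identified by matching the published ±0.038 for the
  dominant class (the per-class-n convention gives ±0.048 and is
  available as an option). A class never predicted has *undefined*
  precision, propagated as an explicit flag and never coerced to 0;
* two labelled RMSE variants, `sqrt(mean(e²))` and `sqrt(Σe²)/n`. The
  published RMSE for the worked example (0.034) is not reproduced by
  either convention (they give 0.410 and 0.0358); since the underlying
  formula is not recoverable, RMSE is reported descriptively and
  excluded from all acceptance checks.

```{r reference}
print(eval_report(reference_confusion()))
```

## The synthetic tremor simulator

No patient recordings are distributed with the package, so end-to-end
behaviour is established on simulated data. Each simulated recording is

```
A · g(t) · [ sin(2πft + φ) + h · sin(4πft + φ₂) ]
```

projected onto a random unit 3-vector (independently for accelerometer
and gyroscope — the sensing axes of a wrist unit and a finger unit are
not aligned), plus per-channel white noise and a slow random-walk drift.
The tremor frequency `f` is drawn once per recording from 4–6 Hz, the
classic Parkinsonian resting band. The gate `g(t)` is a two-state Markov
chain with 2-s mean on-dwell whose stationary on-fraction is the class's
duty cycle, giving "intermittently present" tremor realistic run lengths
rather than a fixed mask.

Class profiles map the clinical ladder onto two dials: amplitude
(0, 0.05, 0.15, 0.45, 1.35 m/s² — roughly tripling per class, since
perceived severity tracks amplitude multiplicatively) and duty cycle
(0, 0.3, 0.8, 0.9, 0.95 — "infrequent" to "most of the time"). The
harmonic ratio defaults to 0.1: resting tremor is near-sinusoidal and a
weak 2f line is realistic without displacing the mean frequency from the
fundamental. Noise (0.02 m/s² accel, half that for gyro) and drift
(0.05) levels are set so a class-0 recording is recognizably
tremor-free after preprocessing. All profile numbers are simulator
conventions chosen once, not clinical measurements, and are overridable.

What the simulator does *not* emulate: re-emergent or postural tremor
dynamics, voluntary-movement artifacts, amplitude dependence on limb
loading, inter-patient frequency drift within a recording, or the
inter-rater disagreement of the clinical gold standard. Tests passing on
simulated data therefore demonstrate that the pipeline recovers known
ground truth — frequency within one spectral bin, amplitude ordering
across classes, high LOOCV accuracy on well-separated classes — not that
it attains any particular accuracy on real patients.

```{r pipeline, eval = FALSE}
ds <- simulate_dataset(class_counts = rep(20, 5), seed = 7)
X <- extract_dataset(ds$recordings, ds$labels)
res <- loocv(classifier_spec("decision_tree"), X, ds$labels,
             selection = list(method = "pairwise", d = 5))
loocv_accuracy(res)
```

The test suite and the acceptance script use this 5×20-recording,
60-s-per-recording configuration; it is large enough for stable medians
per class and LOOCV estimates while keeping a full run in tens of
seconds.

## Known limitations

* The real-data study conditions cannot be reproduced: no recordings are
  available, so claims about accuracy on patients rest entirely on the
  packaged worked-example matrix.
* The selection stage reports fully qualified feature names
  (`signal.feature`); published summaries that name features without
  their source signal cannot be mapped one-to-one.
* The peak-train features degrade gracefully but bluntly (to zero) on
  degenerate composites; an explicit missing-value mechanism would
  preserve more information for downstream learners.
* LDA on fold-internally z-scored features can emit collinearity
  warnings when a training fold contains near-constant features; they
  are harmless but noisy.
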