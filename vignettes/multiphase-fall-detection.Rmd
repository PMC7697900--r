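---
title: "Multiphase fall detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase fall detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
multiphase fall model, the windowing geometry, every tunable parameter with
its unit and default, what the synthetic generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` do not
themselves compute.

## The multiphase fall model

A fall recorded at the lower back decomposes into phases with distinct
signatures on the acceleration norm `Norm_acc(t) = sqrt(ax² + ay² + az²)`
(units g, sampled at 100 Hz):

* **descent** — partial free fall; the norm dips well below the 1 g resting
  value;
* **impact** — a sharp peak, typically above 2 g on wide-range sensors but
  possibly clipped near 2 g on ±2 g hardware;
* **post-impact** — either a long lie (signal variance at the noise floor),
  or recovery movements and resumed walking.

Detection therefore hinges on windows *anchored to the impact peak*, so each
phase occupies a fixed, known position inside the window.

## Windowing geometry

Analysis windows are `windowS = 27.5` s long and advance by `stepS = 1` s.
Each window's *second* second (local interval [1 s, 2 s)) is its peak-search
interval: this is the only placement for which (a) a 1-s pre-peak phase and
25.5 s of post-peak context always fit inside the window wherever the peak
lands in the interval, and (b) the 1-s step makes consecutive search
intervals tile the timeline, so every sample from t = 1 s onward within
coverage is searched exactly once. A window whose search-interval maximum is
below `peakThresholdG = 1.4` g is discarded as minimal movement. Otherwise a
candidate fall window (CFW) of `cfwS = 26.5` s is emitted, anchored with the
peak exactly 1 s after its start.

At 100 Hz the CFW holds 2651 samples (inclusive endpoints: 100 pre-peak
samples, the peak, 100 post-peak, 2450 post-impact). The durations were given
in seconds only; the inclusive-endpoint convention was chosen because it
keeps the peak exactly 1 s after CFW start and the post-impact phase exactly
24.5 s. "Peak" means the global maximum of the search interval — no
prominence logic — and exact amplitude ties anchor at the earliest sample,
for determinism. Trailing data that cannot fill a whole window is ignored,
and recordings shorter than one window yield an empty result with a warning
rather than an error, so a batch run survives degenerate inputs.

Fall recordings can contain several CFWs (multiple impacts, post-fall
activity); the one nearest the annotated impact sample represents the fall,
with the earlier peak winning distance ties. ADL recordings keep every CFW,
because each one is a potential false alarm.

## Features

The five multiphase features, all computed from the orientation-invariant
norm:

| feature | phase | definition |
|---|---|---|
| `LPV` | pre-peak | minimum of the norm (free-fall dip floor), g |
| `UPV` | peak | the anchoring peak value, g (≥ 1.4 by construction) |
| `wavelet_similarity` | impact | normalized correlation with the mother wavelet |
| `periodicity` | post-peak | max lagged autocorrelation, 2-s segment from 0.5 s after the peak |
| `post_impact_sd` | post-impact | sample SD of the norm, g |

The **mother wavelet** is the pointwise mean of the 201-sample impact
segments of the *training-fold* falls, de-meaned and scaled to unit energy
(de-meaning and unit energy are the standard admissibility conditions for a
wavelet-like template). Similarity is its zero-lag normalized correlation
with the de-meaned, energy-normalized impact segment of the CFW — a
single-scale matched filter. This is the simplest operator consistent with a
"similarity coefficient to the template"; a full continuous wavelet
transform across scales was considered and rejected because the template and
candidate segments share one fixed scale by construction.

**Periodicity** had an open design: the source model states the rationale
(walking right after the candidate impact rules out a fall) and the segment
(2 s starting 0.5 s after the peak) but not the statistic. The package uses
the maximum per-lag Pearson autocorrelation over lags of 0.2–1.0 s, clamped
to [0, 1]. Two alternatives were rejected numerically: the biased
autocorrelation estimator scores a pure sinusoid only `(n−k)/n ≈ 0.75` at
its period lag, too weak a response to cadenced motion; and extending the
lag range to 1.5 s leaves fewer than 100 overlapping samples per lag, which
raises the white-noise score ceiling (95th percentile ≈ 0.37 vs ≈ 0.28)
without covering any additional human step period (cadence 1.5–2.5 Hz means
step periods of 0.4–0.67 s).

Zero-variance segments define both `wavelet_similarity` and `periodicity`
as 0 — degenerate inputs score as "no evidence", never as errors. Sample
standard deviations use the n−1 denominator throughout.

The 16 conventional comparison features (max/min/mean/SD of each axis and
the norm) are computed over the full CFW, so both feature sets see identical
inputs. They are deliberately *not* orientation-invariant; the test suite
asserts this asymmetry.

## Classifiers and imbalance

Continuous monitoring yields orders of magnitude more ADL windows than
falls. Before training (and only in training folds), ADL rows are reduced to
`undersampleFraction = 0.10` by a seeded uniform draw; every fall row is
kept. Defaults: 3 nearest neighbours (standardized features), 20
random-forest trees, and an RBF SVM (standardized features) whose
`C ∈ 2⁻⁵…2¹⁵` and `γ ∈ 2⁻¹⁵…2³` (21 × 19 = 399 pairs) are selected by
internal 5-fold cross-validation accuracy on the undersampled training
table, ties resolved toward the smaller C then γ (smoother models,
deterministic). The internal folds are subject-based like the outer ones, so
hyperparameter selection cannot leak subjects either. Undersampling precedes
the grid search, matching the training sequence of the original design.

All five families emit scores in [0, 1], thresholded at 0.5: posterior
probabilities (naive Bayes, logistic regression), neighbour fractions (3-NN
scores take only values {0, ⅓, ⅔, 1}), the ensemble mean of regression
trees (random forest is fitted in regression mode on the 0/1 label precisely
so its score is continuous and an AUC exists), and a Platt-calibrated
sigmoid of the SVM decision value. Platt scaling is fitted in-package (a
logistic regression of the training labels on the decision values) rather
than with libsvm's built-in probability machinery, whose internal
cross-validation is not seedable from R; with it, training is bit-for-bit
reproducible given a seed.

## Cross-validation and metrics

Fold assignment is by subject: subjects with ADL windows are split at the
median ADL count into low/high strata, each stratum seeded-shuffled and
dealt round-robin over the 5 folds; fallers without ADLs are likewise split
at the median fall count. Per-stratum fold counts differ by at most one (a
validity condition of the `FoldAssignment` class — assembling an assignment
that places one subject in two folds is rejected as invalid). Within-stratum
assignment is a seeded shuffle; a deterministic ordering would have worked
too, but the shuffle removes any dependence on subject naming.

Headline metrics pool the confusion counts over all test folds — the only
scheme under which FA/h = FP / total monitored hours is coherent — with
per-fold reports alongside. Monitored hours count ADL recording durations
only. Falls whose recording produced no CFW count as false negatives.
Undefined ratios (no positives, no predicted positives) are reported as
`NA`, never as 0. The AUC is the rank-based Mann–Whitney concordance (ties
one half), which equals the trapezoidal area under the ROC curve; the test
suite checks it against a brute-force pairwise oracle and against an
established ROC implementation.

The comparator multi-threshold detector runs on the same CFWs as the
learned classifiers, so the comparison is on identical candidate sets. Its
"all acceleration signals below 0.75 g" free-fall condition is read as
*norm* < 0.75 g by default (the physics rationale is free fall, and a norm
below the threshold implies every axis below it); a config flag
(`freefallOnNorm = FALSE`) provides the literal per-axis reading. The
posture check low-pass filters the vertical axis with a 2nd-order
Butterworth at 0.25 Hz applied forward–backward: only the cutoff was
specified, and the zero-phase form avoids shifting the 1.6–2.0 s posture
window. Inside a CFW the vertical axis is estimated from the pre-peak
second (median absolute value closest to 1 g, ties x < y < z), when the
wearer is still upright.

## The synthetic generator

Real-world fall recordings of the population this design targets are not
publicly available, so the generator stands in for them. It emulates: quiet
standing with slow postural drift of the gravity direction; walking bouts as
tapered harmonics at 1.5–2.5 Hz with amplitudes (0.1–0.25 g) that keep
walking below the 1.4 g screen; Poisson spike artifacts (default 45/h,
matching the ~46 candidate windows per monitored hour observed in the
reference study) with norm peaks 1.6–2.6 g; and multiphase falls — dip to a
0.3–0.8 g floor for 0.2–0.5 s, damped 12 Hz impact oscillation loading at
least two axes with pre-clipping peaks of 2.0–3.5 g, a smooth-step
orientation flip, then a long lie (probability 0.6) or recovery after
3–8 s. Impact directions are constrained to load two or more axes so that
per-axis ±2 g clipping still leaves a norm above 2 g, keeping the
baseline's impact check non-degenerate — mirroring how wider-range falls
are clipped into the ±2 g range on real hardware. Per-axis noise is
0.02 g SD.

Default scale: 10 subjects, each with one 0.2-h ADL recording (2 monitored
hours) and 30 falls total, spread heterogeneously (each subject at least
one; weights seeded) to exercise the stratifier. These sizes make the full
test suite and the acceptance script desk-scale; the bundled
`farseeing_like.yaml` preset documents the reference scale (15 × 12 h = 180
monitored hours, 143 falls over 46 subjects) without being simulated in the
tests. Every recording derives a sub-seed from the root seed, so any single
recording is reproducible in isolation.

What the generator does **not** emulate: biomechanically validated fall
dynamics, soft-tissue or attachment artifacts, barometric or gyroscope
channels, mis- and under-reported falls contaminating the labels, or the
sheer diversity of real ADLs. Consequently, the synthetic classes are far
more separable than real data: cross-validated sensitivities near 1 and
F-measures above 0.9 on the default conditions demonstrate that the
pipeline's plumbing is correct (no leakage, conservation of windows,
calibrated generator), not that real-world performance would reach those
levels — on the real repository data the corresponding published figures
are dramatically lower. In the same vein, the conventional feature set can
saturate alongside the multiphase set on synthetic data (both feature sets
separate spike artifacts from modelled falls), so the published advantage of
multiphase features is *reported* by the end-to-end checks, not asserted.

## Numerical choices

* **Norm summation order.** The three squared axes are summed in ascending
  order (a vectorized 3-element sorting network), making the norm
  bit-identical under any axis permutation or sign flip — IEEE addition is
  not associative — so the orientation-invariance of the multiphase
  features holds exactly, not just to tolerance.
* **Sample indexing** is 0-based in all stored indices (`impactSample`,
  `peakSample`), with time t ↔ sample `round(t·fs)`; R's 1-based indexing
  is confined to implementation internals.
* **Recordings at other sampling rates are rejected**, not resampled: every
  constant of the design (search-interval width, phase lengths, filter
  cutoff) is defined at 100 Hz.
* **Clipping before norm.** Axes are clipped, then the norm is computed, so
  a clipped norm may exceed 2 g (up to 2√3) — required for the baseline's
  2 g impact check to remain reachable on ±2 g data.
* **CSV round-trips** write 17 significant digits, so samples survive
  write/read bit-exactly.
* **Ties**: peak-search ties → earliest sample; fall-CFW selection ties →
  earlier peak; grid-search ties → smaller (C, γ); ROC ties → concordance ½.

## Limitations

The package evaluates offline, per candidate window; it does not implement
on-device streaming, alarm delivery, or recovery-severity grading. The
synthetic generator is a calibration and testing instrument, not a
substitute for clinical validation data; conclusions about real-world
performance require real-world recordings.
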