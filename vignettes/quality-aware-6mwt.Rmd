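---
title: "Quality-aware distance estimation for smartphone 6-minute walk tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware distance estimation for smartphone 6-minute walk tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmwt)
library(dplyr)
```

## The problem

The 6-minute walk test (6MWT) measures functional capacity as the distance a
person walks in six minutes. Performed outdoors with a smartphone, the walked
distance (6MWD) must be reconstructed from GNSS fixes that arrive roughly
once per second, each carrying latitude, longitude, altitude, a reported
horizontal-accuracy radius ("confidence interval", meters), heading, speed,
and - when available - a cumulative step count and a mean acceleration
magnitude from the inertial sensors. Raw fixes are noisy: positions jump,
altitude disappears when the OS falls back to network positioning, stale
fixes are re-delivered, and accuracy degrades when the walker turns sharply.
`sixmwt` implements the full chain from raw trace to a reliability verdict:
exclusion filtering, resampling, six distance estimators, agreement
statistics, a 52-element quality feature vector, feature screening and
selection, cross-validated classifiers, and two published reference logistic
models - plus a seeded simulator that stands in for clinical recordings,
which are not redistributable.

## Pre-processing

`apply_filters()` removes samples by six ordered rules: missing altitude
(R1), accuracy radius above 25 m (R2), mean acceleration magnitude below
0.5 m/s² (R3, skipped without inertial data), zero step delta (R4, skipped
without step data), non-positive time delta (R5), and implied speed above
5 m/s (R6). Pairwise rules compare against the last *kept* sample, so one
corrupt fix cannot shield the next; a sample failing several rules is
attributed to the first, which affects per-rule counts but never the kept
set. The thresholds are the published defaults and are all configurable. An
optional leading trim (`trim_leading_lock`) reproduces the recording app's
requirement of one fix below 15 m accuracy before the test starts; it is off
by default because archived traces have already passed it.

`resample_1hz()` places samples on the integer-second grid, interpolating
coordinates linearly across gaps of at most 5 s and holding the last value
(padding) across longer ones. The resampled accuracy radius is the
pessimistic maximum of the two bracketing raw values; heading is recomputed
from consecutive grid positions because compass angles cannot be averaged
across the 0/360 wrap, and speed is recomputed as grid-step distance over
one second.

All geometry uses a sphere of radius 6,371,000 m - haversine distances and
initial bearings - and a local equirectangular east/north frame anchored at
the first sample for anything that needs meter-valued planar coordinates.
At walking scale (under 2 km) the frame agrees with the great-circle
distances to better than 0.1%.

## The six estimators

All six integrate distance between consecutive (estimated) positions and
return zero for traces with fewer than two usable samples.

* **baseline** - sums crow-flies distances between consecutive kept fixes.
  Noise inflates it: every jitter step adds length.
* **qss** - quality-based spatial subsampling: per tumbling 5 s window keep
  the fix with the smallest accuracy radius, then accept fixes sequentially
  only with positive time delta, implied speed at most 2 m/s, and differing
  step counts when steps exist. It runs on the raw trace - subsampling is
  its own noise defence - at the cost of cutting corners on curved paths.
* **alphabeta** - a steady-state position/velocity tracker per planar axis.
  The gains come from the tracking index λ = σ_w·T²/σ_n with the per-sample
  accuracy radius as σ_w and σ_n = 3 held constant: r = (4 + λ −
  √(8λ + λ²))/4, α = 1 − r², β = 2(2 − α) − 4√(1 − α). Large λ drives
  α → 1 (trust the measurement); λ = 0 freezes the filter, which is why the
  accuracy radius is floored at 0.01 m by default (`acc_floor_m`, can be
  disabled, degenerate behaviour covered in the tests). σ_n is treated as a
  dimensionless smoothing constant; its published units are inconsistent
  with its role, and its value, 3, is what matters operationally.
* **kalman1d** - independent position/velocity Kalman filters per axis,
  constant-velocity transition, process covariance built as the outer
  product of (6 m, 2 m/s), measurement variance the squared per-sample
  accuracy radius. The initial covariance is set to Q, a common
  self-consistent choice; the posterior forgets it within a few steps.
* **kalman2d** - one six-state constant-acceleration filter for both axes.
  Only the position/speed deviations are published for the process
  covariance; the extension adds an acceleration deviation of 1 m/s²
  (configurable) and keeps the same outer-product construction per axis,
  block-diagonal across axes.
* **kalmansmooth** - forward filter plus Rauch-Tung-Striebel backward pass
  on the state (latitude, longitude, speed), observing all three with the
  fixed covariance diag(1e-8, 1e-8, 1e4): degree-valued coordinate noise
  (≈ 11 m standard deviation) and a speed channel that is essentially
  ignored. This estimator deliberately keeps degree-valued coordinates - the
  published observation covariance only makes sense in degrees - while the
  other filters run in the metric frame so their meter-valued covariances
  are dimensionally coherent. The transition is a random walk; the process
  covariance is not published, so the package defaults to
  diag(5e-9 deg², 5e-9 deg², 0.01 (m/s)²). The coordinate value was chosen
  to give the filter enough bandwidth to follow a 1.3 m/s pedestrian
  (≈ 1.2e-5 deg/s) without lagging - about half the observation noise per
  step - while still averaging several seconds of measurements; much
  smaller values over-smooth gentle curvature and shorten every estimate,
  much larger ones stop smoothing at all. It is exposed as `q_coord`.

Covariances are symmetrized (P ← (P + Pᵀ)/2) after every update to stop
round-off asymmetry from accumulating over hundreds of steps.

## Agreement and the error band

`error_summary()` reports mean, standard deviation (sample, n−1) and maximum
of the absolute error, RMSE, and Bland-Altman limits of agreement
mean ± 1.96·sd over signed errors, with signs as estimate − reference;
percent mode divides by the reference first. `classify_error_band()`
dichotomizes the absolute error at 30 m - the minimal detectable change of
the 6MWD reported for conservative populations (28.1-33.5 m) - and assigns
the boundary itself to "low", a convention the published strict
inequalities leave open.

## The 52 quality features

Seven characteristic series are built from the filtered trace: turning angle
(`curve`, 0° = straight by convention; every monotone use is
convention-invariant), consecutive crow-flies distances (`crows`), speed
(`speed`, GNSS channel with a positional fallback), accuracy radius
(`quality`), heading (`heading`, GNSS channel with a bearing fallback),
wrapped heading differences (`deltaheading`), and inter-sample time deltas
(`fs`). Each is summarised by mean, median, standard deviation, IQR, the
value and lag of the first autocorrelation local maximum, and sample
entropy: 49 grid features, plus the percentage of samples with accuracy
above 15 m, the percentage with speed above 4 m/s, and the difference
between the unfiltered and filtered baseline distances - 52 in all. The
"52" arithmetic is the only consistent reading of the published count
(7 × 7 grid + 3 summative).

Sample entropy uses the standard parameters m = 2, r = 0.2·sd (unpublished
in the original; these are the field defaults) with Chebyshev distances; a
constant series scores 0, and when no template of length m + 1 matches, the
value is capped at log(B) + log(10) as a finite sentinel rather than
infinity. The autocorrelation peak is the first lag whose coefficient
strictly exceeds its predecessor and is at least its successor, searched to
lag n/2, with (0, 0) when none exists - also a choice the source leaves
open, fixed here and tested.

## Screening, selection, reduction, classification

`screen_features()` computes the point-biserial correlation (Pearson against
the 0/1 label, t-test p-value) and the two-sample Kolmogorov-Smirnov
statistic per feature, flagging p < 0.05. The KS test uses the exact null
distribution where available: at cohort-scale group sizes the asymptotic
approximation is conservative and would under-report the nominal level.

`rfe_select()` repeats recursive feature elimination five times. Each
repetition shuffles participants into ten grouped folds (all tests of a
participant stay together), ranks features by the mean absolute coefficient
of an L2-regularized logistic model across fold-wise fits on standardized
features, eliminates the weakest, and retains the subset size with the best
mean out-of-fold accuracy (ties favour fewer features). The consensus set
keeps features chosen in at least three of the five repetitions. The
recursion internals are unpublished; ridge regularization keeps the
rankings stable under separation and the grouped folds are what make the
five repetitions differ, mirroring repetition over different train/test
participants.

`vif_reduce()` iterates: while any variance inflation factor exceeds 2.5,
the worst feature and its most-correlated partner are replaced by the sum of
their standardized values, named `"a+b"`. Standardizing before summing is
required because raw feature scales differ by orders of magnitude; the
published combined names (medians plus IQRs) imply simple sums. The loop
terminates because every merge removes one column and a single column has
VIF 1.

`train_evaluate()` runs logistic regression, an RBF-kernel SVM (kernel
unpublished; RBF is the common default and configurable) and a random
forest under stratified 5-fold cross-validation. Standardization is fitted
per training fold and applied to its test fold - the original normalized
globally, which leaks test-fold moments into training; a
`global_standardize` flag restores the original behaviour for fidelity
runs. Out-of-fold scores are pooled and sensitivity, specificity, F1,
accuracy (threshold 0.5) and AUC are computed once on the pool. Odds ratios
are exponentiated coefficients of a full-data refit on standardized
features; whether the original refit on all data or averaged fold models is
unstated, and the refit is the interpretable choice.

## The reference models

Two published logistic models ship with the package
(`reference_model()`, `reference_predict()`): an error-based model
(probability that the baseline estimate errs by more than 30 m) over
standardized speed_iqr, curve_iqr, heading_sampen, fs_sampen and the
combined crows_median + fs_iqr; and a user-based model (probability of an
unconventionally performed test) over quality_sampen, heading_std,
curve_mean + curve_sampen, and deltaheading_mean + deltaheading_iqr. Their
coefficients are exact as printed; at standardized-zero input they give
P = 0.4452 and P = 0.7109 respectively, and exp(1.54) = 4.665 for the
delta-heading sum agrees with its printed odds ratio 4.64 to within
coefficient rounding. The original standardization statistics were never
published, so the default scaling is fitted on a packaged seeded synthetic
cohort (`inst/extdata/reference_scaling_synthetic.csv`, labelled synthetic);
absolute probabilities under that scaling are approximate, which is why the
package's tests assert only the closed-form values at standardized zero and
the monotonicity of each input with the sign of its printed coefficient.
Callers with their own population can supply scaling statistics via
`fit_reference_scaling()`.

## The simulator

`simulate_walk()` emulates the study's path taxonomy: `regular` (straight
with a gentle 1°/s-sd meander), `stop_and_go` (30-60 s walking alternating
with 15-30 s standing), `back_and_forth` (20 m legs joined by immediate
U-turns) and `circles0..3` (radii 15, 10, 6, 3 m - only "decreasing radius"
is documented; these values span gentle to tight turning). Walking speed is
1.3 m/s with 0.1 m/s per-second jitter, durations 180-360 s, cadence
≈ 1.8 steps/m, acceleration magnitude ≈ 1.2 m/s² walking and ≈ 0.05
standing - the latter two exist to exercise the stillness rules R3/R4.
`regular` and `stop_and_go` are conventional, the rest unconventional.

Observation noise is first-order Gauss-Markov per axis (correlation time
20 s, stationary sd 3 m): correlated noise is the minimal model under which
filtering helps rather than trivially removing white jitter. The noise sd
is inflated by 1 + turning-rate/10°/s (capped at 45°/s), encoding the
observation that positioning degrades with changes of direction; this is
what makes tight circles harder than straight walks, reproducing the
published ordering of per-path errors without touching the estimators. The
reported accuracy radius tracks the effective noise sd (floored at 3 m -
phones rarely report better - plus an exponential jitter of mean 1 m), so
quality-aware algorithms receive an informative channel. Artifacts are
injected per moving sample, mutually exclusively: teleport outliers
(50-200 m displacement, reported accuracy 26-60 m), stale fixes (the
previous position record re-delivered wholesale with current step/inertial
data), and missing-altitude fixes. Everything is deterministic given the
seed.

What the simulator does *not* emulate: multipath and urban-canyon error
structure, device heterogeneity, satellite-geometry drift, inertial
waveforms beyond the per-second magnitude, and human pacing strategy.
Passing tests therefore demonstrate algorithmic correctness and the
qualitative error structure - filtering helps, tight curves hurt,
unconventional walks are separable - not clinical-grade absolute error on
real recordings.

## Problem sizes and runtime choices

The packaged analyses run at desk scale: a 40-test cohort (10 participants
× 4 tests) for the filtering-benefit and path-ordering results, a 100-test
cohort (10 × 10, 50/50 class mix) for classification, 500-step tracks for
the smoother-optimality check, and 1000 null features at n = 200 for
screening calibration. These sizes keep the whole suite in a few minutes
while leaving the measured effects far from their decision boundaries.

## Known limitations

Absolute error magnitudes on the synthetic cohorts depend on the assumed
noise model and are larger than clinical recordings under open sky; only
orderings and comparative statements transfer. The smoother's process
covariance and the 2D filter's acceleration deviation are package choices
where the source is silent, exposed as arguments. Headings are treated as
an opaque angular channel - no magnetic-declination correction is applied,
since the reference frame of archived headings is unknowable downstream.
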