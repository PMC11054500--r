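# sixmwt

Quality-aware walked-distance estimation for smartphone-based outdoor
six-minute walk tests (6MWT).

The 6MWT is a standard clinical measure of functional capacity: the distance
a person can walk in six minutes. Recorded outdoors with a phone, that
distance must be reconstructed from a 1 Hz stream of GNSS fixes whose
quality varies second by second — positions jump, altitude drops out when
the OS falls back to network positioning, stale fixes get re-delivered, and
accuracy degrades whenever the walker turns. `sixmwt` provides the whole
analysis chain for such traces:

* **Pre-processing** — six ordered exclusion rules (missing altitude,
  accuracy radius > 25 m, acceleration magnitude < 0.5 m/s², zero step
  delta, non-positive time delta, implied speed > 5 m/s) with per-sample
  removal provenance, plus 1 Hz resampling with gap padding.
* **Six distance estimators** — crow-flies baseline; quality-based spatial
  subsampling (best fix per 5 s window); a steady-state alpha-beta tracker
  with gains from the tracking index λ (r = (4 + λ − √(8λ + λ²))/4,
  α = 1 − r², β = 2(2 − α) − 4√(1 − α)); per-axis and six-state Kalman
  filters with the squared per-fix accuracy radius as measurement variance;
  and a Rauch–Tung–Striebel smoother on (lat, lon, speed).
* **Agreement statistics** — mean/sd/max absolute error, RMSE and
  Bland–Altman limits of agreement (mean ± 1.96 sd of signed errors),
  with a 30 m minimal-detectable-change error band.
* **A 52-element quality feature vector** — seven characteristic series
  (curviness, point–point distance, speed, accuracy, heading, delta
  heading, time deltas) × seven statistics (mean, median, sd, IQR, first
  autocorrelation-peak value and lag, sample entropy), plus three summative
  features.
* **Screening, selection and classification** — point-biserial and
  Kolmogorov–Smirnov screening, recursive feature elimination over
  participant-grouped folds, variance-inflation-factor reduction at 2.5,
  and logistic / SVM / random-forest classifiers under stratified 5-fold
  cross-validation, with odds ratios from the logistic refit.
* **Published reference logistic models** — error-based and user-based
  equations with their printed coefficients, for scoring new tests.
* **A seeded walk simulator** — regular, stop-and-go, back-and-forth
  (20 m legs) and four circle paths with correlated, curvature-dependent
  GNSS noise and injected artifacts, with exact ground-truth distances.

## Worked example

Simulate a noisy six-minute regular walk, filter it, and estimate the
distance with all six algorithms:

```r
library(sixmwt)

sw <- simulate_walk("regular", duration_s = 360, seed = 42)
fr <- apply_filters(sw$trace)
fr
#> <filter_report> kept 335 of 361 samples
#>   rule  n_removed
#> 1 R1           14
#> 2 R2            6
#> 3 R5            6

estimate_distances(sw$trace)[, 1:3]
#>   algorithm    distance_m n_samples_used
#> 1 baseline           637.            335
#> 2 qss                495.             62
#> 3 alphabeta          597.            361
#> 4 kalman1d           584.            361
#> 5 kalman2d           594.            361
#> 6 kalmansmooth       498.            361

sw$true_distance_m
#> [1] 467
```

The trace was walked for 467 m; 26 of 361 fixes are excluded (no altitude,
poor accuracy, stale timestamps), and the estimators bracket the truth from
above — correlated GNSS noise always adds path length to the crow-flies sum,
while subsampling (qss) and smoothing (kalmansmooth) remove most of it.

Train the reliability classifiers on a simulated cohort (10 participants ×
10 tests, half performed unconventionally) using the user-based feature
set, collinearity-reduced:

```r
co  <- simulate_cohort(n_participants = 10, tests_per_participant = 10, seed = 5)
fe  <- cohort_features(co)
red <- vif_reduce(fe[, unique(unlist(reference_model("user_based")$bindings))])
train_evaluate(red$features, fe$label == "unconventional", seed = 5)
#> <classifier_report> 5-fold stratified CV (seed 5)
#>   model sensitivity specificity    f1 accuracy   auc
#> 1 lr           0.96        0.96 0.96      0.96 0.978
#> 2 svm          1           0.96 0.980     0.98 0.993
#> 3 rf           1           0.94 0.971     0.97 1
```

Unconventional walks (sharp turns, circles, back-and-forth) are separated
from conventional ones essentially perfectly on synthetic data; the same
pipeline applies unchanged to real trace tables.

A thin command-line wrapper over the same functions ships at
`inst/cli/sixmwt-cli.R` (subcommands `simulate`, `preprocess`, `distance`,
`features`, `evaluate-agreement`, `classify`, `run-pipeline`).

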