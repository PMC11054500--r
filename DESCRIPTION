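Package: sixmwt
Title: Quality-Aware Distance Estimation for Smartphone-Based Outdoor
    Six-Minute Walk Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing GNSS traces recorded during outdoor
    six-minute walk tests (6MWT). Implements sample-level noise filtering
    with per-sample removal provenance, 1 Hz resampling, six walked-distance
    estimators (crow-flies baseline, quality-based spatial subsampling,
    alpha-beta tracking, one- and two-dimensional Kalman filters, and a
    Rauch-Tung-Striebel smoother), Bland-Altman agreement statistics, a
    52-element signal-quality feature vector (curviness, heading, speed,
    accuracy and sampling statistics including sample entropy), feature
    screening and selection (point-biserial and Kolmogorov-Smirnov tests,
    recursive feature elimination, variance-inflation-factor reduction),
    cross-validated classifiers that flag unreliable tests, published
    reference logistic models, and a seeded synthetic-walk simulator with
    ground-truth distances for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    xml2,
    ggplot2,
    generics,
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
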