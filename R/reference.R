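#' Published reference logistic models for test reliability
#'
#' The two logistic models shipped with the package score a walk test from
#' its quality features:
#'
#' * `error_based`: probability that the crow-flies distance estimate errs by
#'   more than the 30 m minimal detectable change.
#'   `z = -0.22 + 0.26 X1 + 0.52 X2 + 0.51 X3 - 0.18 X4 + 0.26 X5` with
#'   `X1 = speed_iqr`, `X2 = curve_iqr`, `X3 = heading_sampen`,
#'   `X4 = fs_sampen`, `X5 = crows_median + fs_iqr` (standardized sum).
#' * `user_based`: probability that the walk was performed unconventionally
#'   (not following the straight-path instructions).
#'   `z = 0.90 + 1.03 X1 + 0.81 X2 - 2.65 X3 + 1.54 X4` with
#'   `X1 = quality_sampen`, `X2 = heading_std`,
#'   `X3 = curve_mean + curve_sampen`, `X4 = deltaheading_mean +
#'   deltaheading_iqr`.
#'
#' Inputs are standardized before entering the linear predictor. The original
#' standardization statistics were never published, so the default scaling
#' shipped in `inst/extdata/reference_scaling_synthetic.csv` is fitted on a
#' seeded synthetic cohort (see [fit_reference_scaling()]); absolute
#' probabilities under the default scaling are therefore approximate, while
#' the model structure and coefficients are exact.
#'
#' @param model `"error_based"` or `"user_based"`.
#' @return `reference_model()` returns the model definition: list with
#'   `intercept`, `coefficients` (named), and `bindings` (named list mapping
#'   each input to its constituent feature(s)).
#' @export
reference_model <- function(model = c("error_based", "user_based")) {
  model <- match.arg(model)
  if (model == "error_based") {
    list(
      model = model,
      intercept = -0.22,
      coefficients = c(X1 = 0.26, X2 = 0.52, X3 = 0.51, X4 = -0.18, X5 = 0.26),
      bindings = list(
        X1 = "speed_iqr",
        X2 = "curve_iqr",
        X3 = "heading_sampen",
        X4 = "fs_sampen",
        X5 = c("crows_median", "fs_iqr")
      )
    )
  } else {
    list(
      model = model,
      intercept = 0.90,
      coefficients = c(X1 = 1.03, X2 = 0.81, X3 = -2.65, X4 = 1.54),
      bindings = list(
        X1 = "quality_sampen",
        X2 = "heading_std",
        X3 = c("curve_mean", "curve_sampen"),
        X4 = c("deltaheading_mean", "deltaheading_iqr")
      )
    )
  }
}

reference_inputs <- function(features, model, scaling) {
  ref <- reference_model(model)
  needed <- unique(unlist(ref$bindings))
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    abort(paste0("missing feature(s) for the ", model, " reference model: ",
                 paste(missing, collapse = ", ")))
  }
  std <- function(nm, v) {
    row <- scaling[scaling$feature == nm, ]
    if (nrow(row) != 1) abort(paste0("no standardization statistics for ", nm))
    s <- if (row$sd == 0) 1 else row$sd
    (v - row$mean) / s
  }
  vals <- map(ref$bindings, function(parts) {
    Reduce(`+`, map(parts, function(nm) std(nm, features[[nm]])))
  })
  as_tibble(vals)
}

#' @rdname reference_model
#' @param features data frame (one or more rows) containing the bound feature
#'   columns, on their raw scale.
#' @param scaling standardization statistics: tibble with columns `feature`,
#'   `mean`, `sd` covering every bound feature. Defaults to the packaged
#'   synthetic-cohort statistics.
#' @return `reference_predict()` returns a numeric vector of probabilities in
#'   (0, 1), one per input row.
#' @export
reference_predict <- function(features, model = c("error_based", "user_based"),
                              scaling = default_reference_scaling()) {
  model <- match.arg(model)
  ref <- reference_model(model)
  X <- reference_inputs(features, model, scaling)
  z <- ref$intercept + as.matrix(X) %*% ref$coefficients
  as.numeric(1 / (1 + exp(-z)))
}

#' Standardization statistics for the reference models
#'
#' `fit_reference_scaling()` computes per-feature mean and standard deviation
#' from a table of extracted features; `default_reference_scaling()` loads the
#' packaged statistics, which were fitted on a seeded synthetic cohort (the
#' original study's scaling was not published).
#'
#' @param features data frame of feature columns.
#' @return tibble with columns `feature`, `mean`, `sd`.
#' @export
fit_reference_scaling <- function(features) {
  tibble(
    feature = names(features),
    mean = map_dbl(features, mean),
    sd = map_dbl(features, sd)
  )
}

#' @rdname fit_reference_scaling
#' @export
default_reference_scaling <- function() {
  path <- system.file("extdata", "reference_scaling_synthetic.csv",
                      package = "sixmwt", mustWork = TRUE)
  readr::read_csv(path, col_types = "cdd")
}
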