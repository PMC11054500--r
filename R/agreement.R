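#' Agreement statistics between estimated and reference distances
#'
#' Computes the error statistics used to compare estimators against the
#' trundle-wheel reference: mean, standard deviation and maximum of the
#' absolute error, RMSE, and the Bland-Altman limits of agreement
#' (mean signed error plus/minus 1.96 standard deviations). Signed error is
#' `estimate - reference`; in percent mode every error is
#' `100 * (estimate - reference) / reference`.
#'
#' @param pairs data frame with columns `reference_m` and `estimate_m`
#'   (extra columns such as `trace_id` are carried through to [tidy()]).
#' @param mode `"absolute_m"` (meters) or `"percent"`.
#' @return An `error_summary` object; see [glance.error_summary()].
#' @export
error_summary <- function(pairs, mode = c("absolute_m", "percent")) {
  mode <- match.arg(mode)
  if (!all(c("reference_m", "estimate_m") %in% names(pairs))) {
    abort("pairs needs columns reference_m and estimate_m")
  }
  if (nrow(pairs) == 0) abort("no estimate/reference pairs supplied")
  signed <- pairs$estimate_m - pairs$reference_m
  if (mode == "percent") {
    if (any(pairs$reference_m <= 0)) {
      abort("percent mode requires strictly positive reference distances")
    }
    signed <- 100 * signed / pairs$reference_m
  }
  s <- if (length(signed) > 1) sd(signed) else 0
  m <- mean(signed)
  structure(
    list(
      n = length(signed),
      mode = mode,
      mean_signed = m,
      sd_signed = s,
      mean_abs = mean(abs(signed)),
      sd_abs = if (length(signed) > 1) sd(abs(signed)) else 0,
      max_abs = max(abs(signed)),
      rmse = sqrt(mean(signed^2)),
      loa_low = m - 1.96 * s,
      loa_high = m + 1.96 * s,
      errors = tibble(pairs, signed_error = signed)
    ),
    class = "error_summary"
  )
}

#' @export
print.error_summary <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else "m"
  cat(sprintf("<error_summary> n = %d\n", x$n))
  cat(sprintf("  |error|: mean %.2f%s (sd %.2f), max %.2f%s, RMSE %.2f%s\n",
              x$mean_abs, unit, x$sd_abs, x$max_abs, unit, x$rmse, unit))
  cat(sprintf("  limits of agreement: [%.2f, %.2f] %s\n",
              x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' Broom-style accessors for agreement summaries
#'
#' `tidy()` returns the per-pair signed errors; `glance()` the one-row
#' statistics table.
#'
#' @param x an `error_summary`.
#' @param ... unused.
#' @export
tidy.error_summary <- function(x, ...) x$errors

#' @rdname tidy.error_summary
#' @export
glance.error_summary <- function(x, ...) {
  tibble(
    n = x$n, mode = x$mode,
    mean_abs = x$mean_abs, sd_abs = x$sd_abs, max_abs = x$max_abs,
    rmse = x$rmse, mean_signed = x$mean_signed, sd_signed = x$sd_signed,
    loa_low = x$loa_low, loa_high = x$loa_high
  )
}

#' Classify a test's absolute error as low or high
#'
#' Dichotomizes the absolute distance error at the minimal-detectable-change
#' threshold (default 30 m). The boundary itself is classified as `"low"`.
#'
#' @param abs_error_m non-negative absolute error(s), meters.
#' @param threshold_m band boundary, meters (default 30).
#' @return character vector of `"low"` / `"high"`.
#' @export
classify_error_band <- function(abs_error_m, threshold_m = 30) {
  if (any(abs_error_m < 0, na.rm = TRUE)) abort("absolute error must be non-negative")
  ifelse(abs_error_m <= threshold_m, "low", "high")
}
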