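#' Turning-angle (curviness) series of a planar track
#'
#' Angle between the incoming and outgoing segment directions at each
#' interior point of the track, in degrees in `[0, 180]`; 0 means straight
#' ahead, 180 an immediate U-turn.
#'
#' @param points data frame with planar columns `x`, `y` (see [to_enu()]).
#' @return numeric vector of length `nrow(points) - 2` (empty if fewer than
#'   3 points).
#' @export
curviness_series <- function(points) {
  n <- nrow(points)
  if (n < 3) return(numeric(0))
  dx <- diff(points$x)
  dy <- diff(points$y)
  # direction change between consecutive segments
  a1 <- atan2(dy[-(n - 1)], dx[-(n - 1)])
  a2 <- atan2(dy[-1], dx[-1])
  d <- abs((a2 - a1 + pi) %% (2 * pi) - pi) * 180 / pi
  # a zero-length segment has no direction; treat the turn as 0
  zero <- (dx[-(n - 1)] == 0 & dy[-(n - 1)] == 0) | (dx[-1] == 0 & dy[-1] == 0)
  d[zero] <- 0
  d
}

#' Circular difference of consecutive headings
#'
#' Differences of consecutive heading values wrapped to `(-180, 180]`, so a
#' 350 to 10 degree transition reads +20, not -340.
#'
#' @param headings numeric vector of headings in degrees.
#' @return numeric vector of length `length(headings) - 1`.
#' @export
delta_heading_series <- function(headings) {
  if (length(headings) < 2) return(numeric(0))
  d <- diff(headings)
  -((-d + 180) %% 360 - 180)
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -log(A / B), where B counts pairs of length-`m` templates
#' within Chebyshev distance `r` and A the same for length `m + 1`
#' (self-matches excluded). A constant series returns 0 by convention; when
#' no length-`m + 1` matches exist the value is capped at `log(B) + log(10)`
#' as a finite sentinel.
#'
#' @param series numeric vector, length at least `m + 2`.
#' @param m template length (default 2).
#' @param r tolerance; defaults to `0.2 * sd(series)`.
#' @return non-negative scalar.
#' @export
sample_entropy <- function(series, m = 2, r = NULL) {
  n <- length(series)
  if (n < m + 2) abort("series too short for sample entropy")
  if (sd(series) == 0) return(0)
  if (is.null(r)) r <- 0.2 * sd(series)
  # Chebyshev template distances via a running max over the lag-difference matrix
  D <- abs(outer(series, series, "-"))
  nt <- n - m  # number of templates compared for both m and m + 1
  Dm <- D[seq_len(nt), seq_len(nt)]
  if (m > 1) {
    for (k in seq_len(m - 1)) {
      Dm <- pmax(Dm, D[seq_len(nt) + k, seq_len(nt) + k])
    }
  }
  Dm1 <- pmax(Dm, D[seq_len(nt) + m, seq_len(nt) + m])
  B <- (sum(Dm <= r) - nt) / 2   # exclude self-matches, count unordered pairs
  A <- (sum(Dm1 <= r) - nt) / 2
  if (B == 0) return(0)
  if (A == 0) return(log(B) + log(10))
  -log(A / B)
}

#' First local maximum of the autocorrelation function
#'
#' Biased, normalized autocorrelation over lags `1 .. n/2`; returns the value
#' and lag of the first local maximum (strictly above the previous lag, at
#' least the next). Returns `(0, 0)` for constant or too-short series or when
#' no peak exists.
#'
#' @param series numeric vector.
#' @return tibble with columns `value`, `lag`.
#' @export
autocorr_first_peak <- function(series) {
  n <- length(series)
  none <- tibble(value = 0, lag = 0L)
  if (n < 3 || sd(series) == 0) return(none)
  lag_max <- floor(n / 2)
  rho <- as.numeric(acf(series, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)[-1]  # drop lag 0
  L <- length(rho)
  if (L < 2) return(none)
  for (k in 2:L) {
    nxt <- if (k < L) rho[k + 1] else -Inf
    if (rho[k] > rho[k - 1] && rho[k] >= nxt) {
      return(tibble(value = rho[k], lag = as.integer(k)))
    }
  }
  none
}

series_stats <- function(x, sampen_m = 2) {
  x <- x[!is.na(x)]
  short <- function(need) length(x) < need
  if (length(x) == 0) {
    warn("empty characteristic series; its statistics are set to 0")
    return(tibble(mean = 0, median = 0, std = 0, iqr = 0,
                  ac1value = 0, ac1lag = 0, sampen = 0))
  }
  pk <- autocorr_first_peak(x)
  se <- if (short(sampen_m + 2) || sd(x) == 0) {
    if (short(sampen_m + 2)) warn("series too short for sample entropy; set to 0")
    0
  } else sample_entropy(x, m = sampen_m)
  tibble(
    mean = mean(x),
    median = median(x),
    std = if (length(x) > 1) sd(x) else 0,
    iqr = if (length(x) > 1) stats::IQR(x) else 0,
    ac1value = pk$value,
    ac1lag = as.numeric(pk$lag),
    sampen = se
  )
}

feature_characteristics <- function() {
  c("curve", "crows", "speed", "quality", "heading", "deltaheading", "fs")
}

feature_stat_names <- function() {
  c("mean", "median", "std", "iqr", "ac1value", "ac1lag", "sampen")
}

#' Names of the 52 quality features
#'
#' The 49 grid features `<characteristic>_<statistic>` over characteristics
#' curve (turning angle), crows (consecutive crow-flies distances), speed,
#' quality (accuracy radius), heading, deltaheading and fs (time deltas),
#' plus the three summative features `q_above_tr`, `s_above_tr`,
#' `delta_distance`.
#'
#' @return character vector of length 52, in canonical order.
#' @export
feature_names <- function() {
  grid <- as.vector(t(outer(feature_characteristics(), feature_stat_names(),
                            paste, sep = "_")))
  c(grid, "q_above_tr", "s_above_tr", "delta_distance")
}

#' Extract the 52-element signal-quality feature vector of a trace
#'
#' Builds the seven characteristic series from the filtered trace - turning
#' angle (`curve`), consecutive crow-flies distances (`crows`), point-wise
#' speed (`speed`; GNSS speed with a positional fallback), accuracy radius
#' (`quality`), heading (`heading`; GNSS heading with a bearing fallback),
#' consecutive heading differences (`deltaheading`) and inter-sample time
#' deltas (`fs`) - and summarises each with mean, median, standard deviation,
#' IQR, first autocorrelation-peak value and lag, and sample entropy.
#' Three summative features are added: the percentage of samples with
#' accuracy radius above `quality_tr_m`, the percentage with speed above
#' `speed_tr_ms`, and the difference between the unfiltered and filtered
#' crow-flies distance estimates.
#'
#' @param filtered the trace after [apply_filters()].
#' @param unfiltered the corresponding raw trace (defaults to `filtered`,
#'   giving `delta_distance = 0`).
#' @param quality_tr_m accuracy threshold for `q_above_tr` (default 15 m).
#' @param speed_tr_ms speed threshold for `s_above_tr` (default 4 m/s).
#' @return one-row tibble with 52 feature columns in [feature_names()] order.
#' @export
extract_features <- function(filtered, unfiltered = filtered,
                             quality_tr_m = 15, speed_tr_ms = 4) {
  if (nrow(filtered) == 0 || nrow(unfiltered) == 0) {
    abort("feature extraction needs non-empty traces")
  }
  n <- nrow(filtered)
  enu <- to_enu(filtered)
  crows <- if (n >= 2) {
    haversine_m(filtered$lat[-n], filtered$lon[-n],
                filtered$lat[-1], filtered$lon[-1])
  } else numeric(0)
  dt <- if (n >= 2) diff(filtered$t) else numeric(0)

  speed <- filtered$speed
  if (n >= 2) {
    fallback <- c(crows / dt, NA_real_)
    speed <- ifelse(is.na(speed), fallback, speed)
  }

  heading <- filtered$heading
  if (n >= 2) {
    moved <- crows > 0
    hb <- rep(NA_real_, n - 1)
    if (any(moved)) {
      hb[moved] <- bearing_deg(filtered$lat[-n][moved], filtered$lon[-n][moved],
                               filtered$lat[-1][moved], filtered$lon[-1][moved])
    }
    fallback <- c(hb, hb[length(hb)])
    heading <- ifelse(is.na(heading), fallback, heading)
  }

  series <- list(
    curve = curviness_series(enu),
    crows = crows,
    speed = speed,
    quality = filtered$acc,
    heading = heading,
    deltaheading = delta_heading_series(heading[!is.na(heading)]),
    fs = dt
  )
  grid <- imap(series, function(s, nm) {
    st <- series_stats(s)
    setNames(st, paste0(nm, "_", names(st)))
  })
  out <- dplyr::bind_cols(grid[feature_characteristics()])

  acc_ok <- filtered$acc[!is.na(filtered$acc)]
  sp_ok <- speed[!is.na(speed)]
  out$q_above_tr <- if (length(acc_ok)) 100 * mean(acc_ok > quality_tr_m) else 0
  out$s_above_tr <- if (length(sp_ok)) 100 * mean(sp_ok > speed_tr_ms) else 0
  out$delta_distance <- distance_baseline(unfiltered)$distance_m -
    distance_baseline(filtered)$distance_m
  out[, feature_names()]
}
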