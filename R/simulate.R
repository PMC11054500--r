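#' Noise configuration for the walk simulator
#'
#' Observation noise is a first-order Gauss-Markov (exponentially correlated)
#' process per east/north axis. Its standard deviation is inflated with the
#' instantaneous turning rate of the true path - smartphone positioning
#' degrades with changes of direction - which is what makes tight circular
#' paths harder than straight ones. The reported accuracy radius tracks the
#' effective noise level (never below `acc_floor_m`, plus a positive jitter),
#' so quality-aware algorithms have an informative channel to work with.
#' Gross artifacts are injected per sample while the walker is moving:
#' teleport outliers (large displacement plus a large reported accuracy),
#' stale fixes (the previous position and timestamp re-delivered with current
#' step/inertial data), and fixes without altitude (non-satellite positioning).
#'
#' @param position_sd_m stationary noise standard deviation per axis, meters.
#' @param tau_s noise correlation time, seconds.
#' @param curvature_gain accuracy-degradation gain: the noise sd is multiplied
#'   by `1 + curvature_gain * turning rate (deg/s)`.
#' @param acc_floor_m minimum reported accuracy radius, meters.
#' @param acc_jitter_m mean of the exponential positive jitter added to the
#'   reported accuracy, meters.
#' @param heading_sd_deg observation noise on the heading channel, degrees.
#' @param speed_sd_ms observation noise on the speed channel, m/s.
#' @param outlier_prob per-sample probability of a teleport outlier.
#' @param outlier_range_m displacement range of an outlier, meters.
#' @param stale_prob per-sample probability of a stale (repeated) fix.
#' @param missing_alt_prob per-sample probability of a missing-altitude fix.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(position_sd_m = 3,
                         tau_s = 20,
                         curvature_gain = 1 / 10,
                         acc_floor_m = 3,
                         acc_jitter_m = 1,
                         heading_sd_deg = 5,
                         speed_sd_ms = 0.1,
                         outlier_prob = 0.02,
                         outlier_range_m = c(50, 200),
                         stale_prob = 0.01,
                         missing_alt_prob = 0.02) {
  probs <- c(outlier_prob, stale_prob, missing_alt_prob)
  if (any(probs < 0 | probs > 1)) abort("artifact probabilities must be in [0, 1]")
  if (position_sd_m < 0 || tau_s <= 0 || acc_floor_m < 0 || acc_jitter_m < 0) {
    abort("noise scales must be non-negative (tau_s positive)")
  }
  structure(
    list(position_sd_m = position_sd_m, tau_s = tau_s,
         curvature_gain = curvature_gain, acc_floor_m = acc_floor_m,
         acc_jitter_m = acc_jitter_m, heading_sd_deg = heading_sd_deg,
         speed_sd_ms = speed_sd_ms, outlier_prob = outlier_prob,
         outlier_range_m = outlier_range_m, stale_prob = stale_prob,
         missing_alt_prob = missing_alt_prob),
    class = "noise_config"
  )
}

#' Noise-free simulator configuration
#'
#' Convenience preset: no positional noise, no artifacts; the accuracy,
#' heading and speed channels keep their floor/jitter behaviour so the
#' filters still see realistic metadata.
#' @export
noise_off <- function() {
  noise_config(position_sd_m = 0, heading_sd_deg = 0, speed_sd_ms = 0,
               outlier_prob = 0, stale_prob = 0, missing_alt_prob = 0)
}

#' Simulate one outdoor walk test
#'
#' Generates a 1 Hz true path of the requested family, then overlays
#' correlated observation noise and artifacts (see [noise_config()]) to
#' produce a `walk_trace` with a known ground-truth distance.
#'
#' Path families: `regular` (straight with a gentle meander), `stop_and_go`
#' (walking intervals of 30-60 s alternating with 15-30 s standing still),
#' `back_and_forth` (20 m legs joined by immediate U-turns), and
#' `circles0`..`circles3` (circular paths of decreasing radius, defaults
#' 15, 10, 6 and 3 m). `regular` and `stop_and_go` are labelled
#' `conventional`; the others `unconventional`.
#'
#' @param path_type one of the seven families above.
#' @param duration_s test duration in seconds (study range 180-360).
#' @param speed_mps mean walking speed (default 1.3 m/s).
#' @param speed_jitter_sd per-second speed jitter standard deviation
#'   (default 0.1 m/s; 0 gives a perfectly constant speed).
#' @param leg_length_m leg length for `back_and_forth` (default 20 m).
#' @param circle_radii_m radii of `circles0`..`circles3`, strictly
#'   decreasing (default 15, 10, 6, 3 m).
#' @param noise a [noise_config()].
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @param origin latitude/longitude of the local frame origin.
#' @param participant_id id stored in the trace metadata.
#' @return A `simulated_walk`: list with `trace` (a `walk_trace` whose
#'   `reference_distance_m` is the true distance), `true_path` (tibble of
#'   east/north meters), `true_distance_m`, `path_type`, `label`.
#' @export
simulate_walk <- function(path_type = "regular",
                          duration_s = 360,
                          speed_mps = 1.3,
                          speed_jitter_sd = 0.1,
                          leg_length_m = 20,
                          circle_radii_m = c(15, 10, 6, 3),
                          noise = noise_config(),
                          seed = 1,
                          origin = c(lat = 55.60, lon = 13.00),
                          participant_id = "p01") {
  path_type <- match.arg(path_type, setdiff(path_types(), "unknown"))
  if (duration_s <= 2) abort("duration_s must exceed 2 seconds")
  if (speed_mps <= 0 || speed_jitter_sd < 0) abort("invalid speed parameters")
  if (any(diff(circle_radii_m) >= 0)) {
    abort("circle radii must be strictly decreasing")
  }
  set.seed(seed %% .Machine$integer.max)

  n_seg <- as.integer(duration_s)          # one segment per second
  v <- pmax(0.1, rnorm(n_seg, speed_mps, speed_jitter_sd))
  moving <- rep(TRUE, n_seg)

  if (path_type == "stop_and_go") {
    i <- 1L
    walking <- TRUE
    while (i <= n_seg) {
      len <- if (walking) sample(30:60, 1) else sample(15:30, 1)
      j <- min(n_seg, i + len - 1L)
      if (!walking) moving[i:j] <- FALSE
      walking <- !walking
      i <- j + 1L
    }
    v[!moving] <- 0
  }

  # heading profile, degrees clockwise from north
  theta <- numeric(n_seg)
  theta0 <- runif(1, 0, 360)
  if (path_type %in% c("regular", "stop_and_go")) {
    theta <- theta0 + cumsum(rnorm(n_seg, 0, 1))  # gentle meander
  } else if (path_type == "back_and_forth") {
    walked <- 0
    dir <- 0
    for (k in seq_len(n_seg)) {
      if (walked + v[k] > leg_length_m) {
        dir <- dir + 180
        walked <- 0
      }
      walked <- walked + v[k]
      theta[k] <- theta0 + dir
    }
  } else {
    r <- circle_radii_m[as.integer(sub("circles", "", path_type)) + 1L]
    turn <- (v / r) * 180 / pi            # deg per second
    theta <- theta0 + cumsum(turn)
  }

  dx <- v * sin(theta * pi / 180)
  dy <- v * cos(theta * pi / 180)
  x <- c(0, cumsum(dx))
  y <- c(0, cumsum(dy))
  n <- n_seg + 1L
  true_distance <- sum(v)

  # per-sample turning rate of the true path, for noise inflation
  turn_rate <- c(0, abs(delta_heading_series(theta)), 0)
  if (length(turn_rate) != n) turn_rate <- rep_len(turn_rate, n)
  sd_eff <- noise$position_sd_m * (1 + noise$curvature_gain * pmin(turn_rate, 45))

  ar_unit <- function(n, tau) {
    phi <- exp(-1 / tau)
    e <- numeric(n)
    e[1] <- rnorm(1)
    for (k in 2:n) e[k] <- phi * e[k - 1] + sqrt(1 - phi^2) * rnorm(1)
    e
  }
  ex <- ar_unit(n, noise$tau_s) * sd_eff
  ey <- ar_unit(n, noise$tau_s) * sd_eff

  obs_x <- x + ex
  obs_y <- y + ey
  acc <- pmax(noise$acc_floor_m, sd_eff) + rexp(n, 1 / max(noise$acc_jitter_m, 1e-6))

  seg_mov <- c(moving, moving[n_seg])     # per-sample moving flag
  heading_obs <- (c(theta, theta[n_seg]) +
                    rnorm(n, 0, noise$heading_sd_deg)) %% 360
  speed_obs <- pmax(0, c(v, v[n_seg]) + rnorm(n, 0, noise$speed_sd_ms))
  steps <- round(cumsum(c(0, 1.8 * v)))   # cadence ~1.8 steps per meter
  accel <- ifelse(seg_mov,
                  pmax(0, 1.2 + rnorm(n, 0, 0.1)),
                  pmax(0, 0.05 + rnorm(n, 0, 0.01)))
  alt <- 20 + cumsum(rnorm(n, 0, 0.05))
  tstamp <- as.numeric(seq_len(n) - 1L)

  # artifacts: mutually exclusive per sample, only while moving (so the
  # stale/outlier is attributable to R5/R6-R2 rather than the stillness rules)
  u <- runif(n)
  u[1] <- 1  # never on the first sample
  is_out <- u < noise$outlier_prob & seg_mov
  is_stale <- !is_out & u < noise$outlier_prob + noise$stale_prob & seg_mov
  is_noalt <- !is_out & !is_stale &
    u < noise$outlier_prob + noise$stale_prob + noise$missing_alt_prob

  if (any(is_out)) {
    k <- which(is_out)
    disp <- runif(length(k), noise$outlier_range_m[1], noise$outlier_range_m[2])
    ang <- runif(length(k), 0, 2 * pi)
    obs_x[k] <- obs_x[k] + disp * sin(ang)
    obs_y[k] <- obs_y[k] + disp * cos(ang)
    acc[k] <- runif(length(k), 26, 60)
  }
  if (any(is_stale)) {
    # the positioning system re-delivers the previous fix wholesale; the
    # step/inertial channels come from a different subsystem and stay current
    for (k in which(is_stale)) {
      tstamp[k] <- tstamp[k - 1]
      obs_x[k] <- obs_x[k - 1]
      obs_y[k] <- obs_y[k - 1]
      alt[k] <- alt[k - 1]
      acc[k] <- acc[k - 1]
      heading_obs[k] <- heading_obs[k - 1]
      speed_obs[k] <- speed_obs[k - 1]
    }
  }
  alt[is_noalt] <- NA_real_

  ll <- enu_to_latlon(obs_x, obs_y, origin[["lat"]], origin[["lon"]])
  trace <- walk_trace(
    tibble(t = tstamp, lat = ll$lat, lon = ll$lon, alt = alt, acc = acc,
           heading = heading_obs, speed = speed_obs, steps = steps,
           accel_mag = accel),
    participant_id = participant_id,
    path_type = path_type,
    label = if (path_type %in% c("regular", "stop_and_go")) "conventional" else "unconventional",
    reference_distance_m = true_distance
  )
  structure(
    list(trace = trace,
         true_path = tibble(x = x, y = y),
         true_distance_m = true_distance,
         path_type = path_type,
         label = attr(trace, "label"),
         artifacts = tibble(index = seq_len(n),
                            outlier = is_out, stale = is_stale,
                            missing_alt = is_noalt)),
    class = "simulated_walk"
  )
}

#' @export
print.simulated_walk <- function(x, ...) {
  cat(sprintf("<simulated_walk> %s (%s), true distance %.1f m, %d samples\n",
              x$path_type, x$label, x$true_distance_m, nrow(x$trace)))
  invisible(x)
}

#' Simulate a cohort of walk tests
#'
#' Generates `tests_per_participant` tests for each of `n_participants`
#' synthetic participants, with a per-participant walking-speed offset and
#' stable participant ids (usable as the grouping unit for cross-validation).
#' The conventional/unconventional split follows `class_mix`; path families
#' cycle within each class (regular, stop-and-go for conventional;
#' back-and-forth and the four circle radii for unconventional), and test
#' durations cycle over 180-360 s.
#'
#' @param n_participants number of participants (at least 2).
#' @param tests_per_participant tests per participant.
#' @param class_mix named numeric `c(conventional = , unconventional = )`,
#'   summing to 1.
#' @param noise a [noise_config()] shared by all tests.
#' @param seed root seed; every per-test seed derives from it.
#' @param ... further arguments passed to [simulate_walk()].
#' @return tibble with one row per test: `participant_id`, `test_id`,
#'   `path_type`, `label`, `duration_s`, `true_distance_m`, and list-columns
#'   `trace`, `true_path`.
#' @export
simulate_cohort <- function(n_participants = 10,
                            tests_per_participant = 10,
                            class_mix = c(conventional = 0.5, unconventional = 0.5),
                            noise = noise_config(),
                            seed = 1,
                            ...) {
  if (n_participants < 2) abort("need at least 2 participants")
  if (!setequal(names(class_mix), c("conventional", "unconventional")) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    abort("class_mix must be c(conventional = , unconventional = ) summing to 1")
  }
  set.seed(seed %% .Machine$integer.max)
  speed_offsets <- rnorm(n_participants, 0, 0.1)
  trace_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_participants * tests_per_participant)
  conv_cycle <- c("regular", "stop_and_go")
  unconv_cycle <- c("back_and_forth", paste0("circles", 0:3))
  durations <- c(360, 300, 240, 180)
  n_conv <- round(class_mix[["conventional"]] * tests_per_participant)

  idx <- 0L
  conv_i <- 0L
  unconv_i <- 0L
  rows <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    # cycle the path families globally so every family appears in any
    # reasonably sized cohort
    types <- character(tests_per_participant)
    for (k in seq_len(tests_per_participant)) {
      if (k <= n_conv) {
        conv_i <- conv_i + 1L
        types[k] <- conv_cycle[(conv_i - 1L) %% length(conv_cycle) + 1L]
      } else {
        unconv_i <- unconv_i + 1L
        types[k] <- unconv_cycle[(unconv_i - 1L) %% length(unconv_cycle) + 1L]
      }
    }
    for (k in seq_len(tests_per_participant)) {
      idx <- idx + 1L
      dur <- durations[(idx - 1L) %% length(durations) + 1L]
      sw <- simulate_walk(
        path_type = types[k],
        duration_s = dur,
        speed_mps = max(0.6, 1.3 + speed_offsets[p]),
        noise = noise,
        seed = trace_seeds[idx],
        participant_id = pid,
        ...
      )
      rows[[idx]] <- tibble(
        participant_id = pid,
        test_id = sprintf("%s_t%02d", pid, k),
        path_type = sw$path_type,
        label = sw$label,
        duration_s = dur,
        true_distance_m = sw$true_distance_m,
        trace = list(sw$trace),
        true_path = list(sw$true_path)
      )
    }
  }
  bind_rows(rows)
}
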