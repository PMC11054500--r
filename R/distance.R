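#' Walked-distance estimators
#'
#' Six estimators of the distance walked during an outdoor test, all
#' integrating the distance between consecutive (estimated) positions:
#'
#' * `distance_baseline()`: sums crow-flies (haversine) distances between
#'   consecutive raw positions.
#' * `distance_qss()`: quality-based spatial subsampling - keeps the
#'   best-accuracy fix per 5 s window, then applies its own acceptance rules
#'   (positive time delta, implied speed at most 2 m/s, step counts must
#'   differ when present) before summing distances. Runs on the raw,
#'   unresampled trace; it embeds its own filtering.
#' * `distance_alpha_beta()`: steady-state two-gain tracking filter per
#'   east/north axis, gains derived per sample from the tracking index
#'   computed from the reported accuracy radius (see [alpha_beta_gains()]).
#' * `distance_kalman_1d()`: two independent position/velocity Kalman filters
#'   (one per axis), process covariance built from fixed position and speed
#'   standard deviations (6 m, 2 m/s), measurement variance the squared
#'   per-sample accuracy radius.
#' * `distance_kalman_2d()`: a single six-state (position, velocity,
#'   acceleration per axis) constant-acceleration Kalman filter.
#' * `distance_kalman_smoothing()`: forward Kalman pass on
#'   (latitude, longitude, speed) with fixed observation covariance
#'   `diag(1e-8, 1e-8, 1e4)`, followed by a fixed-interval
#'   Rauch-Tung-Striebel backward smoothing pass; resamples to 1 Hz
#'   internally, padding across gaps.
#'
#' The filter-based estimators expect a filtered, 1 Hz-resampled trace
#' (`distance_kalman_smoothing()` resamples internally). Each returns a
#' one-row tibble with `algorithm`, `distance_m`, `n_samples_used`, and a
#' `positions` list-column holding the estimated track for diagnostics.
#'
#' @param trace a `walk_trace`.
#' @name distance_estimators
NULL

distance_result <- function(algorithm, positions, n_used) {
  d <- if (nrow(positions) >= 2) {
    if (all(c("lat", "lon") %in% names(positions))) {
      n <- nrow(positions)
      sum(haversine_m(positions$lat[-n], positions$lon[-n],
                      positions$lat[-1], positions$lon[-1]))
    } else {
      sum(sqrt(diff(positions$x)^2 + diff(positions$y)^2))
    }
  } else 0
  tibble(
    algorithm = algorithm,
    distance_m = d,
    n_samples_used = as.integer(n_used),
    positions = list(positions)
  )
}

#' @rdname distance_estimators
#' @export
distance_baseline <- function(trace) {
  distance_result("baseline", as_tibble(trace[, c("lat", "lon")]), nrow(trace))
}

#' @rdname distance_estimators
#' @param window_s subsampling window length in seconds (default 5).
#' @param speed_max_ms maximum accepted implied speed in m/s (default 2).
#' @export
distance_qss <- function(trace, window_s = 5, speed_max_ms = 2) {
  if (nrow(trace) < 1) return(distance_result("qss", tibble(lat = numeric(), lon = numeric()), 0))
  t0 <- trace$t[1]
  win <- floor((trace$t - t0) / window_s)
  # best (lowest accuracy radius) sample per tumbling window; ties -> earliest
  idx <- as_tibble(as.data.frame(trace)) %>%
    mutate(.row = row_number(), .win = win,
           .acc = ifelse(is.na(.data$acc), Inf, .data$acc)) %>%
    group_by(.data$.win) %>%
    slice(which.min(.data$.acc)) %>%
    ungroup() %>%
    arrange(.data$t) %>%
    pull(.data$.row)

  accepted <- integer(0)
  for (i in idx) {
    if (length(accepted) == 0) { accepted <- i; next }
    j <- accepted[length(accepted)]
    dt <- trace$t[i] - trace$t[j]
    if (dt <= 0) next
    v <- haversine_m(trace$lat[j], trace$lon[j], trace$lat[i], trace$lon[i]) / dt
    if (v > speed_max_ms) next
    if (!is.na(trace$steps[i]) && !is.na(trace$steps[j]) &&
        trace$steps[i] == trace$steps[j]) next
    accepted <- c(accepted, i)
  }
  distance_result("qss", as_tibble(trace[accepted, c("lat", "lon")]),
                  length(accepted))
}

#' Steady-state tracking-filter gains from the tracking index
#'
#' Optimal gains of the two-gain (alpha-beta) tracking filter as a function of
#' the tracking index `lambda = sigma_w * T^2 / sigma_n`, via the residual
#' factor `(4 + lambda - sqrt(8 * lambda + lambda^2)) / 4 = r`, giving
#' `alpha = 1 - r^2` and `beta = 2 * (2 - alpha) - 4 * sqrt(1 - alpha)`.
#'
#' @param lam tracking index, non-negative; vectorised.
#' @return tibble with columns `lambda`, `alpha`, `beta`.
#' @export
alpha_beta_gains <- function(lam) {
  if (any(lam < 0)) abort("tracking index must be non-negative")
  r <- (4 + lam - sqrt(8 * lam + lam^2)) / 4
  alpha <- 1 - r^2
  beta <- 2 * (2 - alpha) - 4 * sqrt(pmax(0, 1 - alpha))
  tibble(lambda = lam, alpha = alpha, beta = pmax(0, beta))
}

#' @rdname distance_estimators
#' @param sigma_n measurement-noise scale constant of the tracking index
#'   (default 3).
#' @param acc_floor_m lower bound applied to the reported accuracy radius when
#'   forming the tracking index, avoiding the frozen-filter degeneracy at
#'   zero accuracy; set to 0 to disable.
#' @export
distance_alpha_beta <- function(trace, sigma_n = 3, acc_floor_m = 0.01) {
  n <- nrow(trace)
  if (n < 2) return(distance_result("alphabeta", tibble(x = numeric(), y = numeric()), n))
  enu <- to_enu(trace)
  Tk <- c(1, diff(trace$t))
  acc <- ifelse(is.na(trace$acc), sigma_n, trace$acc)
  acc <- pmax(acc, acc_floor_m)
  xs <- numeric(n); ys <- numeric(n)
  xs[1] <- enu$x[1]; ys[1] <- enu$y[1]
  vx <- 0; vy <- 0
  xh <- xs[1]; yh <- ys[1]
  for (k in 2:n) {
    T <- Tk[k]
    g <- alpha_beta_gains(acc[k] * T^2 / sigma_n)
    # predict from previous corrected state and velocity
    xp <- xh + T * vx
    yp <- yh + T * vy
    rx <- enu$x[k] - xp
    ry <- enu$y[k] - yp
    xh <- xp + g$alpha * rx
    yh <- yp + g$alpha * ry
    vx <- vx + g$beta * rx / T
    vy <- vy + g$beta * ry / T
    xs[k] <- xh; ys[k] <- yh
  }
  distance_result("alphabeta", tibble(x = xs, y = ys), n)
}

# Generic linear Kalman forward pass.
# z: n x p matrix of measurements; Rk: list of p x p per-step measurement
# covariances; x0: initial state; P0: initial covariance.
# Returns filtered and predicted states/covariances for smoothing.
kalman_forward_core <- function(z, A, H, Q, Rk, x0, P0) {
  n <- nrow(z)
  d <- length(x0)
  x_filt <- matrix(0, n, d); P_filt <- vector("list", n)
  x_pred <- matrix(0, n, d); P_pred <- vector("list", n)
  x <- x0; P <- P0
  for (k in seq_len(n)) {
    if (k > 1) {
      x <- A %*% x
      P <- A %*% P %*% t(A) + Q
    }
    x_pred[k, ] <- x; P_pred[[k]] <- P
    S <- H %*% P %*% t(H) + Rk[[k]]
    K <- P %*% t(H) %*% solve(S)
    x <- x + K %*% (z[k, ] - H %*% x)
    P <- P - K %*% H %*% P
    P <- (P + t(P)) / 2  # symmetrize against accumulation of round-off
    x_filt[k, ] <- x; P_filt[[k]] <- P
  }
  list(x_filt = x_filt, P_filt = P_filt, x_pred = x_pred, P_pred = P_pred)
}

#' Linear Kalman filtering and fixed-interval smoothing
#'
#' Low-level building blocks used by the distance estimators, exposed for
#' diagnostic and validation work. `kalman_forward()` runs a standard linear
#' Kalman filter; `kalman_rts()` adds the Rauch-Tung-Striebel backward pass.
#'
#' @param z numeric matrix of measurements, one row per time step.
#' @param A,H,Q state transition, observation and process-covariance matrices.
#' @param R measurement covariance: a single matrix, or a list with one matrix
#'   per step.
#' @param x0,P0 initial state and covariance.
#' @return `kalman_forward()`: tibble of filtered states (`state_1`, ...).
#'   `kalman_rts()`: the same for smoothed states.
#' @export
kalman_forward <- function(z, A, H, Q, R, x0, P0) {
  z <- as.matrix(z)
  Rk <- if (is.list(R)) R else rep(list(as.matrix(R)), nrow(z))
  f <- kalman_forward_core(z, A, H, Q, Rk, x0, P0)
  as_tibble(as.data.frame(f$x_filt)) %>%
    setNames(paste0("state_", seq_len(ncol(f$x_filt))))
}

#' @rdname kalman_forward
#' @export
kalman_rts <- function(z, A, H, Q, R, x0, P0) {
  z <- as.matrix(z)
  Rk <- if (is.list(R)) R else rep(list(as.matrix(R)), nrow(z))
  f <- kalman_forward_core(z, A, H, Q, Rk, x0, P0)
  xs <- rts_core(f, A)
  as_tibble(as.data.frame(xs)) %>%
    setNames(paste0("state_", seq_len(ncol(xs))))
}

rts_core <- function(f, A) {
  n <- nrow(f$x_filt)
  xs <- f$x_filt
  Ps <- f$P_filt
  if (n < 2) return(xs)
  for (k in (n - 1):1) {
    Pp <- f$P_pred[[k + 1]]
    G <- f$P_filt[[k]] %*% t(A) %*% solve(Pp)
    xs[k, ] <- f$x_filt[k, ] + G %*% (xs[k + 1, ] - f$x_pred[k + 1, ])
    Ps[[k]] <- f$P_filt[[k]] + G %*% (Ps[[k + 1]] - Pp) %*% t(G)
  }
  xs
}

#' @rdname distance_estimators
#' @param std_pos,std_speed process standard deviations (m, m/s) used to build
#'   the process covariance; defaults 6 m and 2 m/s.
#' @export
distance_kalman_1d <- function(trace, std_pos = 6, std_speed = 2) {
  n <- nrow(trace)
  if (n < 2) return(distance_result("kalman1d", tibble(x = numeric(), y = numeric()), n))
  enu <- to_enu(trace)
  T <- 1
  A <- matrix(c(1, 0, T, 1), 2, 2)
  Q <- outer(c(std_pos, std_speed), c(std_pos, std_speed))
  H <- matrix(c(1, 0), 1, 2)
  Rk <- lapply(ifelse(is.na(trace$acc), std_pos, trace$acc)^2, function(r) matrix(r, 1, 1))
  run_axis <- function(zv) {
    f <- kalman_forward_core(matrix(zv, ncol = 1), A, H, Q, Rk,
                             x0 = c(zv[1], 0), P0 = Q)
    f$x_filt[, 1]
  }
  distance_result("kalman1d", tibble(x = run_axis(enu$x), y = run_axis(enu$y)), n)
}

#' @rdname distance_estimators
#' @param std_acc process acceleration standard deviation (m/s^2) extending
#'   the covariance construction to the six-state filter; default 1.
#' @export
distance_kalman_2d <- function(trace, std_pos = 6, std_speed = 2, std_acc = 1) {
  n <- nrow(trace)
  if (n < 2) return(distance_result("kalman2d", tibble(x = numeric(), y = numeric()), n))
  enu <- to_enu(trace)
  T <- 1
  # state (x, y, vx, vy, ax, ay), constant acceleration
  A <- diag(6)
  A[1, 3] <- T; A[2, 4] <- T
  A[1, 5] <- T^2 / 2; A[2, 6] <- T^2 / 2
  A[3, 5] <- T; A[4, 6] <- T
  s <- c(std_pos, std_speed, std_acc)
  Qa <- outer(s, s)  # per-axis outer-product construction
  Q <- matrix(0, 6, 6)
  ax_idx <- list(c(1, 3, 5), c(2, 4, 6))
  for (ix in ax_idx) Q[ix, ix] <- Qa
  H <- matrix(0, 2, 6); H[1, 1] <- 1; H[2, 2] <- 1
  acc2 <- ifelse(is.na(trace$acc), std_pos, trace$acc)^2
  Rk <- lapply(acc2, function(r) diag(c(r, r), 2))
  z <- cbind(enu$x, enu$y)
  f <- kalman_forward_core(z, A, H, Q, Rk,
                           x0 = c(enu$x[1], enu$y[1], 0, 0, 0, 0), P0 = Q)
  distance_result("kalman2d", tibble(x = f$x_filt[, 1], y = f$x_filt[, 2]), n)
}

#' @rdname distance_estimators
#' @param q_coord,q_speed process variances of the random-walk transition on
#'   the coordinate (deg^2 per step) and speed ((m/s)^2 per step) states.
#' @param r_coord,r_speed fixed observation variances: coordinate noise in
#'   deg^2 (default 1e-8) and speed noise in (m/s)^2 (default 1e4, i.e. the
#'   speed channel is nearly ignored).
#' @export
distance_kalman_smoothing <- function(trace,
                                      q_coord = 5e-9, q_speed = 0.01,
                                      r_coord = 1e-8, r_speed = 1e4) {
  if (nrow(trace) < 2) {
    return(distance_result("kalmansmooth", tibble(lat = numeric(), lon = numeric()), nrow(trace)))
  }
  rs <- resample_1hz(trace)
  n <- nrow(rs)
  if (n < 2) return(distance_result("kalmansmooth", tibble(lat = numeric(), lon = numeric()), n))
  # state and observation: (latitude deg, longitude deg, speed m/s)
  speed <- ifelse(is.na(rs$speed), 0, rs$speed)
  z <- cbind(rs$lat, rs$lon, speed)
  A <- diag(3)
  Q <- diag(c(q_coord, q_coord, q_speed))
  H <- diag(3)
  R <- diag(c(r_coord, r_coord, r_speed))
  f <- kalman_forward_core(z, A, H, Q, rep(list(R), n),
                           x0 = z[1, ], P0 = R)
  xs <- rts_core(f, A)
  distance_result("kalmansmooth", tibble(lat = xs[, 1], lon = xs[, 2]), n)
}

#' Run all six distance estimators on one trace
#'
#' Convenience wrapper reproducing the full estimation stage: filters and
#' resamples as each algorithm requires (baseline and QSS run on filtered /
#' raw data respectively; the tracking filters on filtered, resampled data),
#' and returns one row per algorithm.
#'
#' @param trace a raw `walk_trace`.
#' @param preprocess if `FALSE`, every estimator runs on the raw trace
#'   (used to quantify the impact of pre-processing).
#' @param ... threshold overrides passed to [apply_filters()].
#' @return tibble with columns `algorithm`, `distance_m`, `n_samples_used`,
#'   `positions`.
#' @export
estimate_distances <- function(trace, preprocess = TRUE, ...) {
  if (preprocess) {
    kept <- apply_filters(trace, ...)$kept
    rs <- if (nrow(kept) >= 2) resample_1hz(kept) else kept
  } else {
    kept <- trace
    # the tracking filters still need a strictly increasing time base
    mono <- monotone_time(trace)
    rs <- if (nrow(mono) >= 2) resample_1hz(mono) else mono
  }
  bind_rows(
    distance_baseline(kept),
    distance_qss(trace),
    if (nrow(rs) >= 2) distance_alpha_beta(rs) else distance_result("alphabeta", tibble(x = numeric(), y = numeric()), nrow(rs)),
    if (nrow(rs) >= 2) distance_kalman_1d(rs) else distance_result("kalman1d", tibble(x = numeric(), y = numeric()), nrow(rs)),
    if (nrow(rs) >= 2) distance_kalman_2d(rs) else distance_result("kalman2d", tibble(x = numeric(), y = numeric()), nrow(rs)),
    distance_kalman_smoothing(if (preprocess) kept else monotone_time(trace))
  )
}

# Minimal monotone-time subset: keep each sample whose timestamp strictly
# exceeds the last kept one. Used only when running estimators without the
# exclusion filters.
monotone_time <- function(trace) {
  keep <- logical(nrow(trace))
  last <- -Inf
  for (i in seq_len(nrow(trace))) {
    if (trace$t[i] > last) {
      keep[i] <- TRUE
      last <- trace$t[i]
    }
  }
  rewrap_trace(as_tibble(as.data.frame(trace))[keep, ], trace)
}
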