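test_that("baseline sums crow-flies distances", {
  two <- walk_trace(tibble::tibble(
    t = 0:1, lat = c(0, 100 / 6371000 * 180 / pi), lon = 0
  ))
  expect_equal(distance_baseline(two)$distance_m, 100, tolerance = 1e-9)

  three <- straight_trace(n = 3, speed = 50)  # 0 / 50 / 100 m collinear
  expect_equal(distance_baseline(three)$distance_m, 100, tolerance = 1e-6)

  one <- straight_trace(n = 1)
  expect_equal(distance_baseline(one)$distance_m, 0)
})

test_that("tracking-index gains follow the closed forms", {
  g <- alpha_beta_gains(c(0, 1, 1e6))
  expect_equal(g$alpha, c(0, 0.75, 1), tolerance = 1e-3)
  expect_equal(g$beta[1:2], c(0, 0.5), tolerance = 1e-12)
  # both gains are non-decreasing in the index and alpha stays in [0, 1)
  lam <- exp(seq(log(1e-4), log(1e4), length.out = 100))
  gg <- alpha_beta_gains(lam)
  expect_true(all(diff(gg$alpha) >= 0))
  expect_true(all(diff(gg$beta) >= 0))
  expect_true(all(gg$alpha >= 0 & gg$alpha < 1))
  expect_error(alpha_beta_gains(-1), "non-negative")
})

test_that("the window subsampler picks the best fix and rejects bad steps", {
  # one window with accuracies 10/5/8...: the lowest-accuracy fix is selected
  df <- as.data.frame(straight_trace(n = 15, speed = 1))
  df$acc <- c(10, 5, 8, 10, 10,
              10, 2, 10, 10, 10,
              10, 10, 1, 10, 10)
  tr <- walk_trace(df)
  pos <- distance_qss(tr)$positions[[1]]
  sel_lat <- df$lat[c(2, 7, 13)]  # best fix of each 5 s window
  expect_equal(pos$lat, sel_lat)

  # sub-sampling a straight line is lossless when the endpoints are selected
  df2 <- as.data.frame(straight_trace(n = 60, speed = 1))
  df2$acc <- 10
  df2$acc[1] <- 4
  df2$acc[60] <- 4
  expect_equal(distance_qss(walk_trace(df2))$distance_m, 59, tolerance = 1e-6)

  # chords under-measure arcs: circles give QSS < baseline
  sw <- simulate_walk("circles1", 240, speed_jitter_sd = 0,
                      noise = noise_off(), seed = 2)
  expect_lt(distance_qss(sw$trace)$distance_m,
            distance_baseline(sw$trace)$distance_m)

  # the 2 m/s acceptance rule drops implausible jumps
  df3 <- as.data.frame(straight_trace(n = 20, speed = 1))
  df3$lat[11:20] <- df3$lat[11:20] + 0.01  # teleported second half
  d <- distance_qss(walk_trace(df3))
  expect_lt(d$distance_m, 20)
})

test_that("the steady-state tracking filter obeys its gain limits", {
  rs <- resample_1hz(apply_filters(straight_trace(n = 120))$kept)

  # zero accuracy with the floor disabled freezes the filter entirely
  frozen <- rs; frozen$acc <- 0
  d0 <- distance_alpha_beta(frozen, acc_floor_m = 0)
  expect_equal(d0$distance_m, 0)

  # huge accuracy drives alpha to 1: the filter reproduces the measurements
  trusting <- rs; trusting$acc <- 1e6
  db <- distance_baseline(rs)$distance_m
  expect_lt(abs(distance_alpha_beta(trusting)$distance_m - db) / db, 0.001)

  # noise-free straight walk: within 2% of the true distance
  sw <- simulate_walk("regular", 300, speed_jitter_sd = 0,
                      noise = noise_off(), seed = 5)
  rs2 <- resample_1hz(apply_filters(sw$trace)$kept)
  expect_lt(abs(distance_alpha_beta(rs2)$distance_m - sw$true_distance_m) /
              sw$true_distance_m, 0.02)
})

test_that("the per-axis Kalman filter trusts exact measurements and settles", {
  sw <- simulate_walk("regular", 200, seed = 6)
  rs <- resample_1hz(apply_filters(sw$trace)$kept)
  exact <- rs; exact$acc <- 0
  pos <- distance_kalman_1d(exact)$positions[[1]]
  enu <- to_enu(exact)
  expect_lt(max(abs(pos$x - enu$x), abs(pos$y - enu$y)), 1e-9)

  # constant-position measurements: posterior velocity stays near zero
  still <- walk_trace(tibble::tibble(
    t = 0:99, lat = 52, lon = 13, alt = 20, acc = 5,
    speed = 0, steps = 0, accel_mag = 1
  ))
  d <- distance_kalman_1d(still)
  expect_lt(d$distance_m, 0.01)

  sw2 <- simulate_walk("regular", 300, speed_jitter_sd = 0,
                       noise = noise_off(), seed = 7)
  rs2 <- resample_1hz(apply_filters(sw2$trace)$kept)
  expect_lt(abs(distance_kalman_1d(rs2)$distance_m - sw2$true_distance_m) /
              sw2$true_distance_m, 0.02)
})

test_that("the six-state filter agrees with the per-axis one on straight walks", {
  sw <- simulate_walk("regular", 300, seed = 8)
  rs <- resample_1hz(apply_filters(sw$trace)$kept)

  exact <- rs; exact$acc <- 0
  pos <- distance_kalman_2d(exact)$positions[[1]]
  enu <- to_enu(exact)
  expect_lt(max(abs(pos$x - enu$x), abs(pos$y - enu$y)), 1e-9)

  d1 <- distance_kalman_1d(rs)$distance_m
  d2 <- distance_kalman_2d(rs)$distance_m
  expect_lt(abs(d1 - d2) / d1, 0.05)

  sw2 <- simulate_walk("regular", 300, speed_jitter_sd = 0,
                       noise = noise_off(), seed = 9)
  rs2 <- resample_1hz(apply_filters(sw2$trace)$kept)
  expect_lt(abs(distance_kalman_2d(rs2)$distance_m - sw2$true_distance_m) /
              sw2$true_distance_m, 0.02)
})

test_that("the smoother is exact on constant tracks and optimal on linear ones", {
  still <- walk_trace(tibble::tibble(
    t = 0:49, lat = 52, lon = 13, alt = 20, acc = 5,
    speed = 0, steps = 0, accel_mag = 1
  ))
  d <- distance_kalman_smoothing(still, q_coord = 0, q_speed = 0)
  expect_equal(d$distance_m, 0)

  # Rauch-Tung-Striebel optimality: smoothed RMSE <= filtered RMSE on a
  # matched linear-Gaussian track
  set.seed(10)
  n <- 400
  A <- matrix(c(1, 0, 1, 1), 2, 2); H <- matrix(c(1, 0), 1, 2)
  Q <- diag(c(0.05, 0.02)); R <- matrix(4, 1, 1)
  x <- c(0, 1); truth <- matrix(0, n, 2)
  for (k in 1:n) {
    if (k > 1) x <- A %*% x + c(rnorm(1, 0, sqrt(0.05)), rnorm(1, 0, sqrt(0.02)))
    truth[k, ] <- x
  }
  z <- matrix(truth[, 1] + rnorm(n, 0, 2), ncol = 1)
  f <- kalman_forward(z, A, H, Q, R, x0 = c(z[1], 1), P0 = diag(2))
  s <- kalman_rts(z, A, H, Q, R, x0 = c(z[1], 1), P0 = diag(2))
  rmse_f <- sqrt(mean((f$state_1 - truth[, 1])^2))
  rmse_s <- sqrt(mean((s$state_1 - truth[, 1])^2))
  expect_lte(rmse_s, rmse_f)

  sw <- simulate_walk("regular", 300, speed_jitter_sd = 0,
                      noise = noise_off(), seed = 11)
  kept <- apply_filters(sw$trace)$kept
  expect_lt(abs(distance_kalman_smoothing(kept)$distance_m - sw$true_distance_m) /
              sw$true_distance_m, 0.02)
})

test_that("estimators return 0 on single samples and ignore the epoch", {
  one <- straight_trace(n = 1)
  for (f in list(distance_baseline, distance_qss, distance_alpha_beta,
                 distance_kalman_1d, distance_kalman_2d,
                 distance_kalman_smoothing)) {
    expect_equal(f(one)$distance_m, 0)
  }

  sw <- simulate_walk("circles0", 200, seed = 12)
  shifted <- sw$trace
  shifted$t <- shifted$t + 100000
  shifted <- walk_trace(shifted)
  a <- estimate_distances(sw$trace)
  b <- estimate_distances(walk_trace(shifted))
  expect_equal(a$distance_m, b$distance_m, tolerance = 1e-9)
})

test_that("pre-processing lowers error and QSS shortens curved paths", {
  co <- noisy_cohort_40()
  errs <- evaluate_cohort(co)
  base <- errs[errs$algorithm == "baseline", ]
  mape_on <- mean(base$ape[base$preprocessed])
  mape_off <- mean(base$ape[!base$preprocessed])
  expect_lt(mape_on, mape_off)

  # every estimator stays under 2% error on noise-free regular paths
  sw <- simulate_walk("regular", 240, noise = noise_off(), seed = 13)
  d <- estimate_distances(sw$trace)
  expect_true(all(abs(d$distance_m - sw$true_distance_m) /
                    sw$true_distance_m < 0.02))
})
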