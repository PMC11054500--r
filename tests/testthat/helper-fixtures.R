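# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A straight constant-velocity trace heading due north at `speed` m/s,
# sampled every `dt` seconds, with clean metadata channels.
straight_trace <- function(n = 61, speed = 1.3, dt = 1, lat0 = 52, lon0 = 13,
                           acc = 5) {
  t <- (seq_len(n) - 1) * dt
  dist <- t * speed
  tibble::tibble(
    t = t,
    lat = lat0 + (dist / 6371000) * 180 / pi,
    lon = lon0,
    alt = 20,
    acc = acc,
    heading = 0,
    speed = speed,
    steps = round(1.8 * dist),
    accel_mag = 1.2
  ) |> walk_trace()
}

# Noisy 40-trace cohort with injected artifacts (the study-condition defaults).
noisy_cohort_40 <- function() {
  memo("noisy40", function() simulate_cohort(10, 4, seed = 2024))
}

# Noisy 100-trace cohort (10 participants x 10 tests, 50/50 class mix)
# and its per-trace quality features.
noisy_cohort_100 <- function() {
  memo("noisy100", function() simulate_cohort(10, 10, seed = 2025))
}

cohort_features_100 <- function() {
  memo("features100", function() cohort_features(noisy_cohort_100()))
}
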