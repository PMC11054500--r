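test_that("haversine distance matches closed forms and is a metric", {
  expect_equal(haversine_m(52, 13, 52, 13), 0)
  # one degree of latitude on the sphere: pi * R / 180
  expect_equal(haversine_m(0, 0, 1, 0), pi * 6371000 / 180, tolerance = 1e-9)
  expect_error(haversine_m(91, 0, 0, 0), "out of range")

  set.seed(1)
  lat <- runif(200, -60, 60)
  lon <- runif(200, -170, 170)
  i <- 1:100; j <- 101:200
  d_ij <- haversine_m(lat[i], lon[i], lat[j], lon[j])
  d_ji <- haversine_m(lat[j], lon[j], lat[i], lon[i])
  expect_equal(d_ij, d_ji, tolerance = 1e-12)
  # triangle inequality on random triples
  k <- sample(1:200, 100)
  d_ik <- haversine_m(lat[i], lon[i], lat[k], lon[k])
  d_kj <- haversine_m(lat[k], lon[k], lat[j], lon[j])
  expect_true(all(d_ij <= d_ik + d_kj + 1e-9))
})

test_that("haversine agrees with a spherical law-of-cosines oracle within 1 cm", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  lat0 <- runif(1000, -60, 60)
  lon0 <- runif(1000, -170, 170)
  # pairs within ~1 km
  lat1 <- lat0 + runif(1000, -0.005, 0.005)
  lon1 <- lon0 + runif(1000, -0.005, 0.005)
  ours <- haversine_m(lat0, lon0, lat1, lon1)
  oracle <- geosphere::distCosine(cbind(lon0, lat0), cbind(lon1, lat1),
                                  r = 6371000)
  expect_lt(max(abs(ours - oracle)), 0.01)
})

test_that("bearing follows the compass convention and the azimuth oracle", {
  expect_equal(bearing_deg(0, 0, 1, 0), 0)
  expect_equal(bearing_deg(0, 0, 0, 1), 90)
  expect_error(bearing_deg(10, 10, 10, 10), "coincident")

  skip_if_not_installed("geosphere")
  # forward-inverse oracle: walk a known azimuth on the sphere, recover it
  set.seed(3)
  lat0 <- runif(500, -60, 60); lon0 <- runif(500, -170, 170)
  azi <- runif(500, 0, 360)
  dist <- runif(500, 50, 1000)
  dest <- geosphere::destPoint(cbind(lon0, lat0), azi, dist, r = 6371000)
  ours <- bearing_deg(lat0, lon0, dest[, "lat"], dest[, "lon"])
  diff <- abs(ours - azi)
  diff <- pmin(diff, 360 - diff)
  expect_lt(max(diff), 0.01)
})

test_that("local east-north projection is anchored and metric-faithful", {
  tr <- straight_trace(n = 10)
  enu <- to_enu(tr)
  expect_equal(c(enu$x[1], enu$y[1]), c(0, 0))

  one_up <- walk_trace(tibble::tibble(t = 0:1, lat = c(52, 52.001), lon = 13))
  enu2 <- to_enu(one_up)
  expect_equal(enu2$y[2], 6371000 * 0.001 * pi / 180, tolerance = 1e-9)
  expect_equal(enu2$x[2], 0)

  # consecutive ENU steps match haversine within 0.1% on a sub-2 km wander
  set.seed(4)
  n <- 400
  lat <- 52 + cumsum(rnorm(n, 0, 2e-5))
  lon <- 13 + cumsum(rnorm(n, 0, 2e-5))
  wt <- walk_trace(tibble::tibble(t = seq_len(n), lat = lat, lon = lon))
  enu <- to_enu(wt)
  d_enu <- sqrt(diff(enu$x)^2 + diff(enu$y)^2)
  d_hav <- haversine_m(lat[-n], lon[-n], lat[-1], lon[-1])
  expect_lt(max(abs(d_enu - d_hav) / d_hav), 0.001)
})

test_that("1 Hz resampling interpolates, pads and recomputes kinematics", {
  # already on the grid: positions unchanged
  tr <- straight_trace(n = 30)
  rs <- resample_1hz(tr)
  expect_equal(rs$lat, tr$lat)
  expect_true(all(diff(rs$t) == 1))

  # 2 Hz over 60 s collapses to 61 grid samples
  tr2 <- straight_trace(n = 121, dt = 0.5)
  expect_equal(abs(nrow(resample_1hz(tr2)) - 60) <= 1, TRUE)

  # 0.5 Hz constant-velocity: interpolated midpoints on the line within 1e-9 deg
  tr3 <- straight_trace(n = 31, dt = 2)
  rs3 <- resample_1hz(tr3)
  fit_lat <- tr3$lat[1] + (rs3$t - tr3$t[1]) * (tr3$lat[2] - tr3$lat[1]) / 2
  expect_equal(rs3$lat, fit_lat, tolerance = 1e-9)

  # accuracy at a grid point is the max of the bracketing raw values
  raw <- straight_trace(n = 5, dt = 2)
  raw$acc <- c(5, 9, 4, 8, 3)
  rsa <- resample_1hz(raw)
  expect_equal(rsa$acc[rsa$t == 1], 9)   # between acc 5 and 9
  expect_equal(rsa$acc[rsa$t == 5], 8)   # between acc 4 and 8

  # long gaps hold the last value instead of interpolating
  gap <- walk_trace(tibble::tibble(
    t = c(0, 1, 2, 20), lat = c(52, 52.0001, 52.0002, 52.001), lon = 13
  ))
  rsg <- resample_1hz(gap)
  expect_equal(rsg$lat[rsg$t == 10], 52.0002)

  expect_error(resample_1hz(walk_trace(tibble::tibble(
    t = c(0, 0, 1), lat = 52, lon = 13
  ))), "strictly increasing")
})

test_that("trace IO round-trips CSV, JSON and exports GPX", {
  tr <- straight_trace(n = 15)
  tr$alt[3] <- NA
  tr$heading[5] <- NA
  tr <- walk_trace(tr, participant_id = "p09",
                             path_type = "circles1", label = "unconventional",
                             reference_distance_m = 123.4)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  gpx <- withr::local_tempfile(fileext = ".gpx")

  write_trace(tr, csv)
  back <- read_trace(csv)
  # CSV carries the sample table only, not the metadata
  expect_equal(as.data.frame(back), as.data.frame(tr), ignore_attr = TRUE)
  expect_true(is.na(back$alt[3]))

  write_trace(tr, js)
  backj <- read_trace(js)
  expect_equal(as.data.frame(backj), as.data.frame(tr))
  expect_equal(trace_meta(backj)$path_type, "circles1")
  expect_equal(trace_meta(backj)$reference_distance_m, 123.4)

  export_gpx(tr, gpx)
  doc <- xml2::read_xml(gpx)
  pts <- xml2::xml_find_all(doc, ".//*[local-name() = 'trkpt']")
  expect_length(pts, nrow(tr))
  eles <- xml2::xml_find_all(doc, ".//*[local-name() = 'ele']")
  expect_length(eles, sum(!is.na(tr$alt)))

  # missing mandatory column is reported by name
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(t = 1, lat = 52), bad)
  expect_error(read_trace(bad), "lon")
})
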