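#' Construct a walk trace
#'
#' A walk trace is a tibble of GNSS samples (one row per positioning update)
#' with per-trace metadata stored in attributes. Columns:
#' \describe{
#'   \item{t}{timestamp in seconds (numeric, seconds since an arbitrary epoch)}
#'   \item{lat, lon}{WGS84-style coordinates in degrees}
#'   \item{alt}{altitude in meters, `NA` when the fix had none (non-satellite fix)}
#'   \item{acc}{horizontal-accuracy (confidence-interval) radius in meters}
#'   \item{heading}{degrees clockwise from north in `[0, 360)`, `NA` if absent}
#'   \item{speed}{reported speed in m/s, `NA` if absent}
#'   \item{steps}{cumulative step count, `NA` if absent}
#'   \item{accel_mag}{mean acceleration magnitude over the preceding second,
#'     m/s^2, `NA` if absent}
#' }
#'
#' @param samples data frame with at least `t`, `lat`, `lon`; missing optional
#'   columns are filled with `NA`.
#' @param participant_id opaque participant identifier.
#' @param path_type one of `"regular"`, `"stop_and_go"`, `"back_and_forth"`,
#'   `"circles0"`..`"circles3"`, `"unknown"`.
#' @param label `"conventional"`, `"unconventional"` or `"unknown"`.
#' @param reference_distance_m ground-truth walked distance in meters
#'   (trundle-wheel equivalent), or `NA`.
#' @return A `walk_trace` tibble.
#' @export
walk_trace <- function(samples,
                       participant_id = "unknown",
                       path_type = "unknown",
                       label = "unknown",
                       reference_distance_m = NA_real_) {
  samples <- as_tibble(samples)
  if (!all(c("t", "lat", "lon") %in% names(samples))) {
    abort("a walk trace needs at least columns t, lat, lon")
  }
  for (col in setdiff(trace_columns(), names(samples))) {
    samples[[col]] <- NA_real_
  }
  samples <- samples[, trace_columns()]
  for (col in trace_columns()) samples[[col]] <- as.numeric(samples[[col]])
  validate_samples(samples)
  path_type <- match.arg(path_type, path_types())
  label <- match.arg(label, c("conventional", "unconventional", "unknown"))
  structure(
    samples,
    class = c("walk_trace", class(tibble())),
    participant_id = as.character(participant_id),
    path_type = path_type,
    label = label,
    reference_distance_m = as.numeric(reference_distance_m)
  )
}

trace_columns <- function() {
  c("t", "lat", "lon", "alt", "acc", "heading", "speed", "steps", "accel_mag")
}

path_types <- function() {
  c("unknown", "regular", "stop_and_go", "back_and_forth",
    paste0("circles", 0:3))
}

validate_samples <- function(s) {
  bad_lat <- which(!is.na(s$lat) & abs(s$lat) > 90)
  bad_lon <- which(!is.na(s$lon) & abs(s$lon) > 180)
  bad_acc <- which(!is.na(s$acc) & s$acc < 0)
  if (length(bad_lat)) abort(paste0("latitude out of [-90, 90] at row ", bad_lat[1]))
  if (length(bad_lon)) abort(paste0("longitude out of [-180, 180] at row ", bad_lon[1]))
  if (length(bad_acc)) abort(paste0("negative accuracy radius at row ", bad_acc[1]))
  invisible(s)
}

#' Trace metadata accessors
#' @param trace a `walk_trace`.
#' @return `trace_meta()` returns a one-row tibble of the metadata;
#'   `trace_duration()` the recording span in seconds.
#' @export
trace_meta <- function(trace) {
  tibble(
    participant_id = attr(trace, "participant_id") %||% "unknown",
    path_type = attr(trace, "path_type") %||% "unknown",
    label = attr(trace, "label") %||% "unknown",
    reference_distance_m = attr(trace, "reference_distance_m") %||% NA_real_,
    n_samples = nrow(trace),
    duration_s = trace_duration(trace)
  )
}

#' @rdname trace_meta
#' @export
trace_duration <- function(trace) {
  if (nrow(trace) < 2) return(0)
  max(trace$t) - min(trace$t)
}

# Rebuild a walk_trace around a new sample table, keeping metadata.
rewrap_trace <- function(samples, template) {
  walk_trace(
    samples,
    participant_id = attr(template, "participant_id") %||% "unknown",
    path_type = attr(template, "path_type") %||% "unknown",
    label = attr(template, "label") %||% "unknown",
    reference_distance_m = attr(template, "reference_distance_m") %||% NA_real_
  )
}

#' @export
print.walk_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf(
    "<walk_trace> %d samples, %.0f s, participant %s, path %s (%s)\n",
    nrow(x), meta$duration_s, meta$participant_id, meta$path_type, meta$label
  ))
  if (!is.na(meta$reference_distance_m)) {
    cat(sprintf("  reference distance: %.1f m\n", meta$reference_distance_m))
  }
  NextMethod()
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Vectorised over
#' coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    abort("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  }
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial bearing between coordinate pairs
#'
#' Forward azimuth of the great circle from the first to the second point,
#' degrees clockwise from north in `[0, 360)`.
#'
#' @inheritParams haversine_m
#' @return bearing(s) in degrees.
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  same <- lat1 == lat2 & lon1 == lon2
  if (any(same, na.rm = TRUE)) {
    abort("bearing undefined for coincident points")
  }
  p <- pi / 180
  dlon <- (lon2 - lon1) * p
  y <- sin(dlon) * cos(lat2 * p)
  x <- cos(lat1 * p) * sin(lat2 * p) - sin(lat1 * p) * cos(lat2 * p) * cos(dlon)
  (atan2(y, x) / p) %% 360
}

#' Project a trace into a local east-north frame
#'
#' Equirectangular projection about the first sample: meter-valued planar
#' coordinates adequate at walking scale (sub-2 km), used by the tracking
#' filters and the curviness feature.
#'
#' @param trace a `walk_trace` (or any data frame with `lat`, `lon`).
#' @return tibble with columns `x` (m east) and `y` (m north); first point is
#'   (0, 0).
#' @export
to_enu <- function(trace) {
  if (nrow(trace) < 1) abort("cannot project an empty trace")
  p <- pi / 180
  lat0 <- trace$lat[1]
  lon0 <- trace$lon[1]
  tibble(
    x = EARTH_RADIUS_M * (trace$lon - lon0) * p * cos(lat0 * p),
    y = EARTH_RADIUS_M * (trace$lat - lat0) * p
  )
}

# Inverse of to_enu() for a given origin, used by the simulator.
enu_to_latlon <- function(x, y, lat0, lon0) {
  p <- pi / 180
  tibble(
    lat = lat0 + (y / EARTH_RADIUS_M) / p,
    lon = lon0 + (x / (EARTH_RADIUS_M * cos(lat0 * p))) / p
  )
}

#' Resample a trace onto a 1 Hz grid
#'
#' Places samples on the integer-second grid from `ceiling(t_first)` to
#' `floor(t_last)`. Coordinates and altitude are linearly interpolated across
#' gaps up to `max_gap_s` and held at the last observed value across longer
#' gaps (padding). The accuracy radius at a grid point is the pessimistic
#' maximum of the two bracketing raw values; heading is recomputed from
#' consecutive grid positions and speed as grid-step distance over 1 s.
#'
#' @param trace a `walk_trace` with strictly increasing timestamps (filter
#'   first: see [apply_filters()]).
#' @param max_gap_s interpolate across gaps up to this many seconds; hold the
#'   last value beyond it.
#' @return a `walk_trace` on the unit-second grid.
#' @export
resample_1hz <- function(trace, max_gap_s = 5) {
  if (nrow(trace) < 2) abort("resampling needs at least 2 samples")
  t <- trace$t
  if (any(diff(t) <= 0)) {
    abort("timestamps must be strictly increasing; run apply_filters() first")
  }
  grid <- seq(ceiling(t[1]), floor(t[length(t)]), by = 1)
  if (length(grid) < 1) abort("trace too short to resample")

  interp_gap <- function(v) {
    # linear interpolation, but hold-last across source gaps > max_gap_s
    idx_hi <- findInterval(grid, t, left.open = TRUE) + 1L
    idx_lo <- pmax(findInterval(grid, t), 1L)
    idx_hi <- pmin(idx_hi, length(t))
    gap <- t[idx_hi] - t[idx_lo]
    out <- numeric(length(grid))
    for (i in seq_along(grid)) {
      lo <- idx_lo[i]; hi <- idx_hi[i]
      if (grid[i] <= t[lo] || lo == hi) { out[i] <- v[lo]; next }
      if (gap[i] > max_gap_s) { out[i] <- v[lo]; next }  # pad with last value
      w <- (grid[i] - t[lo]) / (t[hi] - t[lo])
      if (is.na(v[lo]) || is.na(v[hi])) out[i] <- v[lo] else
        out[i] <- v[lo] + w * (v[hi] - v[lo])
    }
    out
  }

  acc_bracket <- function(v) {
    idx_hi <- pmin(findInterval(grid, t, left.open = TRUE) + 1L, length(t))
    idx_lo <- pmax(findInterval(grid, t), 1L)
    pmax(v[idx_lo], v[idx_hi], na.rm = TRUE)
  }

  lat <- interp_gap(trace$lat)
  lon <- interp_gap(trace$lon)
  alt <- interp_gap(trace$alt)
  acc <- acc_bracket(trace$acc)
  steps <- interp_gap(trace$steps)
  steps <- ifelse(is.na(steps), NA_real_, round(steps))
  accel <- interp_gap(trace$accel_mag)

  n <- length(grid)
  step_d <- if (n >= 2) haversine_m(lat[-n], lon[-n], lat[-1], lon[-1]) else numeric(0)
  speed <- if (n >= 2) c(step_d / diff(grid), NA_real_) else rep(NA_real_, n)
  heading <- rep(NA_real_, n)
  if (n >= 2) {
    moved <- step_d > 0
    hb <- rep(NA_real_, n - 1)
    if (any(moved)) {
      hb[moved] <- bearing_deg(lat[-n][moved], lon[-n][moved],
                               lat[-1][moved], lon[-1][moved])
    }
    heading[-n] <- hb
    heading[n] <- heading[n - 1]
  }
  if (n >= 2) speed[n] <- speed[n - 1]

  rewrap_trace(
    tibble(t = grid, lat = lat, lon = lon, alt = alt, acc = acc,
           heading = heading, speed = speed, steps = steps, accel_mag = accel),
    trace
  )
}

#' Read and write walk traces
#'
#' CSV traces carry the sample table only (header
#' `t,lat,lon,alt,acc,heading,speed,steps,accel_mag`; empty cell = absent).
#' JSON traces carry a `meta` object (participant_id, path_type, label,
#' reference_distance_m) plus a `samples` array, and round-trip the metadata.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param trace a `walk_trace`.
#' @param ... passed to [walk_trace()] when reading CSV (metadata).
#' @return `read_trace()` returns a `walk_trace`; the writers return `path`
#'   invisibly.
#' @export
read_trace <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    samples <- as_tibble(obj$samples)
    missing <- setdiff(c("t", "lat", "lon"), names(samples))
    if (length(missing)) {
      abort(paste0("trace JSON lacks mandatory column(s): ",
                   paste(missing, collapse = ", ")))
    }
    meta <- obj$meta %||% list()
    walk_trace(
      samples,
      participant_id = meta$participant_id %||% "unknown",
      path_type = meta$path_type %||% "unknown",
      label = meta$label %||% "unknown",
      reference_distance_m = meta$reference_distance_m %||% NA_real_
    )
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
    missing <- setdiff(c("t", "lat", "lon"), names(df))
    if (length(missing)) {
      abort(paste0("trace CSV ", path, " lacks mandatory column(s): ",
                   paste(missing, collapse = ", ")))
    }
    bad <- which(!complete.cases(df[, c("t", "lat", "lon")]))
    if (length(bad)) {
      abort(paste0("unparseable mandatory field in row ", bad[1],
                   " of ", path, " (t/lat/lon must be numeric)"))
    }
    walk_trace(df, ...)
  }
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    meta <- trace_meta(trace)
    obj <- list(
      meta = list(
        participant_id = meta$participant_id,
        path_type = meta$path_type,
        label = meta$label,
        reference_distance_m = meta$reference_distance_m
      ),
      samples = as.data.frame(trace)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(as_tibble(as.data.frame(trace)), path, na = "")
  }
  invisible(path)
}

#' @rdname read_trace
#' @export
export_gpx <- function(trace, path) {
  doc <- xml2::xml_new_root(
    "gpx", version = "1.1", creator = "sixmwt",
    xmlns = "http://www.topografix.com/GPX/1/1"
  )
  trk <- xml2::xml_add_child(doc, "trk")
  seg <- xml2::xml_add_child(trk, "trkseg")
  t0 <- as.POSIXct(trace$t, origin = "1970-01-01", tz = "UTC")
  for (i in seq_len(nrow(trace))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = format(trace$lat[i], digits = 12),
                              lon = format(trace$lon[i], digits = 12))
    if (!is.na(trace$alt[i])) {
      xml2::xml_add_child(pt, "ele", format(trace$alt[i], digits = 8))
    }
    xml2::xml_add_child(pt, "time", format(t0[i], "%Y-%m-%dT%H:%M:%OS2Z"))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
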