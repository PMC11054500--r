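#' Sample-exclusion filtering of a walk trace
#'
#' Applies the six sample-exclusion rules in order, attributing each removed
#' sample to the first rule it fails. Pairwise rules (R4-R6) compare the
#' candidate against the last *kept* sample, so a single bad fix cannot shield
#' the one after it.
#'
#' \describe{
#'   \item{R1}{altitude absent (non-satellite fix)}
#'   \item{R2}{accuracy radius above `acc_max_m` (default 25 m)}
#'   \item{R3}{mean acceleration magnitude below `accel_min_ms2` (default
#'     0.5 m/s^2) - skipped when the channel is absent}
#'   \item{R4}{step-count delta versus the last kept sample is zero - skipped
#'     when steps are absent}
#'   \item{R5}{time delta versus the last kept sample is less than or equal to
#'     zero (stale fix)}
#'   \item{R6}{implied speed versus the last kept sample above `speed_max_ms`
#'     (default 5 m/s)}
#' }
#'
#' @param trace a `walk_trace`.
#' @param acc_max_m,accel_min_ms2,speed_max_ms rule thresholds; defaults are
#'   the published values.
#' @param trim_leading_lock if `TRUE`, drop leading samples until one arrives
#'   with accuracy below `start_lock_m`, emulating the recording app's
#'   start condition. Off by default.
#' @param start_lock_m lock threshold for `trim_leading_lock` (default 15 m).
#' @return A `filter_report` list with elements `kept` (the filtered
#'   `walk_trace`), `removed` (tibble of `index`, `rule`, `value`), and
#'   `counts` (tibble of per-rule removal counts).
#' @export
apply_filters <- function(trace,
                          acc_max_m = 25,
                          accel_min_ms2 = 0.5,
                          speed_max_ms = 5,
                          trim_leading_lock = FALSE,
                          start_lock_m = 15) {
  if (nrow(trace) < 1) abort("cannot filter an empty trace")
  if (acc_max_m < 0 || accel_min_ms2 < 0 || speed_max_ms < 0 || start_lock_m < 0) {
    abort("filter thresholds must be non-negative")
  }

  n <- nrow(trace)
  start_at <- 1L
  if (trim_leading_lock) {
    lock <- which(!is.na(trace$acc) & trace$acc < start_lock_m)
    if (length(lock) == 0) abort("no sample ever reaches the start lock accuracy")
    start_at <- lock[1]
  }

  rule <- rep(NA_character_, n)
  value <- rep(NA_real_, n)
  if (start_at > 1L) {
    rule[seq_len(start_at - 1L)] <- "lock"
    value[seq_len(start_at - 1L)] <- trace$acc[seq_len(start_at - 1L)]
  }

  last_kept <- NA_integer_
  for (i in start_at:n) {
    if (is.na(trace$alt[i])) {
      rule[i] <- "R1"; value[i] <- NA_real_; next
    }
    if (!is.na(trace$acc[i]) && trace$acc[i] > acc_max_m) {
      rule[i] <- "R2"; value[i] <- trace$acc[i]; next
    }
    if (!is.na(trace$accel_mag[i]) && trace$accel_mag[i] < accel_min_ms2) {
      rule[i] <- "R3"; value[i] <- trace$accel_mag[i]; next
    }
    if (!is.na(last_kept)) {
      if (!is.na(trace$steps[i]) && !is.na(trace$steps[last_kept]) &&
          trace$steps[i] - trace$steps[last_kept] == 0) {
        rule[i] <- "R4"; value[i] <- 0; next
      }
      dt <- trace$t[i] - trace$t[last_kept]
      if (dt <= 0) {
        rule[i] <- "R5"; value[i] <- dt; next
      }
      v <- haversine_m(trace$lat[last_kept], trace$lon[last_kept],
                       trace$lat[i], trace$lon[i]) / dt
      if (v > speed_max_ms) {
        rule[i] <- "R6"; value[i] <- v; next
      }
    }
    last_kept <- i
  }

  removed_idx <- which(!is.na(rule))
  kept_idx <- setdiff(seq_len(n), removed_idx)
  kept <- rewrap_trace(as_tibble(as.data.frame(trace))[kept_idx, ], trace)
  removed <- tibble(index = removed_idx,
                    rule = rule[removed_idx],
                    value = value[removed_idx])
  counts <- tibble(rule = c(paste0("R", 1:6), "lock")) %>%
    left_join(dplyr::count(removed, .data$rule, name = "n_removed"), by = "rule") %>%
    mutate(n_removed = ifelse(is.na(.data$n_removed), 0L, .data$n_removed))

  structure(
    list(kept = kept, removed = removed, counts = counts,
         n_input = n, n_kept = length(kept_idx)),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d of %d samples\n", x$n_kept, x$n_input))
  kept_rows <- x$counts[x$counts$n_removed > 0, ]
  if (nrow(kept_rows)) print(kept_rows)
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) x$removed

#' @export
glance.filter_report <- function(x, ...) {
  wide <- setNames(as.list(x$counts$n_removed), paste0("n_", tolower(x$counts$rule)))
  dplyr::bind_cols(tibble(n_input = x$n_input, n_kept = x$n_kept), as_tibble(wide))
}
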