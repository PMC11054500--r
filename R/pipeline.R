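#' Evaluate all estimators over a cohort of traces
#'
#' Runs every distance estimator on each trace, with and without
#' pre-processing, and returns a tidy per-trace, per-algorithm error table
#' against the ground-truth distances.
#'
#' @param cohort tibble as returned by [simulate_cohort()] (needs list-column
#'   `trace` and `true_distance_m`), or any tibble with those columns.
#' @param ... threshold overrides passed to [apply_filters()].
#' @return tibble with columns `test_id`, `participant_id`, `path_type`,
#'   `label`, `algorithm`, `preprocessed`, `distance_m`, `reference_m`,
#'   `error_m`, `ape` (absolute percentage error).
#' @export
evaluate_cohort <- function(cohort, ...) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    trace <- cohort$trace[[i]]
    ref <- cohort$true_distance_m[i]
    both <- bind_rows(
      mutate(estimate_distances(trace, preprocess = TRUE, ...), preprocessed = TRUE),
      mutate(estimate_distances(trace, preprocess = FALSE), preprocessed = FALSE)
    )
    tibble(
      test_id = cohort$test_id[i] %||% as.character(i),
      participant_id = cohort$participant_id[i] %||% "unknown",
      path_type = cohort$path_type[i] %||% "unknown",
      label = cohort$label[i] %||% "unknown",
      algorithm = both$algorithm,
      preprocessed = both$preprocessed,
      distance_m = both$distance_m,
      reference_m = ref,
      error_m = both$distance_m - ref,
      ape = 100 * abs(both$distance_m - ref) / ref
    )
  })
}

#' Extract quality features for every trace of a cohort
#'
#' Filters each trace, extracts the 52-feature quality vector (the
#' `delta_distance` feature uses the raw trace), and binds the cohort
#' metadata columns.
#'
#' @inheritParams evaluate_cohort
#' @return tibble with metadata columns plus the 52 feature columns.
#' @export
cohort_features <- function(cohort, ...) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    trace <- cohort$trace[[i]]
    kept <- apply_filters(trace, ...)$kept
    feats <- extract_features(kept, trace)
    dplyr::bind_cols(
      tibble(
        test_id = cohort$test_id[i] %||% as.character(i),
        participant_id = cohort$participant_id[i] %||% "unknown",
        path_type = cohort$path_type[i] %||% "unknown",
        label = cohort$label[i] %||% "unknown"
      ),
      feats
    )
  })
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' End-to-end convenience driver: simulate (or accept) a cohort, filter,
#' estimate distances with all six algorithms, compute agreement statistics,
#' extract features, and train the user-based reliability classifiers.
#' Artifacts are written to `out_dir` as plain CSV/JSON files along with a
#' run manifest; nothing in the input is mutated.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort an existing cohort tibble, or `NULL` to simulate one.
#' @param n_participants,tests_per_participant,noise,seed passed to
#'   [simulate_cohort()] when `cohort` is `NULL`; `seed` also drives the
#'   classifier folds.
#' @return invisibly, a list with `errors`, `agreement`, `features`,
#'   `classifier` and the manifest path.
#' @export
run_pipeline <- function(out_dir,
                         cohort = NULL,
                         n_participants = 10,
                         tests_per_participant = 4,
                         noise = noise_config(),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(n_participants, tests_per_participant,
                              noise = noise, seed = seed)
  }
  errors <- evaluate_cohort(cohort)
  readr::write_csv(errors, file.path(out_dir, "distance_errors.csv"))

  agreement <- errors %>%
    filter(.data$preprocessed) %>%
    group_by(.data$algorithm) %>%
    dplyr::group_modify(function(d, g) {
      glance(error_summary(
        tibble(reference_m = d$reference_m, estimate_m = d$distance_m),
        mode = "percent"
      ))
    }) %>%
    ungroup()
  readr::write_csv(agreement, file.path(out_dir, "agreement.csv"))

  feats <- cohort_features(cohort)
  readr::write_csv(feats, file.path(out_dir, "features.csv"))

  ref_cols <- unique(unlist(reference_model("user_based")$bindings))
  red <- vif_reduce(feats[, ref_cols])
  report <- train_evaluate(red$features, feats$label == "unconventional",
                           seed = seed)
  readr::write_csv(report$metrics, file.path(out_dir, "classifier_metrics.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("sixmwt")),
    seed = seed,
    n_traces = nrow(cohort),
    thresholds = sixmwt_defaults(),
    outputs = c("distance_errors.csv", "agreement.csv", "features.csv",
                "classifier_metrics.csv")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(errors = errors, agreement = agreement, features = feats,
                 classifier = report, manifest = manifest_path))
}
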