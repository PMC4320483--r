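#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param ... Overrides for any field.
#' @return Named list: `input` (trace CSV path, or `NULL` to simulate the
#'   default synthetic cohort), `seed`, `zero_threshold`, `method`
#'   (`"kde"`/`"knn"`), `priors`, `bandwidth_floor_rel`, `k`, `schemes`,
#'   `combinations` (list of metric subsets; `NULL` = all 63),
#'   `strata`, `val_size`, `include_invalid_val` (adds the sensitivity run),
#'   `out_dir`.
#' @export
default_run_config <- function(out_dir = tempfile("modeshift_run_"), ...) {
  cfg <- list(
    input = NULL,
    seed = 20140L,
    zero_threshold = 0,
    method = "kde",
    priors = "equal",
    bandwidth_floor_rel = 1e-6,
    k = 5L,
    schemes = c("five_class", "three_class"),
    combinations = list(c("p95", "accel", "decel")),
    strata = c("all", STRATUM_LEVELS),
    val_size = 4L,
    include_invalid_val = FALSE,
    out_dir = out_dir
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full recognition pipeline
#'
#' Orchestrates ingestion (or synthetic-cohort simulation), indoor filtering,
#' zero-speed segmentation, feature computation and exhaustive person-level
#' cross-validation; writes `results.csv`, `summary.csv`, `calibration.csv`,
#' `manifest.json` (the config echoed verbatim plus stage counts) and
#' `log.txt` into `config$out_dir`. Stage counts reconcile: points read =
#' points kept + indoor dropped; sequences formed = sequences featurized +
#' N<2 drops.
#'
#' @param config Configuration list, see [default_run_config()].
#' @return (Invisibly) a list with `features`, `splits`, `runs` (per-scheme
#'   [run_crossval()] output, plus `sensitivity_*` entries when requested),
#'   `calibration`, and `counts`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  points <- if (is.null(config$input)) {
    simulate_cohort(default_cohort_config(seed = config$seed))
  } else {
    read_trace_csv(config$input)
  }
  if (nrow(points) == 0L) {
    abort("Ingestion produced no track points (stage: read).",
          class = "modeshift_data_error")
  }
  filtered <- filter_indoor(points)
  seqs <- segment_trace(filtered, zero_threshold = config$zero_threshold)
  if (nrow(seqs) == 0L) {
    abort("No sequences after segmentation (stage: segment).",
          class = "modeshift_data_error")
  }
  features <- sequence_features(seqs)
  combos <- config$combinations
  if (is.null(combos)) combos <- metric_combinations()
  splits <- enumerate_splits(features, val_size = config$val_size)
  runs <- list()
  for (scheme in config$schemes) {
    runs[[scheme]] <- run_crossval(
      features, splits, combos, scheme = scheme, strata = config$strata,
      method = config$method, priors = config$priors,
      bandwidth_floor_rel = config$bandwidth_floor_rel, k = config$k
    )
    if (isTRUE(config$include_invalid_val)) {
      runs[[paste0("sensitivity_", scheme)]] <- run_sensitivity(
        features, splits, combos, scheme = scheme, strata = config$strata,
        method = config$method, priors = config$priors,
        bandwidth_floor_rel = config$bandwidth_floor_rel, k = config$k
      )
    }
  }
  calib <- calibration_report(seqs)
  counts <- list(
    points_read = nrow(points),
    points_kept = nrow(filtered),
    points_dropped_indoor = attr(filtered, "n_dropped_indoor"),
    share_dropped = (nrow(points) - nrow(filtered)) / nrow(points),
    zero_delimiter_points = attr(seqs, "n_zero_points"),
    mode_change_cuts = attr(seqs, "n_mode_cuts"),
    sequences_formed = nrow(seqs),
    sequences_featurized = nrow(features),
    sequences_dropped_short = attr(features, "n_dropped_short"),
    splits_enumerated = nrow(splits),
    splits_valid_dev = sum(splits$valid_dev),
    splits_valid_both = sum(splits$valid_dev & splits$valid_val)
  )
  results <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    r <- runs[[nm]]$results
    if (nrow(r) > 0L) r$run <- nm
    r
  }))
  summaries <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    s <- runs[[nm]]$summary
    if (nrow(s) > 0L) s$run <- nm
    s
  }))
  readr::write_csv(results, file.path(config$out_dir, "results.csv"),
                   progress = FALSE)
  readr::write_csv(summaries, file.path(config$out_dir, "summary.csv"),
                   progress = FALSE)
  readr::write_csv(calib, file.path(config$out_dir, "calibration.csv"),
                   progress = FALSE)
  manifest <- list(config = config, counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  log_lines <- c(
    sprintf("points read: %d", counts$points_read),
    sprintf("indoor points dropped: %d (%.2f%%)",
            counts$points_dropped_indoor, 100 * counts$share_dropped),
    sprintf("zero-speed delimiter points: %d", counts$zero_delimiter_points),
    sprintf("sequences formed: %d", counts$sequences_formed),
    sprintf("sequences dropped (duration < 2 s): %d",
            counts$sequences_dropped_short),
    sprintf("mode-change cuts: %d", counts$mode_change_cuts),
    sprintf("splits enumerated: %d (valid dev: %d, valid both: %d)",
            counts$splits_enumerated, counts$splits_valid_dev,
            counts$splits_valid_both)
  )
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(list(features = features, splits = splits, runs = runs,
                 calibration = calib, counts = counts))
}
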