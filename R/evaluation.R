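#' Enumerate person-level development/validation splits
#'
#' All `C(n, val_size)` unordered partitions of the cohort into a development
#' set (model fitting) and a validation set (kappa computation), in
#' deterministic order (lexicographic by the sorted validation set). For each
#' split, `valid_dev` / `valid_val` record whether every transport mode
#' present in the sequence table is carried by at least one person on that
#' side; the main cross-validation uses only splits valid on both sides,
#' the sensitivity run only requires `valid_dev`.
#'
#' @param sequences Sequence or feature tibble (used for the person-to-mode
#'   incidence).
#' @param person_ids Cohort person ids; defaults to those in `sequences`.
#' @param val_size Validation-set size (default 4, of a 12-person cohort).
#' @return Tibble with columns `split_id`, `val` and `dev` (list-columns of
#'   person ids), `valid_dev`, `valid_val`.
#' @export
enumerate_splits <- function(sequences, person_ids = NULL, val_size = 4L) {
  if (is.null(person_ids)) person_ids <- sort(unique(sequences$person_id))
  person_ids <- sort(as.character(person_ids))
  n <- length(person_ids)
  if (val_size <= 0L || val_size >= n) {
    abort("`val_size` must be strictly between 0 and the cohort size.",
          class = "modeshift_config_error")
  }
  modes_all <- sort(unique(sequences$mode))
  person_modes <- split(sequences$mode, sequences$person_id)
  covers <- function(persons) {
    all(modes_all %in% unique(unlist(person_modes[persons], use.names = FALSE)))
  }
  sets <- combn(person_ids, val_size, simplify = FALSE)
  tibble::tibble(
    split_id = seq_along(sets),
    val = sets,
    dev = lapply(sets, function(v) setdiff(person_ids, v)),
    valid_dev = vapply(sets, function(v) covers(setdiff(person_ids, v)), logical(1)),
    valid_val = vapply(sets, covers, logical(1))
  )
}

#' All metric combinations of size 1 to `max_size`
#'
#' @param metrics Metric names; defaults to the seven speed metrics.
#' @param max_size Largest subset size, in `{1, 2, 3}`.
#' @return List of character vectors in deterministic order (by size, then
#'   combinatorial order). With 7 metrics and `max_size = 3` this yields
#'   7 + 21 + 35 = 63 subsets.
#' @export
metric_combinations <- function(metrics = METRIC_NAMES, max_size = 3L) {
  if (!max_size %in% 1:3) {
    abort("`max_size` must be 1, 2 or 3.", class = "modeshift_config_error")
  }
  sizes <- seq_len(min(max_size, length(metrics)))
  unlist(lapply(sizes, function(k) combn(metrics, k, simplify = FALSE)),
         recursive = FALSE)
}

#' Collapse motorized modes into one class
#'
#' Relabels `train`, `bus` and `car` as `motorized` (they all represent
#' sedentary travel); `walk` and `bike` pass through. Applied to labels
#' *before* model fitting under the three-class scheme.
#'
#' @param mode Character vector of mode labels.
#' @return Relabelled character vector.
#' @export
collapse_motorized <- function(mode) {
  ifelse(mode %in% c("train", "bus", "car"), "motorized", mode)
}

#' Confusion table between true and predicted labels
#'
#' @param true,predicted Label vectors of equal length.
#' @param classes Ordered class set; defaults to the canonical order over the
#'   labels observed.
#' @return Integer matrix, rows = true, columns = predicted.
#' @export
confusion_table <- function(true, predicted, classes = NULL) {
  if (is.null(classes)) classes <- class_sort(unique(c(true, predicted)))
  as.matrix(table(
    factor(true, levels = classes),
    factor(predicted, levels = classes)
  ))
}

#' Cohen's kappa from a confusion table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` the diagonal share and expected agreement
#' `p_e = sum_c (row_c/N) * (col_c/N)` from the marginals. When `p_e = 1`
#' (all mass in a single cell, e.g. a validation set carrying one class
#' predicted perfectly) the convention `kappa = 0` applies: agreement is then
#' fully explained by chance.
#'
#' @param confusion Square count matrix (rows = true, columns = predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  n <- sum(confusion)
  if (n < 1) {
    abort("Confusion table is empty.", class = "modeshift_domain_error")
  }
  po <- sum(diag(confusion)) / n
  pe <- sum((rowSums(confusion) / n) * (colSums(confusion) / n))
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Observed (absolute) agreement from a confusion table
#'
#' @inheritParams cohens_kappa
#' @return Diagonal share in `[0, 1]`.
#' @export
observed_agreement <- function(confusion) {
  n <- sum(confusion)
  if (n < 1) {
    abort("Confusion table is empty.", class = "modeshift_domain_error")
  }
  sum(diag(confusion)) / n
}

#' Evaluate one development/validation split
#'
#' Fits the discriminant on the development persons' sequences (all
#' durations) and evaluates kappa and observed agreement on the validation
#' persons' sequences, per requested duration stratum. Under
#' `scheme = "three_class"` labels are collapsed with [collapse_motorized()]
#' before fitting. Strata with no validation sequences are omitted.
#'
#' @param split A row of [enumerate_splits()] output, or a list with `dev`
#'   and `val` person-id vectors.
#' @param features Feature tibble from [sequence_features()].
#' @param combination Metric subset (1-3 names).
#' @param scheme `"five_class"` or `"three_class"`.
#' @param strata Strata to report: any of `"all"` and the four duration bins
#'   (default: all five read-outs).
#' @param stratum_matched_training If `TRUE`, fit a separate model per
#'   stratum on development sequences of that stratum only (default `FALSE`:
#'   one model on all durations).
#' @param ... Passed to [fit_discriminant()] (`method`, `priors`, `k`, ...).
#' @return Tibble with one row per stratum: `scheme`, `combination`,
#'   `stratum`, `kappa`, `agreement`, `n_sequences`.
#' @export
evaluate_split <- function(split, features, combination,
                           scheme = c("five_class", "three_class"),
                           strata = c("all", STRATUM_LEVELS),
                           stratum_matched_training = FALSE, ...) {
  scheme <- match.arg(scheme)
  dev_p <- unlist(split$dev)
  val_p <- unlist(split$val)
  labels <- features$mode
  if (scheme == "three_class") labels <- collapse_motorized(labels)
  classes <- class_sort(unique(labels))
  dev_idx <- features$person_id %in% dev_p
  val_idx <- features$person_id %in% val_p
  res <- list()
  fit_once <- NULL
  for (st in strata) {
    v <- if (st == "all") val_idx else val_idx & features$stratum == st
    if (!any(v)) next
    if (stratum_matched_training && st != "all") {
      d <- dev_idx & features$stratum == st
      if (length(unique(labels[d])) < 2L) next
      model <- fit_discriminant(features[d, ], labels[d], combination, ...)
    } else {
      if (is.null(fit_once)) {
        fit_once <- fit_discriminant(features[dev_idx, ], labels[dev_idx],
                                     combination, ...)
      }
      model <- fit_once
    }
    pred <- predict(model, features[v, ])
    ct <- confusion_table(labels[v], pred, classes = classes)
    res[[length(res) + 1L]] <- tibble::tibble(
      scheme = scheme,
      combination = paste(combination, collapse = "+"),
      stratum = st,
      kappa = cohens_kappa(ct),
      agreement = observed_agreement(ct),
      n_sequences = sum(v)
    )
  }
  dplyr::bind_rows(res)
}

#' Exhaustive cross-validation over splits and metric combinations
#'
#' The main analysis: for every metric combination and every split with full
#' mode coverage in *both* development and validation sets, fit on the
#' development persons and score the validation persons, per duration
#' stratum. Summaries report the median and interquartile range (type-7
#' percentiles) of kappa over splits, and the median observed agreement, per
#' combination x stratum.
#'
#' @param features Feature tibble.
#' @param splits Output of [enumerate_splits()].
#' @param combinations List of metric subsets (see [metric_combinations()]),
#'   or a single character vector.
#' @param scheme `"five_class"` or `"three_class"`.
#' @param strata Strata to evaluate (default all five read-outs).
#' @param require_valid_val If `FALSE` (the sensitivity analysis, see
#'   [run_sensitivity()]) splits only need full coverage on the development
#'   side.
#' @param ... Passed on to [evaluate_split()] / [fit_discriminant()].
#' @return List with `results` (one row per split x combination x stratum)
#'   and `summary` (median/IQR rows).
#' @export
run_crossval <- function(features, splits, combinations,
                         scheme = c("five_class", "three_class"),
                         strata = c("all", STRATUM_LEVELS),
                         require_valid_val = TRUE, ...) {
  scheme <- match.arg(scheme)
  if (is.character(combinations)) combinations <- list(combinations)
  use <- splits[splits$valid_dev & (!require_valid_val | splits$valid_val), ]
  if (nrow(use) == 0L) {
    warn("No valid splits: returning empty results.")
    return(list(results = tibble::tibble(), summary = tibble::tibble()))
  }
  out <- vector("list", nrow(use) * length(combinations))
  pos <- 0L
  for (combo in combinations) {
    for (i in seq_len(nrow(use))) {
      r <- evaluate_split(use[i, ], features, combo, scheme = scheme,
                          strata = strata, ...)
      if (nrow(r) > 0L) {
        r$split_id <- use$split_id[i]
        r$val_persons <- paste(sort(unlist(use$val[i])), collapse = ",")
        pos <- pos + 1L
        out[[pos]] <- r
      }
    }
  }
  results <- dplyr::bind_rows(out[seq_len(pos)])
  summary <- summarize_crossval(results)
  list(results = results, summary = summary)
}

#' @rdname run_crossval
#' @export
run_sensitivity <- function(features, splits, combinations,
                            scheme = c("five_class", "three_class"),
                            strata = c("all", STRATUM_LEVELS), ...) {
  run_crossval(features, splits, combinations, scheme = scheme,
               strata = strata, require_valid_val = FALSE, ...)
}

#' Median/IQR kappa summaries over splits
#'
#' @param results Per-split results from [run_crossval()].
#' @return Tibble with one row per combination x scheme x stratum: median
#'   kappa, 25th/75th kappa percentiles, median observed agreement, split
#'   count.
#' @export
summarize_crossval <- function(results) {
  if (nrow(results) == 0L) return(tibble::tibble())
  results |>
    dplyr::group_by(.data$scheme, .data$combination, .data$stratum) |>
    dplyr::summarise(
      kappa_median = percentile(.data$kappa, 0.5),
      kappa_q25 = percentile(.data$kappa, 0.25),
      kappa_q75 = percentile(.data$kappa, 0.75),
      agreement_median = percentile(.data$agreement, 0.5),
      n_splits = dplyr::n(),
      .groups = "drop"
    )
}

#' Share of observation time in sequences longer than a threshold
#'
#' Long sequences are classified reliably; this reports how much of the
#' total observed travel time they carry.
#'
#' @param sequences Sequence or feature tibble with a `duration` column.
#' @param min_duration Threshold in seconds (default 60; strictly longer
#'   sequences count).
#' @return Proportion in `[0, 1]`.
#' @export
observation_time_share <- function(sequences, min_duration = 60) {
  if (nrow(sequences) == 0L) {
    abort("Empty sequence table.", class = "modeshift_domain_error")
  }
  sum(sequences$duration[sequences$duration > min_duration]) /
    sum(sequences$duration)
}
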