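#' Speed metrics for a single sequence
#'
#' Computes the seven per-sequence speed metrics that form the discriminant
#' feature space:
#'
#' * `mean` — mean speed (km/h);
#' * `p95` — 95th percentile of speed (km/h), type-7 interpolation;
#' * `sd` — sample standard deviation of speed (km/h, denominator N-1);
#' * `rcm` — rate-of-change metric, the mean absolute second-to-second speed
#'   change `(1/(N-1)) * sum |S_n - S_(n-1)|` (km/h per second);
#' * `rcm_std` — standardized rate of change, `rcm / sd`, with the
#'   convention `rcm_std = 0` for a constant sequence (`sd = 0`);
#' * `accel` — 95th percentile of consecutive speed differences (km/h per
#'   second), a proxy for strong acceleration events;
#' * `decel` — 5th percentile of the same differences, a proxy for braking.
#'
#' @param speeds Numeric vector of at least two 1 Hz speed observations
#'   (km/h).
#' @return Named numeric vector with elements
#'   `mean, p95, sd, rcm, rcm_std, accel, decel`.
#' @export
compute_metrics <- function(speeds) {
  n <- length(speeds)
  if (n < 2L) {
    abort("Speed metrics are undefined for sequences with fewer than 2 points.",
          class = "modeshift_undefined_metrics_error")
  }
  d <- diff(speeds)
  s <- sd(speeds)
  r <- mean(abs(d))
  c(
    mean = mean(speeds),
    p95 = percentile(speeds, 0.95),
    sd = s,
    rcm = r,
    rcm_std = if (s > 0) r / s else 0,
    accel = percentile(d, 0.95),
    decel = percentile(d, 0.05)
  )
}

#' Feature table for a sequence table
#'
#' Applies [compute_metrics()] to every sequence of duration >= 2; shorter
#' sequences (possible, e.g., under the mode-change cut) have undefined
#' difference-based metrics and are dropped here and counted in the
#' `n_dropped_short` attribute.
#'
#' @param seqs Sequence tibble from [segment_trace()].
#' @return The sequence tibble without the `speeds` list-column, with the
#'   seven metric columns appended.
#' @export
sequence_features <- function(seqs) {
  keep <- seqs$duration >= 2L
  kept <- seqs[keep, , drop = FALSE]
  if (nrow(kept) > 0L) {
    m <- t(vapply(kept$speeds, compute_metrics, numeric(7)))
    feats <- dplyr::bind_cols(
      kept[, setdiff(names(kept), "speeds")],
      tibble::as_tibble(m)
    )
  } else {
    feats <- kept[, setdiff(names(kept), "speeds")]
    for (nm in METRIC_NAMES) feats[[nm]] <- numeric(0)
  }
  attr(feats, "n_dropped_short") <- sum(!keep)
  feats
}

#' Write a feature table to CSV (full double precision)
#'
#' @param features Feature tibble from [sequence_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  out <- features
  out$stratum <- as.character(out$stratum)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
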