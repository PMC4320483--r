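#' Duration strata
#'
#' Sequence-length bins used to stratify classification performance:
#' `<=15s`, `16-30s`, `31-60s` and `>60s`. The boundaries are inclusive as
#' printed (15 falls in the first bin, 60 in the third, 61 in the fourth), so
#' the four bins partition the positive integers.
#'
#' @param duration Integer sequence duration(s) in seconds, each >= 1.
#' @return Factor with levels `c("<=15s", "16-30s", "31-60s", ">60s")`.
#' @export
assign_stratum <- function(duration) {
  if (any(!is.finite(duration)) || any(duration < 1)) {
    abort("`duration` must be >= 1 second.", class = "modeshift_domain_error")
  }
  cut(duration,
      breaks = c(0, 15, 30, 60, Inf),
      labels = STRATUM_LEVELS,
      right = TRUE)
}

#' @rdname assign_stratum
#' @export
STRATUM_LEVELS <- c("<=15s", "16-30s", "31-60s", ">60s")

#' Cut speed traces into sequences at zero speed
#'
#' A *sequence* is a maximal run of consecutive points whose speed exceeds
#' `zero_threshold` (default 0 km/h, exact equality: zero speed is read as
#' "no transport"). Delimiter points are discarded. A change of annotated
#' mode inside a run also cuts the sequence, so each sequence carries a
#' single true mode label; such cuts are reported via the `n_mode_cuts`
#' attribute.
#'
#' @param points Track-point tibble (already indoor-filtered; see
#'   [filter_indoor()]).
#' @param zero_threshold Speeds at or below this value (km/h) delimit
#'   sequences. Must be >= 0.
#' @return A sequence tibble with one row per sequence: `person_id`,
#'   `commute_id`, `trace_id`, `seq_id`, `mode`, `duration` (the count of
#'   1 Hz observations), `stratum`, and list-column `speeds`. Attributes
#'   `n_zero_points` (discarded delimiters) and `n_mode_cuts` are attached.
#' @export
segment_trace <- function(points, zero_threshold = 0) {
  if (!is.numeric(zero_threshold) || zero_threshold < 0) {
    abort("`zero_threshold` must be >= 0.", class = "modeshift_domain_error")
  }
  empty <- tibble::tibble(
    person_id = character(), commute_id = character(), trace_id = character(),
    seq_id = character(), mode = character(), duration = integer(),
    stratum = factor(character(), levels = STRATUM_LEVELS),
    speeds = list()
  )
  if (nrow(points) == 0L) {
    attr(empty, "n_zero_points") <- 0L
    attr(empty, "n_mode_cuts") <- 0L
    return(empty)
  }
  points <- dplyr::arrange(points, .data$trace_id, .data$timestamp)
  n_zero <- 0L
  n_mode_cuts <- 0L
  rows <- list()
  for (tid in unique(points$trace_id)) {
    tr <- points[points$trace_id == tid, , drop = FALSE]
    moving <- tr$speed_kmh > zero_threshold
    n_zero <- n_zero + sum(!moving)
    # run ids: new run at every transition of moving status or of mode
    run_brk <- c(TRUE, moving[-1] != moving[-length(moving)] |
                   tr$mode[-1] != tr$mode[-nrow(tr)])
    run_id <- cumsum(run_brk)
    for (rid in unique(run_id[moving])) {
      idx <- which(run_id == rid)
      prev_same <- rid > 1L && any(run_id == rid - 1L & moving)
      if (prev_same) n_mode_cuts <- n_mode_cuts + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        person_id = tr$person_id[idx[1L]],
        commute_id = tr$commute_id[idx[1L]],
        trace_id = tid,
        seq_id = sprintf("%s#%03d", tid, rid),
        mode = tr$mode[idx[1L]],
        duration = length(idx),
        speeds = list(tr$speed_kmh[idx])
      )
    }
  }
  if (length(rows) == 0L) {
    attr(empty, "n_zero_points") <- n_zero
    attr(empty, "n_mode_cuts") <- 0L
    return(empty)
  }
  seqs <- dplyr::bind_rows(rows)
  seqs$stratum <- assign_stratum(seqs$duration)
  seqs <- seqs[, c("person_id", "commute_id", "trace_id", "seq_id", "mode",
                   "duration", "stratum", "speeds")]
  attr(seqs, "n_zero_points") <- n_zero
  attr(seqs, "n_mode_cuts") <- n_mode_cuts
  seqs
}

#' Write / read a sequence table (inline-speeds dialect)
#'
#' Serialises the sequence table to CSV with the speed list inlined as a
#' `;`-separated string, and reads it back bit-exactly.
#'
#' @param seqs Sequence tibble from [segment_trace()].
#' @param path File path.
#' @return `write_sequences_csv()` returns `path` invisibly;
#'   `read_sequences_csv()` returns the sequence tibble.
#' @export
write_sequences_csv <- function(seqs, path) {
  out <- seqs[, c("person_id", "commute_id", "trace_id", "seq_id", "mode",
                  "duration", "stratum")]
  out$stratum <- as.character(out$stratum)
  out$speeds <- vapply(
    seqs$speeds,
    function(s) paste(format(s, digits = 17, trim = TRUE, scientific = FALSE),
                      collapse = ";"),
    character(1)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @export
read_sequences_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    person_id = as.character(raw$person_id),
    commute_id = as.character(raw$commute_id),
    trace_id = as.character(raw$trace_id),
    seq_id = as.character(raw$seq_id),
    mode = as.character(raw$mode),
    duration = as.integer(raw$duration),
    stratum = factor(raw$stratum, levels = STRATUM_LEVELS),
    speeds = lapply(strsplit(raw$speeds, ";", fixed = TRUE), as.numeric)
  )
}
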