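#' Read GPS traces from the canonical CSV format
#'
#' The canonical interchange format is a UTF-8 CSV with one row per 1 Hz
#' track point and columns `person_id`, `commute_id`, `timestamp` (seconds),
#' `speed_kmh`, and optionally `lat`, `lon` (decimal degrees WGS84, may be
#' empty), `indoor` (0/1) and `mode` (one of walk/bike/train/bus/car/unknown).
#' A *trace* is the set of rows sharing one `(person_id, commute_id)` pair;
#' the returned table carries a `trace_id` key identifying each trace, so a
#' "list of traces" is represented as one tidy table grouped by `trace_id`.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(speed_kmh = "speed")`.
#' @return A tibble of track points, sorted by person, commute and timestamp,
#'   with columns `trace_id`, `person_id`, `commute_id`, `timestamp`,
#'   `speed_kmh`, `lat`, `lon`, `indoor`, `mode`.
#' @seealso [write_trace_csv()], [read_gpx()], [filter_indoor()]
#' @export
read_trace_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Trace file not found: ", path), class = "modeshift_io_error")
  }
  # read everything as text and convert with base R's correctly rounded
  # strtod, so doubles written at full precision round-trip bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(dialect)) {
    for (canonical in names(dialect)) {
      if (dialect[[canonical]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[canonical]]] <- canonical
      }
    }
  }
  required <- c("person_id", "commute_id", "timestamp", "speed_kmh")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(
      paste0("Trace CSV is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "modeshift_schema_error"
    )
  }
  pts <- tibble::tibble(
    person_id  = as.character(raw$person_id),
    commute_id = as.character(raw$commute_id),
    timestamp  = as.integer(raw$timestamp),
    speed_kmh  = as.numeric(raw$speed_kmh),
    lat        = if ("lat" %in% names(raw)) as.numeric(raw$lat) else NA_real_,
    lon        = if ("lon" %in% names(raw)) as.numeric(raw$lon) else NA_real_,
    indoor     = if ("indoor" %in% names(raw)) as.logical(as.integer(raw$indoor)) else FALSE,
    mode       = if ("mode" %in% names(raw)) as.character(raw$mode) else "unknown"
  )
  bad_speed <- which(!is.finite(pts$speed_kmh) | pts$speed_kmh < 0)
  if (length(bad_speed) > 0L) {
    abort(
      paste0("Non-finite or negative speed in row(s): ",
             paste(head(bad_speed, 5L), collapse = ", ")),
      class = "modeshift_schema_error"
    )
  }
  bad_coord <- which((!is.na(pts$lat) & abs(pts$lat) > 90) |
                       (!is.na(pts$lon) & abs(pts$lon) > 180))
  if (length(bad_coord) > 0L) {
    abort(
      paste0("Coordinates out of WGS84 range in row(s): ",
             paste(head(bad_coord, 5L), collapse = ", ")),
      class = "modeshift_schema_error"
    )
  }
  pts <- dplyr::arrange(pts, .data$person_id, .data$commute_id, .data$timestamp)
  dup <- duplicated(pts[, c("person_id", "commute_id", "timestamp")])
  if (any(dup)) {
    key <- pts[which(dup)[1L], ]
    abort(
      paste0("Duplicate track point for person ", key$person_id, ", commute ",
             key$commute_id, ", timestamp ", key$timestamp),
      class = "modeshift_duplicate_error"
    )
  }
  dplyr::mutate(
    pts,
    trace_id = paste(.data$person_id, .data$commute_id, sep = "/"),
    .before = 1L
  )
}

#' Write GPS traces to the canonical CSV format
#'
#' Inverse of [read_trace_csv()]: all fields round-trip exactly (doubles are
#' written with shortest round-trip precision).
#'
#' @param points Track-point tibble as returned by [read_trace_csv()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(points, path) {
  out <- points[, c("person_id", "commute_id", "timestamp", "speed_kmh",
                    "lat", "lon", "indoor", "mode")]
  out$indoor <- as.integer(out$indoor)
  # %.17g guarantees an exact double round trip through text
  for (col in c("speed_kmh", "lat", "lon")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Great-circle distance between WGS84 coordinates
#'
#' Haversine distance on a sphere with mean Earth radius 6371.0088 km.
#' Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Derive speed between two track points from coordinates
#'
#' Great-circle distance divided by elapsed time, in km/h. Used when a GPX
#' input carries no logged speed. The result is unsigned: swapping the two
#' points gives the same value.
#'
#' @param lat1,lon1 Coordinates of the earlier point (decimal degrees).
#' @param t1 Timestamp of the earlier point (seconds).
#' @param lat2,lon2,t2 Coordinates and timestamp of the later point.
#' @return Speed in km/h (never negative). Vectorised.
#' @export
derive_speed <- function(lat1, lon1, t1, lat2, lon2, t2) {
  dt <- abs(as.numeric(t2) - as.numeric(t1))
  if (any(dt == 0)) {
    abort("Cannot derive speed across an interval of zero duration.",
          class = "modeshift_invalid_interval_error")
  }
  haversine_km(lat1, lon1, lat2, lon2) / (dt / 3600)
}

#' Read GPS traces from a GPX 1.1 file
#'
#' Each track segment (`<trkseg>`) becomes one trace. Speed is taken from a
#' per-trackpoint `<speed>` extension element when every point carries one
#' (values are passed through unchanged, in km/h); otherwise it is derived
#' from consecutive coordinates with [derive_speed()] (the first point of a
#' segment gets speed 0). Timestamps are converted to seconds from segment
#' start.
#'
#' @param path Path to a GPX 1.1 file.
#' @param person_id Person identifier to assign (GPX has no standard field
#'   for it); defaults to the file name without extension.
#' @return Track-point tibble in the same layout as [read_trace_csv()], with
#'   `commute_id` set to `trk<i>.seg<j>`.
#' @export
read_gpx <- function(path, person_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("GPX file not found: ", path), class = "modeshift_io_error")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      abort(paste0("Malformed GPX XML: ", conditionMessage(e)),
            class = "modeshift_parse_error")
    }
  )
  xml2::xml_ns_strip(doc)
  if (is.null(person_id)) {
    person_id <- sub("\\.[^.]*$", "", basename(path))
  }
  segs <- xml2::xml_find_all(doc, ".//trk/trkseg")
  out <- list()
  trk_nodes <- xml2::xml_find_all(doc, ".//trk")
  seg_counter <- 0L
  for (ti in seq_along(trk_nodes)) {
    trk_segs <- xml2::xml_find_all(trk_nodes[[ti]], "./trkseg")
    for (si in seq_along(trk_segs)) {
      seg_counter <- seg_counter + 1L
      pts <- xml2::xml_find_all(trk_segs[[si]], "./trkpt")
      if (length(pts) == 0L) next
      lat <- as.numeric(xml2::xml_attr(pts, "lat"))
      lon <- as.numeric(xml2::xml_attr(pts, "lon"))
      time_txt <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
      speed_txt <- xml2::xml_text(xml2::xml_find_first(pts, ".//speed"))
      speed <- suppressWarnings(as.numeric(speed_txt))
      have_speed <- all(!is.na(speed))
      tsec <- gpx_time_seconds(time_txt)
      if (!have_speed) {
        if (any(is.na(tsec))) {
          abort("Track point without <time>: cannot derive speed.",
                class = "modeshift_missing_time_error")
        }
        n <- length(lat)
        speed <- c(0, derive_speed(lat[-n], lon[-n], tsec[-n],
                                   lat[-1], lon[-1], tsec[-1]))
      }
      t0 <- if (all(is.na(tsec))) seq_along(lat) - 1L else tsec - tsec[1L]
      commute_id <- sprintf("trk%d.seg%d", ti, si)
      out[[seg_counter]] <- tibble::tibble(
        trace_id = paste(person_id, commute_id, sep = "/"),
        person_id = person_id,
        commute_id = commute_id,
        timestamp = as.integer(round(t0)),
        speed_kmh = speed,
        lat = lat, lon = lon,
        indoor = FALSE,
        mode = "unknown"
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      trace_id = character(), person_id = character(),
      commute_id = character(), timestamp = integer(),
      speed_kmh = numeric(), lat = numeric(), lon = numeric(),
      indoor = logical(), mode = character()
    ))
  }
  dplyr::bind_rows(out)
}

# ISO-8601 GPX time strings -> numeric seconds (NA-safe)
gpx_time_seconds <- function(x) {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  as.numeric(t)
}

#' Remove indoor points and split traces at the gaps
#'
#' Drops every point flagged `indoor`; each maximal run of surviving points
#' with contiguous (1 Hz) timestamps becomes its own trace, so later
#' segmentation never bridges a removed indoor run. Timestamp gaps larger
#' than one second split a trace the same way, because the
#' consecutive-difference metrics assume 1 Hz spacing.
#'
#' @param points Track-point tibble (see [read_trace_csv()]).
#' @return The filtered tibble; `trace_id` gains a `.partN` suffix wherever a
#'   trace was split. Attribute `n_dropped_indoor` records the removed count.
#' @export
filter_indoor <- function(points) {
  kept <- points[!points$indoor, , drop = FALSE]
  n_dropped <- nrow(points) - nrow(kept)
  if (nrow(kept) > 0L) {
    kept <- kept |>
      dplyr::group_by(.data$person_id, .data$commute_id) |>
      dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
      dplyr::mutate(part = cumsum(c(1L, diff(.data$timestamp) > 1L))) |>
      dplyr::ungroup()
    multi <- kept |>
      dplyr::group_by(.data$person_id, .data$commute_id) |>
      dplyr::mutate(n_parts = max(.data$part)) |>
      dplyr::ungroup()
    kept$trace_id <- ifelse(
      multi$n_parts > 1L,
      paste0(kept$person_id, "/", kept$commute_id, ".part", kept$part),
      paste0(kept$person_id, "/", kept$commute_id)
    )
    kept$part <- NULL
  }
  attr(kept, "n_dropped_indoor") <- n_dropped
  kept
}
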