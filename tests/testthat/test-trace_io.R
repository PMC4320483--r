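test_that("CSV reading groups rows into traces and validates the schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,commute_id,timestamp,speed_kmh,lat,lon,indoor,mode",
    "p1,c1,0,0,,,0,walk",
    "p1,c1,1,5,,,0,walk",
    "p1,c1,2,6,,,0,walk"
  ), f)
  pts <- read_trace_csv(f)
  expect_equal(nrow(pts), 3L)
  expect_equal(length(unique(pts$trace_id)), 1L)
  expect_equal(pts$speed_kmh, c(0, 5, 6))
  expect_equal(pts$timestamp, 0:2)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,commute_id,timestamp,speed_kmh",
    "p1,c2,0,1", "p1,c2,1,2", "p1,c2,2,3",
    "p1,c1,0,4", "p1,c1,1,5", "p1,c1,2,6"
  ), f2)
  pts2 <- read_trace_csv(f2)
  expect_equal(length(unique(pts2$trace_id)), 2L)
  expect_equal(unname(table(pts2$trace_id))[1:2], c(3L, 3L),
               ignore_attr = TRUE)
  # sorted by commute then timestamp
  expect_equal(pts2$speed_kmh[1:3], c(4, 5, 6))
})

test_that("CSV reading rejects bad speeds, missing columns and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,commute_id,timestamp,speed_kmh",
    "p1,c1,0,3", "p1,c1,1,-1"
  ), f)
  expect_error(read_trace_csv(f), "row", class = "modeshift_schema_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,commute_id,timestamp", "p1,c1,0"), f2)
  expect_error(read_trace_csv(f2), "speed_kmh",
               class = "modeshift_schema_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,commute_id,timestamp,speed_kmh",
    "p1,c1,0,3", "p1,c1,0,4"
  ), f3)
  expect_error(read_trace_csv(f3), "Duplicate",
               class = "modeshift_duplicate_error")
})

test_that("trace CSV round-trips every field exactly", {
  set.seed(42)
  pts <- tibble::tibble(
    trace_id = "pX/c1", person_id = "pX", commute_id = "c1",
    timestamp = 0:49,
    speed_kmh = round(runif(50, 0, 120), 7) + runif(50) * 1e-9,
    lat = 52 + cumsum(rnorm(50, 0, 1e-5)),
    lon = 5 + cumsum(rnorm(50, 0, 1e-5)),
    indoor = rep(FALSE, 50),
    mode = sample(c("walk", "bike"), 50, replace = TRUE)
  )
  # sort modes into runs so the table is a valid trace (not required by io)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(pts, f)
  back <- read_trace_csv(f)
  expect_identical(back$speed_kmh, pts$speed_kmh)
  expect_identical(back$lat, pts$lat)
  expect_identical(back$lon, pts$lon)
  expect_identical(back$mode, pts$mode)
  expect_identical(back$timestamp, pts$timestamp)
})

test_that("derive_speed matches closed-form cases and is symmetric", {
  expect_equal(derive_speed(52, 5, 0, 52, 5, 1), 0)
  # 0.001 deg latitude is ~111.195 m of arc; over 1 s that is ~400.3 km/h
  v <- derive_speed(0, 0, 0, 0.001, 0, 1)
  expect_equal(v, 400.3, tolerance = 1e-3)
  expect_equal(derive_speed(0.001, 0, 0, 0, 0, 1), v)
  expect_error(derive_speed(0, 0, 5, 0.001, 0, 5),
               class = "modeshift_invalid_interval_error")
})

test_that("haversine agrees with an independent implementation", {
  set.seed(1)
  n <- 1000
  lat1 <- runif(n, -89, 89); lon1 <- runif(n, -180, 180)
  lat2 <- runif(n, -89, 89); lon2 <- runif(n, -180, 180)
  ours <- haversine_km(lat1, lon1, lat2, lon2) * 1000
  ref <- oracle_haversine_m(lat1, lon1, lat2, lon2)
  expect_equal(ours, ref, tolerance = 1e-9)
})

gpx_header <- '<?xml version="1.0" encoding="UTF-8"?>
<gpx version="1.1" creator="t" xmlns="http://www.topografix.com/GPX/1/1">'

test_that("GPX speed extensions are passed through unchanged", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(paste0(gpx_header, '<trk><trkseg>
    <trkpt lat="52.0" lon="5.0"><time>2010-07-01T08:00:00Z</time>
      <extensions><speed>12.5</speed></extensions></trkpt>
    <trkpt lat="52.0001" lon="5.0"><time>2010-07-01T08:00:01Z</time>
      <extensions><speed>13.25</speed></extensions></trkpt>
  </trkseg></trk></gpx>'), f)
  tr <- read_gpx(f)
  expect_equal(tr$speed_kmh, c(12.5, 13.25))
  expect_equal(tr$timestamp, 0:1)
})

test_that("GPX without speed derives it from coordinates", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines(paste0(gpx_header, '<trk><trkseg>
    <trkpt lat="52.0" lon="5.0"><time>2010-07-01T08:00:00Z</time></trkpt>
    <trkpt lat="52.0" lon="5.0"><time>2010-07-01T08:00:01Z</time></trkpt>
  </trkseg></trk></gpx>'), f)
  tr <- read_gpx(f)
  expect_equal(tr$speed_kmh, c(0, 0))

  f2 <- withr::local_tempfile(fileext = ".gpx")
  writeLines(paste0(gpx_header, '<trk><trkseg>
    <trkpt lat="0" lon="0"><time>2010-07-01T08:00:00Z</time></trkpt>
    <trkpt lat="0" lon="1"><time>2010-07-01T09:00:00Z</time></trkpt>
  </trkseg></trk></gpx>'), f2)
  tr2 <- read_gpx(f2)
  # one degree of longitude on the equator over an hour: ~111.19 km/h
  expect_equal(tr2$speed_kmh[2], 111.19, tolerance = 1e-3)
})

test_that("GPX parsing errors are classified", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines("<gpx><trk><trkseg>", f)
  expect_error(read_gpx(f), class = "modeshift_parse_error")

  f2 <- withr::local_tempfile(fileext = ".gpx")
  writeLines(paste0(gpx_header, '<trk><trkseg>
    <trkpt lat="0" lon="0"></trkpt>
    <trkpt lat="0" lon="1"></trkpt>
  </trkseg></trk></gpx>'), f2)
  expect_error(read_gpx(f2), class = "modeshift_missing_time_error")
})

test_that("indoor filtering removes points and splits traces at the gap", {
  tr <- make_trace(1:10)
  expect_identical(filter_indoor(tr)$speed_kmh, tr$speed_kmh)
  expect_equal(length(unique(filter_indoor(tr)$trace_id)), 1L)

  tr$indoor[4:6] <- TRUE
  out <- filter_indoor(tr)
  expect_equal(nrow(out), 7L)
  expect_equal(attr(out, "n_dropped_indoor"), 3L)
  parts <- split(out$speed_kmh, out$trace_id)
  expect_equal(lengths(parts), c(3L, 4L), ignore_attr = TRUE)
  expect_equal(unname(parts[[1]]), c(1, 2, 3))
  expect_equal(unname(parts[[2]]), c(7, 8, 9, 10))

  tr$indoor <- TRUE
  expect_equal(nrow(filter_indoor(tr)), 0L)
})

test_that("indoor filtering never increases points and respects gaps > 1 s", {
  set.seed(99)
  for (i in 1:20) {
    tr <- make_trace(runif(30, 0, 10))
    tr$indoor <- runif(30) < 0.3
    out <- filter_indoor(tr)
    expect_lte(nrow(out), nrow(tr))
    # within each resulting trace, timestamps are contiguous at 1 Hz
    for (ts in split(out$timestamp, out$trace_id)) {
      if (length(ts) > 1L) expect_true(all(diff(ts) == 1L))
    }
  }
})
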