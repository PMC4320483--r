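# Independent brute-force oracles, coded without reference to the package
# implementation (no stats::quantile, no shared helpers).

# linear interpolation between order statistics at rank 1 + q (n - 1)
oracle_percentile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  r <- 1 + q * (n - 1)
  lo <- floor(r)
  hi <- ceiling(r)
  xs[lo] + (r - lo) * (xs[hi] - xs[lo])
}

oracle_metrics <- function(speeds) {
  n <- length(speeds)
  d <- speeds[-1] - speeds[-n]
  m <- sum(speeds) / n
  s <- sqrt(sum((speeds - m)^2) / (n - 1))
  r <- sum(abs(d)) / (n - 1)
  c(
    mean = m,
    p95 = oracle_percentile(speeds, 0.95),
    sd = s,
    rcm = r,
    rcm_std = if (s > 0) r / s else 0,
    accel = oracle_percentile(d, 0.95),
    decel = oracle_percentile(d, 0.05)
  )
}

# naive O(m*q) product-Gaussian kernel sum, log posterior per class
oracle_kde_posterior <- function(train_by_class, bandwidths_by_class, priors,
                                 x) {
  gauss <- function(z) exp(-z^2 / 2) / sqrt(2 * pi)
  scores <- vapply(seq_along(train_by_class), function(ci) {
    mat <- train_by_class[[ci]]
    h <- bandwidths_by_class[[ci]]
    dens <- 0
    for (i in seq_len(nrow(mat))) {
      k <- 1
      for (j in seq_len(ncol(mat))) {
        k <- k * gauss((x[j] - mat[i, j]) / h[j]) / h[j]
      }
      dens <- dens + k
    }
    priors[ci] * dens / nrow(mat)
  }, numeric(1))
  scores / sum(scores)
}

oracle_haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371008.8)
}

# tiny trace-table constructor for segmentation/feature tests
make_trace <- function(speeds, mode = "walk", person = "pA", commute = "c1") {
  n <- length(speeds)
  tibble::tibble(
    trace_id = paste(person, commute, sep = "/"),
    person_id = person, commute_id = commute,
    timestamp = seq_len(n) - 1L,
    speed_kmh = as.numeric(speeds),
    lat = NA_real_, lon = NA_real_,
    indoor = FALSE,
    mode = if (length(mode) == 1L) rep(mode, n) else mode
  )
}
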