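#' Default mode profiles for the synthetic commute generator
#'
#' One profile per transport mode, parameterising the speed-trace generator:
#'
#' * `cruise_median`, `cruise_iqr` — log-normal law (median and
#'   interquartile range, km/h) for the target mean speed of a long bout;
#'   calibrated to published per-mode sequence-speed distributions of
#'   sequences lasting at least one minute (walk 4.1, bike 14.9, train 88.3,
#'   bus 31.1, car 41.7 km/h with their printed IQRs).
#' * `ar_coefficient`, `noise_sd` — AR(1) second-to-second speed fluctuation
#'   around the deterministic profile (coefficient, innovation SD in km/h).
#' * `ramp_rate` — symmetric acceleration/deceleration ramp (km/h per s).
#' * `bout_duration_median`, `bout_duration_iqr` — log-normal law for short
#'   bout durations (seconds).
#' * `long_share`, `long_duration_median`, `long_duration_iqr` — share of
#'   bouts drawn from the long-bout (>= 61 s) duration law, and that law's
#'   median/IQR; the two-component mixture reproduces both the
#'   short-dominated overall duration distribution and the observed share of
#'   minute-plus sequences per mode.
#' * `stop_duration_mean` — mean length (s) of the zero-speed stop runs
#'   separating bouts.
#' * `n_bouts_range` — bouts per commute leg (uniform integer draw).
#'
#' @return Named list of profile lists, one per mode.
#' @export
default_mode_profiles <- function() {
  prof <- function(mode, cruise_median, cruise_iqr, ar_coefficient, noise_sd,
                   ramp_rate, bout_duration_median, bout_duration_iqr,
                   long_share, long_duration_median, long_duration_iqr,
                   stop_duration_mean, n_bouts_range) {
    list(mode = mode, cruise_median = cruise_median, cruise_iqr = cruise_iqr,
         ar_coefficient = ar_coefficient, noise_sd = noise_sd,
         ramp_rate = ramp_rate,
         bout_duration_median = bout_duration_median,
         bout_duration_iqr = bout_duration_iqr,
         long_share = long_share,
         long_duration_median = long_duration_median,
         long_duration_iqr = long_duration_iqr,
         stop_duration_mean = stop_duration_mean,
         n_bouts_range = n_bouts_range)
  }
  list(
    walk  = prof("walk",   4.1, c(3.6, 4.7),    0.50, 0.45, 1,
                 3,  c(2, 12),  0.069,  94, c(70, 112),  4, c(70, 86)),
    bike  = prof("bike",  14.9, c(13.1, 16.4),  0.70, 0.90, 2,
                 7,  c(3, 18),  0.170, 139, c(87, 264),  5, c(46, 60)),
    train = prof("train", 88.3, c(75.1, 104.0), 0.95, 1.00, 2,
                 6,  c(2, 15),  0.300, 471, c(205, 705), 20, c(10, 16)),
    bus   = prof("bus",   31.1, c(24.1, 33.7),  0.85, 1.20, 3,
                 20, c(8, 40),  0.156,  79, c(69, 101),  10, c(22, 30)),
    car   = prof("car",   41.7, c(35.6, 53.9),  0.80, 2.20, 3,
                 40, c(22, 58), 0.500, 219, c(109, 387),  8, c(9, 13))
  )
}

#' Default cohort configuration
#'
#' A 12-person cohort with two back-and-forth commutes each (four one-way
#' traces per person). The per-person mode assignment is one plausible
#' synthetic completion of the published per-mode subject counts (walk 2,
#' bike 9, train 5, bus 3, car 3, summing to 22 because multi-mode commuters
#' chain legs): two bike-train-walk commuters, three bike-train commuters,
#' four pure cyclists and three car-to-bus (park-and-ride) commuters.
#'
#' @param seed Integer seed driving all randomness (per-commute substreams
#'   are derived from it, so regeneration is order-independent).
#' @return List with `n_persons`, `assignment`, `commutes_per_person`,
#'   `seed`.
#' @export
default_cohort_config <- function(seed = 20140L) {
  assignment <- list(
    p01 = c("bike", "train", "walk"),
    p02 = c("bike", "train", "walk"),
    p03 = c("bike", "train"),
    p04 = c("bike", "train"),
    p05 = c("bike", "train"),
    p06 = "bike",
    p07 = "bike",
    p08 = "bike",
    p09 = "bike",
    p10 = c("car", "bus"),
    p11 = c("car", "bus"),
    p12 = c("car", "bus")
  )
  list(n_persons = length(assignment), assignment = assignment,
       commutes_per_person = 2L, seed = as.integer(seed))
}

# sdlog of a log-normal from its quartiles
sigma_from_iqr <- function(iqr) {
  (log(iqr[2]) - log(iqr[1])) / (2 * qnorm(0.75))
}

# Deterministic speed profile of one bout: ramp up at `r` km/h/s, cruise,
# ramp down, with the cruise level solved so that a long bout's mean speed
# equals the drawn target `target_mean`. Short bouts that cannot physically
# reach the target become triangular (ramp-limited).
bout_profile <- function(duration, target_mean, ramp_rate) {
  t_ <- duration
  r <- ramp_rate
  if (t_ == 1L) return(min(target_mean, r))
  disc <- 1 - 4 * target_mean / (r * t_)
  cruise <- if (disc >= 0) (r * t_ / 2) * (1 - sqrt(disc)) else r * t_ / 2
  k <- max(1L, floor(cruise / r))
  if (2L * k >= t_) {
    k1 <- ceiling(t_ / 2)
    c(pmin(r * seq_len(k1), cruise), rev(pmin(r * seq_len(t_ - k1), cruise)))
  } else {
    c(r * seq_len(k), rep(cruise, t_ - 2L * k), r * rev(seq_len(k)))
  }
}

# AR(1) fluctuation, stationary start
ar1_noise <- function(n, phi, sd_innov) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
  if (n > 1L) {
    eps <- rnorm(n - 1L, 0, sd_innov)
    for (i in 2:n) e[i] <- phi * e[i - 1L] + eps[i - 1L]
  }
  e
}

draw_bout_duration <- function(p) {
  if (runif(1) < p$long_share) {
    max(61L, as.integer(round(rlnorm(1, log(p$long_duration_median),
                                     sigma_from_iqr(p$long_duration_iqr)))))
  } else {
    min(60L, max(1L, as.integer(round(rlnorm(1, log(p$bout_duration_median),
                                             sigma_from_iqr(p$bout_duration_iqr))))))
  }
}

# speeds (with trailing stop run) for one commute leg of `mode`
simulate_leg <- function(profile) {
  n_bouts <- sample(seq(profile$n_bouts_range[1], profile$n_bouts_range[2]), 1L)
  sig_cruise <- sigma_from_iqr(profile$cruise_iqr)
  speeds <- list()
  bout_dur <- integer(n_bouts)
  for (b in seq_len(n_bouts)) {
    t_ <- draw_bout_duration(profile)
    m_ <- rlnorm(1, log(profile$cruise_median), sig_cruise)
    prof <- bout_profile(t_, m_, profile$ramp_rate)
    noisy <- pmax(prof + ar1_noise(t_, profile$ar_coefficient, profile$noise_sd),
                  0.1)
    n_stop <- 1L + stats::rpois(1, max(0, profile$stop_duration_mean - 1))
    speeds[[b]] <- c(noisy, rep(0, n_stop))
    bout_dur[b] <- t_
  }
  list(speeds = unlist(speeds, use.names = FALSE), bout_durations = bout_dur)
}

#' Simulate a labelled synthetic GPS commute cohort
#'
#' Generates 1 Hz speed traces for a cohort of commuters. Each commute leg
#' consists of a drawn number of movement bouts separated by zero-speed
#' stops; within a bout, speed ramps up at the mode's ramp rate, fluctuates
#' as an AR(1) process around a cruise level, and ramps back down. Bout
#' durations follow a short/long log-normal mixture and long-bout mean
#' speeds a log-normal law calibrated per mode (see
#' [default_mode_profiles()]). Multi-mode commuters chain legs (e.g. bike to
#' the station, train, walk to work) with stops between legs; return trips
#' reverse the chain. All points carry the generating mode label and
#' `indoor = FALSE`. Output is bit-for-bit reproducible given
#' `(config, profiles, seed)`; each (person, commute) pair runs on its own
#' counter-derived substream, so per-person regeneration is
#' order-independent.
#'
#' @param config Cohort configuration, see [default_cohort_config()].
#' @param profiles Mode profiles, see [default_mode_profiles()].
#' @param seed Optional integer overriding `config$seed`.
#' @return Track-point tibble in the canonical layout (see
#'   [read_trace_csv()]), with an attached `bout_table` attribute recording
#'   every generated bout (`trace_id`, `mode`, `duration`) for
#'   generator-vs-segmentation checks.
#' @export
simulate_cohort <- function(config = default_cohort_config(),
                            profiles = default_mode_profiles(),
                            seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  unknown <- setdiff(unique(unlist(config$assignment)), names(profiles))
  if (length(unknown) > 0L) {
    abort(paste0("Assignment uses unknown mode(s): ",
                 paste(unknown, collapse = ", ")),
          class = "modeshift_config_error")
  }
  persons <- names(config$assignment)
  traces <- list()
  bouts <- list()
  commute_counter <- 0L
  for (pi in seq_along(persons)) {
    legs_out <- config$assignment[[pi]]
    for (ci in seq_len(config$commutes_per_person)) {
      for (dir in c("out", "back")) {
        commute_counter <- commute_counter + 1L
        commute_id <- sprintf("c%d_%s", ci, dir)
        legs <- if (dir == "out") legs_out else rev(legs_out)
        sub <- substream_seed(config$seed, pi, commute_counter)
        trace <- with_local_seed(sub, function() {
          speeds <- list()
          leg_bouts <- list()
          for (li in seq_along(legs)) {
            leg <- simulate_leg(profiles[[legs[li]]])
            speeds[[li]] <- leg$speeds
            leg_bouts[[li]] <- tibble::tibble(
              mode = legs[li], duration = leg$bout_durations
            )
          }
          list(
            speed = unlist(speeds, use.names = FALSE),
            mode = rep(legs, vapply(speeds, length, integer(1))),
            bouts = dplyr::bind_rows(leg_bouts)
          )
        })
        tid <- paste(persons[pi], commute_id, sep = "/")
        traces[[commute_counter]] <- tibble::tibble(
          trace_id = tid,
          person_id = persons[pi],
          commute_id = commute_id,
          timestamp = seq_along(trace$speed) - 1L,
          speed_kmh = trace$speed,
          lat = NA_real_,
          lon = NA_real_,
          indoor = FALSE,
          mode = trace$mode
        )
        trace$bouts$trace_id <- tid
        bouts[[commute_counter]] <- trace$bouts
      }
    }
  }
  points <- dplyr::bind_rows(traces)
  attr(points, "bout_table") <-
    dplyr::bind_rows(bouts)[, c("trace_id", "mode", "duration")]
  points
}

#' Per-mode calibration summary of a (synthetic) cohort
#'
#' Summarises a segmented cohort the way published per-mode tables are laid
#' out: number of persons, number of sequences, and median/IQR of sequence
#' duration and of per-sequence mean speed, both over all sequences and over
#' sequences of at least one minute. Intended for side-by-side inspection
#' against the generator's calibration targets
#' (`default_mode_profiles()$<mode>$cruise_median` / `cruise_iqr`).
#'
#' @param seqs Sequence tibble from [segment_trace()].
#' @param min_long Duration (s) defining the long-sequence column
#'   (default 60: at least one minute).
#' @return Tibble with one row per mode x subset (`all` / `long`); modes
#'   absent from the cohort appear with `n_sequences = 0`.
#' @export
calibration_report <- function(seqs, min_long = 60) {
  seqs$seq_speed <- vapply(seqs$speeds, mean, numeric(1))
  out <- list()
  for (mode in MODE_LEVELS) {
    sub_all <- seqs[seqs$mode == mode, ]
    for (subset in c("all", "long")) {
      s <- if (subset == "all") sub_all else
        sub_all[sub_all$duration >= min_long, ]
      out[[length(out) + 1L]] <- if (nrow(s) == 0L) {
        tibble::tibble(
          mode = mode, subset = subset, n_persons = 0L, n_sequences = 0L,
          duration_median = NA_real_, duration_q25 = NA_real_,
          duration_q75 = NA_real_, speed_median = NA_real_,
          speed_q25 = NA_real_, speed_q75 = NA_real_
        )
      } else {
        tibble::tibble(
          mode = mode, subset = subset,
          n_persons = length(unique(s$person_id)),
          n_sequences = nrow(s),
          duration_median = percentile(s$duration, 0.5),
          duration_q25 = percentile(s$duration, 0.25),
          duration_q75 = percentile(s$duration, 0.75),
          speed_median = percentile(s$seq_speed, 0.5),
          speed_q25 = percentile(s$seq_speed, 0.25),
          speed_q75 = percentile(s$seq_speed, 0.75)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
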