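# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the default synthetic cohort at the package's reference seed
default_cohort <- function() {
  fixture("default_cohort", function() {
    points <- simulate_cohort(seed = 20140)
    seqs <- segment_trace(points)
    features <- sequence_features(seqs)
    splits <- enumerate_splits(features)
    list(points = points, seqs = seqs, features = features, splits = splits)
  })
}

# a small fast cohort: 6 persons, every person performs all five modes,
# few bouts per leg -> every split is valid and pipelines run in seconds
mini_cohort_config <- function(seed = 7L) {
  assignment <- setNames(
    rep(list(c("walk", "bike", "train", "bus", "car")), 6),
    sprintf("q%02d", 1:6)
  )
  list(n_persons = 6L, assignment = assignment, commutes_per_person = 1L,
       seed = as.integer(seed))
}

mini_profiles <- function() {
  profs <- default_mode_profiles()
  for (m in names(profs)) profs[[m]]$n_bouts_range <- c(2L, 4L)
  profs
}

mini_cohort <- function() {
  fixture("mini_cohort", function() {
    points <- simulate_cohort(mini_cohort_config(), mini_profiles())
    seqs <- segment_trace(points)
    features <- sequence_features(seqs)
    splits <- enumerate_splits(features, val_size = 2L)
    list(points = points, seqs = seqs, features = features, splits = splits)
  })
}
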