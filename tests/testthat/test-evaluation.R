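seq_stub <- function(person_id, mode) {
  tibble::tibble(person_id = person_id, mode = mode)
}

test_that("split enumeration is exhaustive, ordered and coverage-aware", {
  s12 <- seq_stub(sprintf("p%02d", 1:12), rep("walk", 12))
  splits <- enumerate_splits(s12, val_size = 4)
  expect_equal(nrow(splits), choose(12, 4))
  # deterministic lexicographic order by sorted validation set
  expect_equal(splits$val[[1]], sprintf("p%02d", 1:4))

  s4 <- seq_stub(paste0("p", 1:4), rep("walk", 4))
  expect_equal(nrow(enumerate_splits(s4, val_size = 2)), 6L)
  expect_error(enumerate_splits(s4, val_size = 4),
               class = "modeshift_config_error")

  # one mode carried by a single person: putting that person in the
  # validation set invalidates the development side
  s <- seq_stub(c("p1", "p2", "p3", "p4", "p1", "p2", "p3", "p4", "p1"),
                c(rep("walk", 4), rep("bike", 4), "train"))
  sp <- enumerate_splits(s, val_size = 2)
  in_val <- vapply(sp$val, function(v) "p1" %in% v, logical(1))
  expect_true(all(!sp$valid_dev[in_val]))
  expect_true(all(sp$valid_val[in_val]))
})

test_that("metric combinations enumerate subsets of size 1 to 3", {
  combos <- metric_combinations()
  expect_equal(length(combos), 63L)
  expect_equal(sum(lengths(combos) == 1), 7L)
  expect_equal(sum(lengths(combos) == 2), 21L)
  expect_equal(sum(lengths(combos) == 3), 35L)
  expect_equal(length(metric_combinations(max_size = 1)), 7L)
  expect_equal(length(metric_combinations(c("p95", "accel"), 3)), 3L)
})

test_that("motorized collapse relabels exactly train, bus and car", {
  expect_equal(collapse_motorized(c("train", "bus", "car", "walk", "bike")),
               c("motorized", "motorized", "motorized", "walk", "bike"))
})

test_that("Cohen's kappa matches closed forms and the degenerate convention", {
  perfect <- diag(c(10, 20, 30))
  expect_equal(cohens_kappa(perfect), 1)
  expect_equal(observed_agreement(perfect), 1)

  indep <- matrix(25, 2, 2)
  expect_equal(cohens_kappa(indep), 0)

  # validation set carrying one class, 97% predicted as that class:
  # observed agreement 0.97 but kappa exactly 0
  degenerate <- matrix(c(97, 3, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(observed_agreement(degenerate), 0.97)
  expect_equal(cohens_kappa(degenerate), 0)

  off <- matrix(c(0, 5, 7, 0), 2, 2)
  expect_equal(observed_agreement(off), 0)

  expect_error(cohens_kappa(matrix(0, 2, 2)),
               class = "modeshift_domain_error")
})

test_that("kappa agrees with an independent implementation and is
           permutation invariant", {
  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    ct <- matrix(rpois(k * k, 6), k, k)
    if (sum(ct) == 0) next
    expect_equal(cohens_kappa(ct), e1071::classAgreement(ct)$kappa,
                 tolerance = 1e-12)
    perm <- sample(k)
    expect_equal(cohens_kappa(ct[perm, perm]), cohens_kappa(ct))
  }
})

test_that("observation-time share is the duration-weighted long fraction", {
  expect_equal(observation_time_share(tibble::tibble(duration = c(30, 70))),
               0.7)
  expect_equal(observation_time_share(tibble::tibble(duration = c(65, 70))),
               1)
  expect_equal(
    observation_time_share(tibble::tibble(duration = c(10, 20, 60, 61))),
    61 / 151)
  expect_error(observation_time_share(tibble::tibble(duration = numeric(0))),
               class = "modeshift_domain_error")
})

test_that("evaluating a split is deterministic and perfect when separable", {
  mini <- mini_cohort()
  sp <- mini$splits[mini$splits$valid_dev & mini$splits$valid_val, ][1, ]
  r1 <- evaluate_split(sp, mini$features, c("p95", "accel", "decel"),
                       scheme = "three_class")
  r2 <- evaluate_split(sp, mini$features, c("p95", "accel", "decel"),
                       scheme = "three_class")
  expect_identical(r1, r2)
  expect_true(all(r1$kappa <= 1 & r1$kappa >= -1))
  expect_true(all(r1$agreement >= 0 & r1$agreement <= 1))

  # a trivially separable construction gives kappa exactly 1
  f <- tibble::tibble(
    person_id = rep(c("a", "b", "c"), each = 8),
    mode = rep(rep(c("walk", "train"), each = 4), 3),
    stratum = factor(">60s", levels = STRATUM_LEVELS),
    p95 = rep(rep(c(4, 90), each = 4), 3) + rnorm(24, 0, 0.1)
  )
  sp2 <- list(dev = c("a", "b"), val = "c")
  r3 <- evaluate_split(sp2, f, "p95", scheme = "five_class", strata = ">60s")
  expect_equal(r3$kappa, 1)
  expect_equal(r3$agreement, 1)
})

test_that("cross-validation summaries are median/IQR over valid splits", {
  mini <- mini_cohort()
  combo <- list(c("p95", "accel"))
  run <- run_crossval(mini$features, mini$splits, combo,
                      scheme = "three_class", strata = ">60s")
  expect_equal(unique(run$results$stratum), ">60s")
  n_valid <- sum(mini$splits$valid_dev & mini$splits$valid_val)
  expect_equal(run$summary$n_splits, n_valid)
  expect_equal(run$summary$kappa_median, percentile(run$results$kappa, 0.5))
  expect_lte(run$summary$kappa_q25, run$summary$kappa_median)
  expect_gte(run$summary$kappa_q75, run$summary$kappa_median)

  # duplicating every split leaves medians unchanged
  doubled <- summarize_crossval(rbind(run$results, run$results))
  expect_equal(doubled$kappa_median, run$summary$kappa_median)

  # single-split run: the median is that split's kappa
  one <- mini$splits[mini$splits$valid_dev & mini$splits$valid_val, ][1, ]
  r1 <- run_crossval(mini$features, one, combo, scheme = "three_class",
                     strata = ">60s")
  expect_equal(r1$summary$kappa_median, r1$results$kappa)
  expect_equal(r1$summary$kappa_q25, r1$summary$kappa_q75)
})

test_that("the sensitivity run is a superset of the main run", {
  mini <- mini_cohort()
  combo <- list("p95")
  main <- run_crossval(mini$features, mini$splits, combo,
                       scheme = "five_class", strata = ">60s")
  sens <- run_sensitivity(mini$features, mini$splits, combo,
                          scheme = "five_class", strata = ">60s")
  expect_true(all(main$results$split_id %in% sens$results$split_id))
  expect_gte(nrow(sens$results), nrow(main$results))
  # in the mini cohort every person carries every mode: the two runs agree
  expect_equal(sens$results, main$results)
})

test_that("collapsing motorized labels never lowers observed agreement", {
  set.seed(32)
  for (i in 1:30) {
    true <- sample(MODE_LEVELS, 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.6, true, sample(MODE_LEVELS, 60, TRUE))
    a5 <- observed_agreement(confusion_table(true, pred))
    a3 <- observed_agreement(
      confusion_table(collapse_motorized(true), collapse_motorized(pred)))
    expect_gte(a3, a5)
  }
})
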