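#!/usr/bin/env Rscript
# Step 3: exhaustive person-level cross-validation.
#
# (a) Headline runs: the best three-metric combination (p95 + acceleration
#     + deceleration) over all 168 fully-valid 8/4 splits, all duration
#     strata, five-class and three-class (motorized collapsed) schemes.
# (b) Metric sweep: all 63 combinations of 1-3 metrics, > 60 s stratum,
#     both schemes, over every 4th valid split (42 splits) to keep the
#     sweep under ten minutes on one core.
# (c) Sensitivity: headline combination over the 441 splits that are valid
#     on the development side only.

suppressMessages(library(modeshift))

seqs <- read_sequences_csv("results/sequences.csv")
features <- sequence_features(seqs)
splits <- enumerate_splits(features)
cat(sprintf("Splits: %d enumerated, %d dev-valid, %d valid on both sides\n",
            nrow(splits), sum(splits$valid_dev),
            sum(splits$valid_dev & splits$valid_val)))

headline <- c("p95", "accel", "decel")

cat("\n[a] Headline runs, all strata, all valid splits ...\n")
res_head <- list()
for (scheme in c("five_class", "three_class")) {
  run <- run_crossval(features, splits, list(headline), scheme = scheme)
  res_head[[scheme]] <- run
  s <- run$summary[match(c(STRATUM_LEVELS, "all"), run$summary$stratum), ]
  cat(sprintf("  %s:\n", scheme))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-7s median kappa %.3f (IQR %.3f-%.3f), agreement %.3f\n",
                s$stratum[i], s$kappa_median[i], s$kappa_q25[i],
                s$kappa_q75[i], s$agreement_median[i]))
  }
}
readr::write_csv(dplyr::bind_rows(lapply(res_head, `[[`, "results")),
                 "results/crossval_headline.csv")
readr::write_csv(dplyr::bind_rows(lapply(res_head, `[[`, "summary")),
                 "results/crossval_headline_summary.csv")

cat("\n[b] 63-combination sweep, > 60 s stratum, split subsample ...\n")
valid <- splits[splits$valid_dev & splits$valid_val, ]
sub <- valid[seq(1, nrow(valid), by = 4), ]
sweep <- list()
for (scheme in c("five_class", "three_class")) {
  run <- run_crossval(features, sub, metric_combinations(), scheme = scheme,
                      strata = ">60s")
  sweep[[scheme]] <- run$summary
  top <- run$summary[order(-run$summary$kappa_median), ][1:5, ]
  cat(sprintf("  %s, top combinations:\n", scheme))
  for (i in 1:5) {
    cat(sprintf("    %-22s median kappa %.3f\n",
                top$combination[i], top$kappa_median[i]))
  }
}
readr::write_csv(dplyr::bind_rows(sweep), "results/crossval_sweep_summary.csv")

cat("\n[c] Sensitivity run (dev-valid splits only) ...\n")
sens <- run_sensitivity(features, splits, list(headline),
                        scheme = "five_class", strata = ">60s")
lowest <- sens$results[order(sens$results$kappa), ][1:3, ]
cat(sprintf("  %d splits; median kappa %.3f; lowest outliers:\n",
            nrow(sens$results), sens$summary$kappa_median))
for (i in 1:3) {
  cat(sprintf("    split %d (val: %s): kappa %.3f, agreement %.3f\n",
              lowest$split_id[i], lowest$val_persons[i], lowest$kappa[i],
              lowest$agreement[i]))
}
readr::write_csv(sens$results, "results/crossval_sensitivity.csv")
cat("\nWrote results/crossval_*.csv\n")
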