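#!/usr/bin/env Rscript
# Step 2: ingest the cohort CSV, filter indoor points, cut traces into
# zero-speed-delimited sequences and compute the seven speed metrics.

suppressMessages(library(modeshift))

points <- read_trace_csv("results/cohort.csv")
filtered <- filter_indoor(points)
cat(sprintf("Points read: %d; indoor dropped: %d (%.2f%%)\n",
            nrow(points), attr(filtered, "n_dropped_indoor"),
            100 * attr(filtered, "n_dropped_indoor") / nrow(points)))

seqs <- segment_trace(filtered)
cat(sprintf("Sequences formed: %d (discarded %d zero-speed delimiter points)\n",
            nrow(seqs), attr(seqs, "n_zero_points")))
print(table(seqs$mode, seqs$stratum))

features <- sequence_features(seqs)
cat(sprintf("Sequences featurized: %d (dropped %d of duration < 2 s)\n",
            nrow(features), attr(features, "n_dropped_short")))

write_sequences_csv(seqs, "results/sequences.csv")
write_features_csv(features, "results/features.csv")
cat("Wrote results/sequences.csv and results/features.csv\n")
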