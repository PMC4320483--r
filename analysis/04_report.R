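#!/usr/bin/env Rscript
# Step 4: human-readable report and box-plot figures from the
# cross-validation outputs of step 3. Figures go to scratch/figures (they
# are conveniences; every number they show is in the results CSVs).

suppressMessages({
  library(modeshift)
  library(dplyr)
  library(ggplot2)
})

res <- readr::read_csv("results/crossval_headline.csv",
                       show_col_types = FALSE)
sweep <- readr::read_csv("results/crossval_sweep_summary.csv",
                         show_col_types = FALSE)

cat("Median kappa by duration stratum (p95 + accel + decel):\n")
res |>
  filter(stratum != "all") |>
  group_by(scheme, stratum) |>
  summarise(kappa = median(kappa), agreement = median(agreement),
            .groups = "drop") |>
  arrange(scheme, factor(stratum, levels = STRATUM_LEVELS)) |>
  as.data.frame() |>
  print(digits = 3)

cat("\nBest single metric (> 60 s, five classes):\n")
sweep |>
  filter(scheme == "five_class", !grepl("\\+", combination)) |>
  arrange(desc(kappa_median)) |>
  select(combination, kappa_median, kappa_q25, kappa_q75) |>
  as.data.frame() |>
  print(digits = 3)

dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)

p1 <- res |>
  filter(stratum != "all") |>
  mutate(stratum = factor(stratum, levels = STRATUM_LEVELS)) |>
  ggplot(aes(stratum, kappa)) +
  geom_boxplot(outlier.size = 0.5) +
  facet_wrap(~scheme) +
  labs(x = "sequence duration", y = "Cohen's kappa",
       title = "Cross-validated kappa by sequence duration") +
  theme_bw()
ggsave("scratch/figures/kappa_by_stratum.pdf", p1, width = 7, height = 4)

p2 <- sweep |>
  mutate(size = lengths(strsplit(combination, "+", fixed = TRUE))) |>
  ggplot(aes(reorder(combination, kappa_median), kappa_median)) +
  geom_pointrange(aes(ymin = kappa_q25, ymax = kappa_q75), size = 0.2) +
  coord_flip() +
  facet_wrap(~scheme) +
  labs(x = NULL, y = "median kappa (> 60 s sequences)",
       title = "Metric-combination sweep") +
  theme_bw(base_size = 7)
ggsave("scratch/figures/kappa_by_combination.pdf", p2, width = 7, height = 9)

cat("\nWrote scratch/figures/kappa_by_stratum.pdf and",
    "scratch/figures/kappa_by_combination.pdf\n")
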