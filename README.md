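# modeshift

Recognising modes of transport — walking, bicycling, train, bus, car —
from nothing but the speed a GPS logger records every second. The package
is aimed at physical-activity and exposure-assessment studies that carry
GPS devices but no accelerometers or travel diaries: it turns raw 1 Hz
speed traces into per-trip mode labels with a quantified, cross-validated
accuracy.

## Method

1. **Segmentation.** Indoor-flagged points are removed, and each commute's
   speed profile is cut into *sequences* wherever speed is zero (zero
   speed = no transport). Sequences are stratified by duration:
   `<=15s`, `16-30s`, `31-60s`, `>60s`.
2. **Speed metrics.** Per sequence of speeds `S_1..S_N`, seven metrics:
   mean, 95th percentile (`p95`), standard deviation, the rate-of-change
   metric `RCM = (1/(N-1)) * sum |S_n - S_(n-1)|`, its standardized form
   `RCM/sd`, and acceleration/deceleration proxies (95th and 5th
   percentiles of consecutive speed differences).
3. **Non-parametric discriminant analysis.** Class-conditional
   product-Gaussian kernel density estimates (Silverman bandwidths per
   class and dimension) combined with priors via Bayes' rule; a kNN
   discriminant ships as a sensitivity alternative.
4. **Evaluation.** Person-level cross-validation over all C(12,4) = 495
   development/validation partitions, Cohen's kappa
   `(p_o - p_e)/(1 - p_e)` and observed agreement per split, summarised as
   median and IQR per metric combination, duration stratum and class
   scheme (five classes, or walk/bike/motorized).

Because the underlying study's raw GPS data are not public, the package
includes a seeded synthetic cohort generator calibrated so that per-mode
speed and duration distributions of the generated sequences match the
published ones (e.g. minute-plus sequence speed medians of 4.1, 14.9,
88.3, 31.1 and 41.7 km/h for walk/bike/train/bus/car). All claims the
package makes are computed on that synthetic cohort.

## Worked example

```r
library(modeshift)

points  <- simulate_cohort(seed = 20140)   # 195,456 points, 12 persons
seqs    <- segment_trace(filter_indoor(points))
feats   <- sequence_features(seqs)         # 2,861 sequences with metrics
splits  <- enumerate_splits(feats)         # 495 splits, 168 valid both sides

run <- run_crossval(feats, splits, list(c("p95", "accel", "decel")),
                    scheme = "three_class", strata = ">60s")
run$summary
#>   scheme      combination     stratum kappa_median kappa_q25 kappa_q75
#> 1 three_class p95+accel+decel >60s       0.974      0.967     0.983
#>   agreement_median n_splits
#> 1 0.986            168
```

Read: with the three metrics `p95 + accel + decel`, collapsing train, bus
and car into one "motorized" class, sequences lasting longer than a minute
are recognised with a median chance-corrected agreement of 0.97 across the
168 person-splits where every mode occurs on both sides — near-perfect
agreement. The same run with all five classes gives median kappa 0.91
(bus/car confusions account for most errors), and `p95` alone gives 0.80.
Short sequences are markedly harder (five-class medians 0.56 / 0.66 /
0.67 / 0.91 across the four duration strata).

The numbered scripts under `analysis/` run the full study — cohort
generation and calibration check, segmentation and features, the headline
and 63-combination cross-validation sweeps, the sensitivity analysis and
a report with figures — writing tables under `results/`.

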