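# gnotostat

Statistics for gnotobiotic *Drosophila*–yeast assays: how long do ingested
yeasts persist in the fly gut, does oxidative stress explain which ones are
cleared, and which yeasts do flies prefer to eat?

The package is for experimentalists running (or re-analyzing) three standard
assay types and wanting the quantitative pipeline — from raw plate counts,
plate-reader exports, and abdomen-color tallies to classified results — to be
explicit, tested, and reproducible.

## What it computes

**CFU quantification.** Serial-dilution plate counts become CFU-per-fly
abundances via the countable-plate rule (most concentrated non-confluent
dilution) and

```
CFU/fly = count / d × V_homogenate / V_plated / n_flies
```

with the assay's quality-control rule: discard any experiment whose time-zero
negative control exceeds 50 CFU/fly (strictly).

**Relative persistence.** For test-yeast replicate X at time t, against the
*S. cerevisiae* reference arm,

```
R_X(t) = [TY_X(t) / mean(SC(t))] / [TY_X(0) / mean(SC(0))]
```

with replicate-paired time-zero normalization (or a 1:1 fallback when
time-zero plates are unusable), log-t or bootstrap confidence intervals at
95/99/99.9%, and the table vocabulary "Persists at 99.9%" / "Removed at 99%"
/ "No change" at the most stringent level excluding 1. Absolute decline is
tabulated as fold-clearance ratios (mean CFU/fly at interval start ÷ mean at
end) with cross-experiment averages.

**Growth kinetics.** OD time series become plateau rise, AUC, lag, and the
maximum specific growth rate (windowed slope of log OD in the growth
region), plus within-strain inhibition calls under H₂O₂:
`no_growth_under_h2o2`, `reduced_growth`, or `unaffected` by the AUC-based
inhibition index.

**Feeding preference.** Dyed two-choice counts become the preference index
`PI = (n_focal + n_purple/2) / n_fed`, tested against 0.5 at three levels,
with dye-swap reconciliation (`preferred` / `not_preferred` /
`inconsistent`) and a dye-confounded flag from the no-choice controls.

**Simulators.** Seeded generators for all three assay types (lognormal vial
loads with exponential clearance and Poisson plating; logistic OD curves
with an oxidant-effect multiplier; multinomial feeding outcomes) emit the
same CSV schemas the analyses read, with ground truth, so the whole pipeline
is testable without any external data.

## Worked example

```r
library(gnotostat)

sim <- simulate_persistence(seed = 101)                       # raw plate counts
ab  <- quantify_cfu(sim$raw, zero_substitute = default_zero_substitute())
qc_experiment(ab)$keep
#> [1] TRUE

res <- persistence_analysis(ab)
res[, c("experiment", "timepoint_h", "point_estimate", "ci95_lo", "ci95_hi", "label")]
#>   experiment timepoint_h point_estimate ci95_lo ci95_hi     label
#> 1        sim          24           1.24   0.516    2.99 No change
#> 2        sim          48           5.94   0.872   40.51 No change

clearance_table(ab)$summary
#>   interval    treatment mean_ratio
#> 1     0-24   test_yeast        6.5
#> 2    24-48   test_yeast       30.5
#> 3     0-24 s_cerevisiae        9.8
#> 4    24-48 s_cerevisiae      175.3
```

Reading the output: the simulated test yeast is cleared more slowly than the
reference (generator defaults k = 0.11 vs 0.17/h), so its relative
persistence ratio drifts above 1 — 5.9-fold by 48 h here — but with three
replicates and realistic sample noise the 95% interval still spans 1, hence
"No change". Both arms decline in absolute terms (6.5- and 9.8-fold over the
first day), which is exactly the pattern these assays show: relative
persistence and absolute clearance are different questions.
`build_report()` assembles these tables (plus growth and preference results)
into one deterministic plain-text report.

Published cross-experiment clearance averages are one call away from the
per-experiment ratios:

```r
clearance_summary(c(7.9, 11.2, 24.0, 7.6, 23.3))            # 0-24 h
#> [1] 14.8
clearance_summary(c(10.4, 3.5, 650.0, 266.1, 4028.6, 88.9)) # 24-48 h
#> [1] 841.3
```

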