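---
title: "Methods behind gnotostat: persistence, growth, and preference statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gnotostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnotostat)
```

gnotostat analyzes the three quantitative readouts of gnotobiotic
*Drosophila*–yeast experiments: colony-forming-unit (CFU) persistence in the
gut, *in vitro* growth under oxidative stress, and two-choice feeding
preference. This vignette explains the models and procedures, the tunable
parameters and their defaults, the numerical choices, what the synthetic-data
generators do and do not emulate, and the package's known limitations.

## CFU quantification from serial dilutions

A homogenate of pooled dissected guts (default 10 flies in 200 µL) is carried
through a serial dilution (default 1 to 1/1000) and 10 µL of each dilution is
plated. The most concentrated plate on which individual colonies are visible
is the countable one; plates recorded as `CONFLUENT` are lawns. The estimate
is

$$\widehat{\mathrm{CFU/fly}} = \frac{\text{count}}{d} \cdot
  \frac{V_\text{homogenate}}{V_\text{plated}} \cdot \frac{1}{n_\text{flies}},$$

with $d$ the dilution factor of the counted plate. The estimator is
homogeneous of degree 1 in the count and $-1$ in the dilution, and — because
plating is Poisson — unbiased for the sampled load, with relative error
$\approx 1/\sqrt{\text{count}}$ per plate (hence the convention of counting
plates with tens to a few hundred colonies).

Quality control follows the assay's discard rule: an experiment whose
time-zero negative control exceeds 50 CFU/fly is discarded. The inequality is
strict — a control at exactly 50 keeps the experiment. Negative-control
counts are never subtracted from treatment counts.

Two conventions for zeros coexist on purpose. Raw zeros are preserved
(`cfu_per_fly = 0`, `below_detection = TRUE`) so that absolute clearance
ratios use the data as recorded. Where downstream statistics work on the log
scale and need positivity, `default_zero_substitute()` supplies half a colony
at the most concentrated dilution (1 CFU/fly at the default geometry); the
substitution is explicit and upstream, never silent inside the statistics.
Confluence is an explicit marker in the input, not inferred from a numeric
cutoff, because recorded plate data do not preserve the information needed to
re-threshold; an optional `max_countable` can additionally mark high counts.

## Relative persistence

For test-yeast replicate $X$ at time $t$, with the reference
(*S. cerevisiae*) arm fed in parallel vials,

$$R_X(t) = \left.\frac{TY_X(t)}{\overline{SC}(t)} \middle/
  \frac{TY_X(0)}{\overline{SC}(0)}\right.$$

Test-yeast replicates pair with their own time-0 value (same vial); the
reference enters only as the average of its replicates, because the two arms'
vials are unrelated. $R > 1$ means the test yeast is retained relative to the
reference; $R < 1$, removed. At $t = 0$ the statistic is exactly 1 by
construction. When time-0 plates are unusable (all confluent), a unit (1:1)
normalization replaces the divisor — the historical fallback for one
experiment — via `normalization = "unit"`.

The interval method is a genuinely open design point (the assay literature
reports multi-level intervals without naming a construction). The default,
`log_t`, is a Student-t interval on natural-log ratios, back-transformed:
ratios are positive and replicate noise is plausibly multiplicative, so the
log scale is the natural one, and the point estimate under it is the
geometric mean. The alternative, `bootstrap_percentile`, resamples the
arithmetic mean (default $B = 10{,}000$, seeded) and takes inverse-CDF
(type 1) quantiles, so the Monte-Carlo interval converges to the exact
quantile of the discrete resampling distribution — at $n = 3$ that
distribution has only 27 equally likely resamples and can be enumerated
exactly, which is how the package's tests check it. All levels are cut from
one resample set, so nesting across levels holds by construction. Reports
always name the method used.

Classification follows the most stringent level in \{95%, 99%, 99.9%\}
whose interval excludes 1: "Persists at 99.9%", "Removed at 99%",
"No change". The preference module reuses the same rule against 0.5.

**A calibration caveat worth knowing.** The per-replicate ratios share one
denominator — the average of the reference replicates — so they are
positively correlated, and a t interval that treats them as independent is
anti-conservative. With $m$ reference replicates, the shared term carries
$1/m$ of the per-replicate noise variance for *any* symmetric per-sample
noise; at $m = 3$ the t statistic is inflated by $\sqrt{2}$, giving true
null coverage $P(|t_2| \le t_{0.975,2}/\sqrt{2}) \approx 0.91$ for the
nominal 95% interval. The package's simulation studies measure ≈ 0.89 under
its generator defaults. This is a property of the statistic's design, not of
any particular noise level (it is scale-free); it cannot be removed without
changing the interval construction itself, so the package implements the
standard construction and documents the undercoverage here. Calls at the
99%/99.9% levels are correspondingly the more trustworthy ones.

### Clearance ratios

Absolute decline is summarized per experiment and interval as the ratio of
replicate-mean CFU/fly at the interval's start to the mean at its end: 1
means unchanged, 10 means ten-fold fewer. Means (not per-replicate pairs)
are used because the summary is experiment-level. Ratios multiply across
adjacent intervals by construction. Cross-experiment summaries are
arithmetic means, printed half-up at one decimal (`round_half_up()`; base
`round()`'s half-to-even would print a mean ending in .25 one ulp low).

## Growth kinetics

OD time series (default: readings every 0.5 h for 72 h) are summarized per
curve:

* **baseline** — mean of the first 3 readings. No plate blank is assumed;
  all metrics are invariant to adding a constant to the whole curve.
* **delta_od** — plateau rise above baseline (clipped at 0).
* **auc** — trapezoidal area of the baseline-subtracted, zero-clipped curve
  (OD·h); additive over any partition of the time axis.
* **mu_max** — maximum specific growth rate: the largest least-squares slope
  of $\log(\mathrm{OD} - \text{baseline} + \varepsilon)$ over sliding
  windows of 5 points ($\varepsilon = 10^{-3}$). Only windows lying entirely
  in the growth region — baseline-subtracted OD at or above the rise
  threshold at every point — are eligible. This floor is essential, not
  cosmetic: near the baseline the log transform amplifies read noise without
  bound, and an unrestricted maximum over windows diverges (median relative
  error above 200% at read-noise SD 0.01 in the package's simulations,
  versus ≈ 7% with the floor). It is the windowed equivalent of fitting the
  exponential region only.
* **lag** — first time the baseline-subtracted OD reaches the rise
  threshold; undefined (NA) for curves that never rise.
* **growth_call** — `delta_od >= rise_threshold`. The threshold (default
  0.05 OD, configurable) operationalizes "no growth": it is 5× a typical
  plate-reader noise SD, so a flat noisy curve essentially never triggers it.

Because inocula are not standardized across strains in the assay this
package targets, lag and mu_max are not comparable *between* strains; the
report layer only contrasts treatments *within* a strain. The inhibition
call compares the replicate-averaged control and oxidant-treated curves:
`no_growth_under_h2o2` when the control grows and the treated curve never
rises; otherwise the inhibition index $1 - \mathrm{AUC}_{\text{treated}} /
\mathrm{AUC}_{\text{control}}$ (clipped to $[0,1]$) calls `unaffected` at
≤ 0.1 and `reduced_growth` above. A strain whose control does not grow has
no within-strain reference and is an error, not a call.

## Feeding preference

Abdomens are scored red, blue, purple (fed on both patches) or empty. The
preference index credits purple flies half to each option:

$$PI = \frac{n_\text{focal} + n_\text{purple}/2}
            {n_\text{red} + n_\text{blue} + n_\text{purple}},$$

so $PI = 0.5$ is no preference, empties never enter, and the index obeys
color-swap antisymmetry ($PI_\text{blue} + PI_\text{red} = 1$) identically.
Choice treatments orient the index toward the test yeast whatever its dye;
no-choice controls orient it toward blue, so a dye bias reads as $PI \ne
0.5$.

Inference needs replicate-level variation, but assay point estimates are
traditionally computed on averaged counts; the package therefore reports
both the mean of per-replicate PIs (used for the t interval, default
`t_linear`, truncated to $[0,1]$) and the pooled-count PI (index applied to
counts summed over replicates). The two differ when replicate denominators
differ. Replicates in which no fly fed carry no information about choice and
are excluded from inference with a warning. The dye-swap verdict calls a
yeast `preferred` only when both labelings prefer it, `not_preferred` when
neither does, `inconsistent` otherwise, and raises a `dye_confounded` flag
whenever a no-choice control itself classifies a color preference.

## The synthetic-data generators

The generators encode the study conditions the analyses assume and give
every test a known ground truth.

**Persistence.** Per vial, initial load per fly is lognormal
($\log_{10}$ mean 5, SD 0.3 — of the order of the $>10^5$ CFU/fly seen at
time zero in heavily fed flies). Loads decay exponentially; the defaults
$k_{ty} = 0.11$, $k_{sc} = 0.17$ per hour mirror the observed fold-declines
over the first day (≈ 15-fold for test yeasts, ≈ 60-fold for the
reference). Each measured sample adds per-(vial, timepoint) lognormal noise
(SD 0.3 $\log_{10}$): pure between-vial noise would cancel exactly in the
paired persistence ratio, which would make the generator useless for
calibration and power studies, and real pooled-homogenate samples do vary
between timepoints beyond plating error. Plating is Poisson around
$N \cdot n_\text{flies} \cdot d \cdot V_\text{plated}/V_\text{homogenate}$,
with counts above 300 per plate (a conventional countability bound) emitted
as confluent lawns. Note that at realistic time-zero loads the default
1–1/1000 series can produce samples that are confluent at every dilution —
as happens in real experiments; simulation studies in this package plate
down to $10^{-5}$ so that every sample stays quantifiable, mirroring the
protocol's "dilute further and re-plate" response.

**Growth.** Logistic curves $od(t) = b + \frac{\eta K}{1 + e^{-\eta r (t -
t_m)}} + \mathcal N(0, \sigma^2)$ with the oxidant effect $\eta \in [0,1]$
scaling both plateau and rate ($\eta = 0$: complete inhibition). Defaults
$K = 1$ OD, $r = 0.45$/h (≈ 90-minute doubling), $t_m = 12$ h, $\sigma =
0.01$ describe a yeast in rich medium in a plate reader.

**Choice.** Each fly independently feeds with probability $f$ (default
0.8); a fed fly is purple with probability $q$ (0.1) and otherwise picks
the focal patch with probability $p$. Expected PI is $(1-q)p + q/2$ —
0.68 at $p = 0.7$.

What the generators do **not** emulate: in-gut regrowth or non-exponential
clearance (crop retention, biofilms), fly mortality, evaporation or drift
in OD plates, plate-position effects, ambiguous abdomen coloration, and any
correlation between a fly's feeding and its neighbors'. Tests passing on
synthetic data therefore validate the statistical machinery under the
stated model, not the model's fidelity to any particular real dataset.

## Problem sizes and reproducibility

The package's simulation studies use 2,000 runs for null-interval
calibration, 200 for persistence-call power, 500 assays for preference
recovery, and 1,000 curves per arm for growth-call accuracy and rate
recovery — sizes at which Monte-Carlo error is small against the margins
being checked. All generators take explicit seeds and never touch the
caller's RNG stream; analysis functions that resample (the bootstrap) take
a seed argument and derive deterministic substreams per timepoint or
treatment. `scripts/acceptance.R` re-runs all of these from a single
`--seed` and writes the resulting numbers as JSON.

## Known limitations

* The log-t persistence interval undercoverages under the null (≈ 0.89–0.91
  at 3 reference replicates) because of the shared reference denominator;
  see above. Increasing reference replication, not resampling, is the
  design-level fix.
* With 3 replicates the bootstrap percentile interval is extremely coarse
  (27 atoms) and is offered for robustness checks, not as the default.
* Historical significance labels from published tables need not reproduce
  bit-exactly from raw data: the original interval construction is unstated,
  and classification near a boundary is sensitive to it.
* `mu_max` is a windowed empirical slope, deliberately model-free; it sits
  ≈ 5–8% below the generating logistic rate even without noise (the logistic
  has already left pure exponential growth wherever the signal is
  measurable). Parametric growth-model fitting is out of scope.
* Quantification requires at least one non-confluent plate; samples
  confluent at every dilution are an error by design (the wet-lab remedy is
  further dilution, not imputation).
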