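---
title: "Screening vegetation indices for in-season corn yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening vegetation indices for in-season corn yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscreen)
```

## The problem

Corn yield varies strongly between seasons and within fields, which makes
historic yield maps a poor basis for in-season input decisions. Canopy
reflectance observed from a UAV offers a within-season alternative: green
canopy absorbs strongly in the visible bands (chlorophyll and carotenoid
pigments), reflects strongly in the near infrared, and the red-edge region
in between is highly sensitive to chlorophyll content. A vegetation index
(VI) compresses the five sensor bands — blue 475, green 560, red 668, red
edge 717 and NIR 842 nm — into one number tracking canopy state. The
question this package answers is which VI, observed at which phenological
stage (V5 … R5), carries the most information about end-of-season grain
yield, and how consistently it does so across seasons.

## From pixels to plot band sets

Raw 16-bit digital numbers are calibrated to reflectance per band with the
reference-panel relation $\rho = \mathrm{DN} \cdot \rho_{panel} /
\mathrm{DN}_{panel}$, clipped to $[0,1]$. Background removal is a
supervised per-pixel classification into corn, soil and weed over the
five-band feature vector; the default learner is a linear-kernel
support-vector machine with an 80/20 holdout split reporting accuracy.
The classifier family is pluggable behind a fixed contract (`fit`,
`predict`, holdout accuracy) because published workflows rarely state
kernel or parameters. Zonal statistics then average the reflectance of
pixels whose *centers* fall inside each plot polygon (the digitized
middle harvest rows) and are classified as corn; the kept-pixel share is
reported as the canopy fraction, whose complement is the soil cover. A
plot with no kept pixels yields a missing band set rather than an error.

Scene coordinates are local metric with origin at the top-left corner and
y increasing downward; no CRS reprojection or mosaicking is attempted —
inputs are assumed stitched and registered upstream. Scenes travel as
five-page float TIFFs, polygons as GeoJSON with a `plot_id` property.

## The index library

All indices are pure arithmetic over band reflectances held in a registry.
Narrowband-defined indices are mapped to sensor bands through a fixed
table (445 → blue, 705/717 → red edge, 750/800/842 → NIR); constants use
the canonical published values (SAVI $L = 0.5$, OSAVI 0.16, WDRVI
$\alpha = 0.2$, EVI 2.5/6/7.5/1). Two registered names (CIgreen and
RIgreen) share the canonical form NIR/G − 1; they are kept as distinct
entries because both names circulate, and any monotone-equivalent pair
gives identical screening decisions. A band combination that zeroes a
denominator produces a missing value which is excluded pairwise
downstream — no imputation. Custom indices register from formula strings
over `B, G, R, RE, NIR` parsed by a deliberately minimal grammar
(`+ - * / ^ sqrt`, numbers, parentheses); any other symbol or call is
rejected, so a configuration file cannot execute code.

## The stability screen

For each flight the screen computes the Pearson correlation $r$ between
each VI and plot yield over the subplot-level observations (default 16
plots; treatment means are *not* aggregated first). A VI scores 1 on a
flight when $|r| \ge 0.7$, the conventional strong-correlation cut-off;
p-values (t transform, $n-2$ df) are reported but play no role in
selection. Per season, scores accumulate over flights; a VI is **stable**
when its cumulative score is at least 2 — strongly correlated on at least
two dates — and VIs with at least one scoring flight are ranked into
tiers by descending cumulative score (ties share a tier, alphabetical
within, so results are deterministic). Both views are emitted because
"top three tiers" and "stable at least twice" answer different questions;
the stable sets feed the cross-year analysis. With $n = 16$, $|r| = 0.7$
sits near the $p = 0.05$ boundary, which is why the screen demands
repeated rather than single-date exceedance.

For three seasons the stable sets are partitioned into the seven disjoint
Venn regions; indices common to all three seasons are the
highest-consistency predictors. The partition is exact set algebra and is
tested against brute-force enumeration. A packaged worked example
(`inst/extdata/stable_sets_synthetic.json`, a *reconstructed* three-season
outcome: the counts 12/12/28 per season, union 31, 16 shared by ≥2
seasons and 5 by all three are fixed, and region members not determined
by the recorded narrative were filled with plausible registry indices)
exercises the partition at realistic scale.

## The random-forest cross-check

Correlation screening is linear and univariate; as a cross-check, a
random-forest regressor is tuned per growth stage by randomized-search
cross-validation — 100 candidate hyperparameter sets over number of trees
(100–1000), minimum samples to split (2–10), minimum samples per leaf
(1–5) and feature subsampling (all vs √p), scored by 5-fold held-out R²,
bootstrap resampling always on — and indices are ranked by permutation
importance: the mean drop in R² over 10 seeded permutations of one
column. The search-space bounds are package defaults (the tuned-parameter
list is standard; published ranges rarely are), and importance is
computed on the training rows because the protocol fits the final forest
on all data; both choices are explicit knobs. The top-ranked index gets a
companion simple linear fit so the forest's pick and the screen's pick
can be compared on the same R²/MAPE scale. The forest is a ranker only —
forest-based yield prediction is out of scope.

## Yield models

The yield model is intentionally minimal: ordinary least squares of yield
on one index, $R^2 = 1 - SSE/SST$, MAPE $= 100 \cdot
\mathrm{mean}(|y-\hat y|/y)$ (defined because yields are strictly
positive), slope t-test with the `***`/`**`/`*`/`ns` convention at
0.001/0.01/0.05. Within a stage, candidate fits are ranked by R²
descending with ties broken by lower MAPE then alphabetically — a
deterministic stand-in for a formal MAPE-difference test, which is not
well defined at these sample sizes; both metrics are always reported so
other rules can be applied downstream. Treatment comparisons use a
one-way RCBD ANOVA (treatment + block fixed; split-plot error strata are
ignored since a single cash crop is analysed) followed by Fisher's LSD,
$t_{1-\alpha/2,\,df_e}\sqrt{2\,\mathrm{MSE}/r}$, with agglomerative
letter grouping; the all-means-equal case (MSE = 0) degenerates safely to
a single letter. Yields enter at the 15.5 % moisture standard via
$y_{15.5} = y_{wet}(100 - m)/84.5$.

## What the generator emulates — and what it does not

`sim_config()` encodes the study conditions: three seasons, four
cover-crop treatments × four blocks (16 subplots), and a seven-flight
schedule (V5 = 35, V7 = 48, V11 = 60, Vn = 67, R1 = 83, R3 = 95, R5 = 119
DAP — anchored on typical reported flight days and padded to a full
season). Per plot a latent vigor $v = \mu + \tau_{trt} + \beta_{blk} +
\varepsilon$ (defaults: $\mu = 0.6$, treatment effects +0.08/−0.12/−0.06/
+0.10, block SD 0.03, plot SD 0.04) drives both yield, $y = 2 +
\text{year effect} + 10v + \varepsilon_y$ ($\sigma_y = 0.35$ Mg/ha, year
effects +2.7/−1.7/+1.2 giving season means near 10.7/6.3/9.2 Mg/ha), and
reflectance through a two-endmember mixture $\rho_b(t) = (1-c(t))\,
\rho_{soil,b} + c(t)\,\rho_{leaf,b}(chl)$: canopy cover $c(t)$ is
logistic (midpoint 45 DAP, plateau 0.95), the chlorophyll proxy is
$v \cdot g(t)$ with $g$ flat-topped over 83–95 DAP, visible-band leaf
reflectance decays exponentially with chlorophyll, the red edge declines
mildly, and NIR rises with vigor. Plot-level band noise (SD 0.004) and
the 16-plot sample size were fixed once by an analytic signal-to-noise
calculation targeting $r(\mathrm{MTCI}_{R1}, y) \approx 0.88$, the regime
in which red-edge chlorophyll indices clear the 0.7 screen at silking in
well over 90 % of seasons while early-vegetative flights (low canopy
cover, low chlorophyll gain) do not — the qualitative pattern the screen
is designed to detect.

Pixel-level scenes lay the 16 plots on a grid (default 120 px plots,
10 px margins, ≈ 281k pixels — sized so the default 2 % weed share still
yields ≥ 5,000 labelled weed pixels), draw `round(c · n)` corn pixels per
plot carrying the plot band set plus pixel noise (SD 0.02), soil
elsewhere, and weed with an intermediate soil/leaf spectrum. Labels are
sampled from the true class map, 5,000 per class by default.

The generator deliberately omits much of what makes real imagery hard:
no radiative-transfer realism (no PROSAIL), no weather-driven growth, no
spatial autocorrelation between neighbouring plots, no atmospheric or
BRDF effects, no mosaicking seams, and every index is driven by the *same*
latent vigor, so indices are far more mutually correlated than in the
field. Passing tests therefore demonstrate that the machinery is correct
and well-calibrated — not that any particular index will dominate on real
fields.

## Numerical choices and degenerate inputs

* All randomness flows from named integer seeds; generators and the
  forest restore the caller's RNG state. Full runs hash reproducibly
  (`pipeline_hash()`, MD5 over a canonical text serialization).
* Zero denominators in VI formulas → `NA`, excluded pairwise; a
  zero-variance correlation input (e.g. constant yields under a fully
  degenerate null) warns and yields missing `r` rather than erroring.
* Correlations require ≥ 3 complete pairs; regressions require ≥ 3 pairs
  and non-constant predictors; flights with fewer complete plots than CV
  folds are skipped with a warning in the forest ranking.
* Ties are always broken deterministically (alphabetically) — in tier
  ranking, winner selection and importance ranking.
* Pixel membership is pixel-center containment, simple and unambiguous on
  plot-scale polygons.

## Problem sizes in the test suite

The suite exercises the pipeline at the study's own scale (16 plots, 7
flights, 3 seasons). Replicate-based properties use 100 screening
replicates (planted-index recovery and the R1-vs-V5 ordering), 200
null-scenario and 200 parameter-recovery replicates, and 20 seeded
forest-ranking runs; oracle comparisons use 1,000 random band sets or
datasets. These sizes give the binomial acceptance margins (≥ 90 %,
< 10 %, ≥ 95 %) comfortable standard errors while keeping a full run in
the low minutes on one core.
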