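---
title: "Cross-year corn and soybean mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-year corn and soybean mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropmapr)
```

## The problem

Timely maps of corn and soybean extent matter for production forecasting, but
reference labels for the current season (field campaigns, crop-specific
land-cover rasters) only become available after the season ends. cropmapr
implements a rapid cross-year strategy: classifiers are trained entirely on
prior years' imagery and labels, and the training year is chosen by how
similar its crop progress was to the mapping year's, measured from weekly
state-level progress reports. Classification is *fuzzy* — per coarse pixel we
regress the percent cover of each crop, not a discrete label — because at
~500 m resolution most agricultural pixels are mixtures.

The package works on tabular representations of the three inputs: per-pixel
reflectance time series (46 8-day composites of 7 bands per year, with
quality flags), a fine-resolution crop-label raster (corn / soybean / other),
and weekly cumulative crop-progress percentages per state, crop and stage.
A synthetic-data module generates all three with controllable cross-year
phenology shifts so the complete workflow is testable without downloads.

## Phenology retrieval

Crop phenology is retrieved per pixel by fitting an asymmetric double
sigmoid to the EVI time series,

$$f(t) = V_b + V_a\,[\sigma(p(t - D_i)) - \sigma(q(t - D_d))],$$

with $\sigma$ the standard logistic, $V_b$ the background EVI, $V_a$ the
amplitude, $p, q$ the rising/falling slopes (day$^{-1}$) and $D_i, D_d$ the
limb mid-dates. EVI uses the standard three-band form
$2.5(NIR - red)/(NIR + 6\,red - 7.5\,blue + 1)$; values with non-positive
denominator or outside $[-1, 1.5]$ are flagged invalid and treated as
missing. A composite enters the fit only when its quality flag is good and
the bands are within $[0, 1]$. The container carries one quality flag per
composite: whole-composite failures (clouds, inversion failures) dominate in
practice, and a band-level mask collapses conservatively to this form.

Fitting is bounded Levenberg–Marquardt least squares. Initial values come
from the data ($V_b$ at the 5th EVI percentile, $V_a$ the 5–95 percentile
range, mid-dates at the half-amplitude crossings, slopes 0.1/day with two
fallback starts); bounds are $V_b \in [-0.2, 0.6]$, $V_a \in [0, 1.2]$,
$p, q \in [0.01, 1]$, mid-dates in $[1, 366]$, and $D_d$ is parameterized as
$D_i + L$ with $L \ge 8$ days so the falling mid-date cannot cross the
rising one. Pixels with fewer than 10 valid composites (6 in early mode) or
a non-convergent fit are marked unfit and propagate as no-data; a flat
series (no seasonal cycle) degenerates gracefully to background-only.

### Derived metrics

The second derivative of a logistic limb with slope $s$ and mid-date $D$ has
extrema at $D \pm \ln(2+\sqrt{3})/s$, giving closed forms for the four
transition dates ($D_1, D_2$ around green-up, $D_3, D_4$ around senescence)
plus the season lengths $L_{id} = D_d - D_i$ and $L_{14} = D_4 - D_1$.
$D_{peak}$ is the argmax of the fitted curve over the observation window on
a 0.05-day grid (ties to the earlier day). Full mode yields 13 phenological
metrics; early mode drops the 6 "late" metrics tied to the falling limb.

**Domain of validity.** The closed forms treat each limb independently. The
limbs' mutual overlap scales as $e^{-S}$ with
$S = \min(p, q)\,(D_d - D_i)$, and because second-derivative extrema are
quartically flat they are displaced by residual overlap: we measured
deviations from a numerical second-derivative extremum search of up to
~0.3 day for $S \approx 7$, dropping below 0.025 day for $S \ge 10$. Typical
corn and soybean seasons sit at $S \approx 9\text{–}10$; the
oracle-equivalence tests therefore state their 0.05-day agreement for curves
with $S \ge 10$ and the package documents larger deviations for short, slow
seasons as a known limitation of per-limb closed forms.

### Early season

The early window ends with the 28th composite, day of year
$8 \times 28 = 224$ (mid-August, when both crops have normally reached peak
growth); later composites are treated as not yet acquired. Only the rising
limb is fitted. Because a fitted rising sigmoid is monotone, its argmax
would degenerate to the window end, so early-mode $D_{peak}$ is the day of
the maximum quality-masked *observed* EVI instead — a meaningful peak-growth
date that stays defined before senescence is observable. (In full mode
$D_{peak}$ uses the fitted curve, which is robust to single noisy
composites; the observed/fitted choice is a package decision.)

## Features

Seven spectral metrics — SWIR1 (band 6), SWIR2 (band 7), EVI, NDTI
$(b_6 - b_7)/(b_6 + b_7)$, VI64 $(b_6 - b_4)/(b_6 + b_4)$, DIF64
$b_6 - b_4$, DIF67 $b_6 - b_7$ — are anchored to phenology at two stages:
`avg`, the mean over $[D_i, D_d]$ (or $[D_i, 224]$ in early mode), and
`peak`, interpolated to $D_{peak}$. Reflectances are averaged/interpolated
first and indices computed from the resulting band values; the alternative
(index-then-interpolate) differs only at second order, and one consistent
convention keeps the sign identities (VI64 vs DIF64, NDTI vs DIF67) exact.
Full-season vectors have $13 + 7 \times 2 = 27$ named features; early-season
$7 + 7 \times 2 = 21$. Interpolation requires valid composites bracketing
the target; out-of-span targets are missing. Pixels with missing features
are dropped from training; at prediction they are imputed with training-set
feature medians so the map stays total (unfit pixels remain no-data).

## Fuzzy targets and classification

The fine label raster is aggregated in `factor × factor` blocks (default 16,
emulating ~30 m labels under a ~480 m pixel; exact footprint overlay with
map projections is out of scope and block aggregation preserves the
statistical structure). Block class counts give percent coverage summing to
exactly 100. Hard-classification training uses pure pixels only: a strict
\>75% single-class threshold, applied symmetrically to "other".

Random forests (k = 100 trees, m = 1 variable per node, seeded and
single-threaded for determinism) are trained per state and year: fuzzy mode
fits one regression forest per crop on coverage percent; hard mode one
3-class forest. Fuzzy predictions are clipped to $[0, 100]$; when corn +
soybean exceed 100 they are rescaled proportionally (the reconciliation rule
is a package choice) and "other" takes the remainder.

## Training-year selection and phenological adjustment

Weekly cumulative progress series are interpolated to the day of year of
50% completion per (state, year, crop, stage); corn and soybean stages pool
into one progress-item vector per state-year. If the first report already
exceeds 50%, the date is back-extrapolated from the first two reports but
clipped to at most 7 days before the first report — sparse early reporting
otherwise produces absurd dates. Similarity between years is the RMSD of
shared 50%-progress dates; the training year is the RMSD argmin (ties to
the most recent year, closest to current practice). The control strategy
("close year") simply takes the prior year — the following year for the
earliest mapping year.

The optional adjustment moves mapping-year phenology into the training
year's frame via $X_t = a + bX_v$ fitted on the shared 50% dates: A1 fits
$a, b$ by OLS (the regression direction matches "transform mapping into
training frame"; a non-positive slope is degenerate and errors), A2 fixes
$b = 1$ (mean shift), A0 is the identity. Date metrics map affinely, season
lengths scale by $b$, per-day rates divide by $b$; amplitudes and spectral
metrics are never adjusted. One pooled adjustment covers both crops'
stages — per-crop adjustment is fragile with few shared stages, and pooling
mirrors the pooled similarity vector.

## Validation

Predicted coverage is aggregated to counties (assigned at coarse-pixel
centers) as coverage-weighted area. Agreement with reference coverage uses
two measures per crop: county-level $R^2$, computed as the squared Pearson
correlation of county area vectors (the one-to-one estimator
$1 - SS_{res}/SS_{tot}$ is reported alongside, since the estimator choice is
open), and the percentage difference of total area.

## The synthetic generator

The generator is the package's study-condition definition, not a tuning
surface. A landscape is tiled with rectangular fields of 8–24 fine cells
(240–720 m edges, typical of the Corn Belt), classes drawn at 40% corn, 40%
soybean, 20% other with a ±15-point west–east corn/soybean gradient that
gives counties distinct crop intensities. Per-pixel class trajectories draw
double-sigmoid parameters from class populations (corn mid-June green-up,
soybean ~12 days later, "other" a weak broad cycle); a coarse pixel's EVI is
the coverage-weighted mixture of its class trajectories, so sub-pixel
composition is expressed spectrally exactly as mixed pixels express it.
Band archetypes are linear in class greenness with corn and soybean
separated mainly in SWIR1–green contrast (the VI64/DIF64 rationale), and
the NIR band is solved from the (noisy) EVI trajectory so the computed
index reproduces it. EVI noise is Gaussian ($\sigma = 0.02$); 5% of
composites are flagged bad with cloud-like contamination. Weekly progress
tables are Gaussian CDFs of stage-date populations anchored to the class
phenology ($D_1$ emergence, $D_{peak}$ peak stages, $D_4$ maturity — a
simulator convention), rounded to whole percent as published reports are.

The default experiment simulates three years with uniform phenology shifts
(0, +15, +5 days), ordered so the mapping year (+5, the most recent) has
the dissimilar +15 year as its prior year: the close-year control then
selects the worse training set while progress similarity selects the
0-shift year. Scales — a 512×512 fine grid, 32×32 coarse pixels, 64
counties — were chosen so the full experiment (about 3,000 curve fits plus
six forests) completes in about a minute on one core while leaving enough
counties for a stable $R^2$.

What the generator does **not** emulate: spatial autocorrelation of weather
within a state (the shift is uniform), double-cropping and multi-cycle
phenology, view-geometry artifacts, sub-state progress heterogeneity, and
real label noise. Passing tests therefore demonstrate the correctness and
internal consistency of the algorithms under realistic statistical
structure, not real-data accuracy.

## Numerical choices and degenerate inputs

- Day of year is 1-based; composite $n$ covers days $[8(n-1)+1, 8n]$ and is
  dated by its start day. The early cutoff is day-of-year 224 in leap years
  too (the day-of-year rule, not the calendar date, is primary).
- Argmax ties (peak dates) break toward the earlier day.
- Block aggregation with a power-of-two factor makes the sum-to-100 and
  mass-conservation identities exact in floating point.
- Equal-RMSD ties select the most recent candidate year.
- Unfit pixels propagate `NA` through features, prediction and county areas
  (no-data pixels contribute no area).
- All stochastic components (landscapes, parameter draws, noise, forests)
  are seed-derived and single-threaded; rerunning with the same seed
  reproduces results bit-for-bit.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
experiment <- simulate_experiment(cfg)
feats <- experiment_features(experiment, season = "full")

run <- run_cross_year(experiment, mapping_year = 2014,
                      strategy = "similar_progress", features = feats)
run$selection          # RMSD table and chosen training year
tidy(run$report)       # county-level R^2 and area bias per crop
autoplot(run$report)   # county scatter, mapped vs reference
```

## Known limitations

Single growth cycle per year only; per-limb closed forms degrade for short,
slow seasons (see above); the 50%-progress similarity summarizes a whole
season in one number and can hide stage-specific divergence; simple linear/
shift adjustments cannot correct nonlinear phenology differences; counties
straddling zone borders are assigned by pixel center.
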