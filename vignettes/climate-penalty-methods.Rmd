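---
title: "Estimating the climate penalty on surface air quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the climate penalty on surface air quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climpen)
library(dplyr)
```

## The statistic

Warmer summers worsen surface air quality even at constant emissions: ozone
production accelerates, biogenic precursor emissions rise, wildfire and
secondary-aerosol formation intensify. **climpen** quantifies this *climate
penalty* as the slope

$$ m(\Delta y) = \frac{\mathrm{Cov}(\Delta T,\ \Delta y)}{\mathrm{Var}(\Delta T)} $$

where $\Delta T$ and $\Delta y$ are *detrended interannual anomalies* of
summer-mean (JJA) temperature and of a pollutant aggregate — summer-mean
PM2.5 (µg/m³), June-to-May annual-mean PM2.5, or summer-mean 8-h-max ozone
(ppb). Detrending is the residual of an ordinary least-squares fit of the
seasonal series on calendar year; it removes the long-term mean and the
linear decline driven by emission controls in one step, so the slope
isolates the temperature response. By the Frisch–Waugh–Lovell theorem this
slope equals the temperature coefficient of the joint regression of the raw
seasonal value on temperature and year — the package exploits that identity
for a fully vectorised per-cell fit, and the test suite asserts it to
1e-9 relative on random instances.

Inference per cell/site uses the t distribution with $n-2$ degrees of
freedom on the detrended pairs, two-sided, with significance screened at
$\alpha = 0.05$ and no multiple-testing correction (each cell is reported,
not selected). Regional estimates pool all cell-year anomaly pairs in a
region into one unweighted OLS fit; their uncertainty comes from a
*year-block bootstrap* (below).

## What the synthetic generator emulates — and what it does not

All estimators are exercised against `make_truth()` /
`simulate_fields()`, which invert the analysis model: daily pollutant =
per-cell baseline + per-cell linear trend + per-cell sensitivity ×
interannual summer temperature anomaly + iid Gaussian daily noise.
Key conventions:

* **Pollution-year indexing.** The daily response is indexed by the
  June-to-May "pollution year" (the most recent 1 June), so the JJA mean
  *and* the June-to-May annual mean both respond with exactly $\beta$ per
  °C. This makes zero-noise self-consistency exact (relative error
  < 1e-12 in the tests); a calendar-year indexing would attenuate the
  annual response by the June-to-December day fraction.
* **Seasonal cycle.** Temperature has a sinusoidal cycle indexed by a
  leap-invariant day of year (29 Feb shares day 59), so seasonal means of
  the cycle are identical across years and cancel exactly under
  detrending. `tmax`/`tmin` are constructed symmetrically (±5 °C) around
  the intended mean, so `(tmax + tmin) / 2` reproduces it exactly.
* **Spatial correlation.** Interannual anomaly fields and smooth
  sensitivity fields are white noise convolved with a separable Gaussian
  kernel (width `spatial_corr_len` cells, default 3) and renormalised to
  exact unit marginal variance. The true spatial covariance of real
  anomaly fields is not known to this package; the kernel is a configurable
  stand-in, and the year-block bootstrap is the piece of the machinery
  that does not depend on getting it right.
* **Study conditions.** Defaults are fixed at: 17 years (2000–2016),
  summer-anomaly sd 0.6 °C, daily noise sd 0.5·√92 so the JJA seasonal-mean
  noise sd is 0.5 units, PM trend −0.25 µg/m³/yr on a 10 µg/m³ baseline,
  ozone trend −0.4 ppb/yr on 45 ppb, species mass shares sulfate 0.30,
  nitrate 0.10, ammonium 0.12, OC 0.25, EC 0.05 (sum 0.82; the remainder
  is the unspeciated `other` column, so species plus remainder sum to the
  total exactly). These are desk-scale but realistic magnitudes for
  continental-US summer records.
* **Not emulated:** the error structure of the upstream
  machine-learning concentration fields (noise here is iid by design),
  wildfire events (a decadal shift in $\beta$ stands in for a worsening
  fire regime), humidity/precipitation covariates, and day-to-day weather
  in temperature (only the summer-mean anomaly enters the pollutant
  model). Passing tests therefore demonstrate correctness of the
  estimation machinery under the stated model, not robustness to every
  feature of real data.

Grids are regular lat/lon at desk scale (default 0.25°, up to 20×30
cells); the estimator is resolution-agnostic, so nothing depends on the
1 km scale of the archival datasets this layout mirrors.

## Aggregation and completeness

Daily records become monthly means only for months with at least 7
non-missing daily values ("more than 6"); summer (JJA) means need at least
2 of the 3 monthly means; June-to-May annual means, labelled by the June
year, need at least 9 of 12 ("more than eight"); and a site enters the
sensitivity diagnosis only with at least 11 complete years in 2000–2016.
All four thresholds are configurable, boundaries are implemented as strict
readings of the inequalities (6 days rejected, 7 accepted, etc.), and
months are weighted equally in seasonal means (monthly-then-seasonal
construction, not day-count weighting). One documentation note: the
source conventions for the summer month set are contradictory (JJA in the
analysis definitions, July–September in one processing sentence); the
package defaults to JJA and exposes the month set as the `months`
argument. Incomplete windows are dropped, never imputed; slope fits
listwise-delete years missing either member of the pair.

A simulated 2000–2016 record supports June-to-May annual means for label
years 2000–2015 only (June–December 2016 is 7 < 9 months); real archives
have the same edge unless data extend into the following May.

Station utilities mirror the observational design: pollutant monitors are
paired with all temperature stations within 30 km great-circle distance
(haversine, sphere radius 6371 km), averaged datewise *before* monthly
aggregation (the alternative order is a documented unknown; datewise-first
is the default); grid cells validate against monitors within 5 km.

## Regional bootstrap, decadal change, moving windows

The bootstrap resamples **years** with replacement, keeping every cell
within a resampled year together. Years are the natural exchangeable unit
here: the anomaly fields are strongly correlated across cells within a
year, so resampling cells would understate uncertainty, while year blocks
preserve the cross-cell dependence without modelling it. `B = 1000`
replicates and a percentile CI are defaults; the replicate slope depends
on the data only through per-year sums, so replicates are computed from
per-year sufficient statistics and a multinomial count draw — numerically
identical to refitting, and fast enough for coverage studies at
`B = 1000` × hundreds of Monte-Carlo repeats.

Two calibration facts, both recomputed by the test suite and
`scripts/acceptance.R`: fed pairs drawn directly from the anomaly
regression model (its input contract), the bootstrap's 95% percentile CI
covers the true pooled slope ~93% of the time at 17 year-blocks, with a
bootstrap/OLS standard-error ratio near 0.95 — slight undercoverage of
the usual small-block kind. Fed the full chain including per-cell
detrending, coverage is about a point lower (detrending deflates residual
variance and induces negative serial correlation); the full chain is
validated separately by the cellwise parameter-recovery study, whose mean
bias is < 0.05 units/°C with per-cell `±1.96·SE` coverage ~92%.

Decadal change compares pooled sensitivities between 2000–2009 and
2010–2016. Period-specific fits **re-detrend within the period** — the
trend removed should be the trend of the data actually fit; full-record
detrending is available by passing a full-record `anomaly_pairs()` result.
Percent change is $100(m_{\text{late}}-m_{\text{early}})/m_{\text{early}}$,
defined only for a positive early slope (a no-penalty-to-penalty
transition is flagged, not forced into a percentage). Its CI pairs
bootstrap draw *i* of the early period with draw *i* of the late period
and is significant when it excludes zero. Moving windows slide a 5-year
(configurable) window across the record — thirteen windows on 17 years —
re-detrending within each.

## Exposure distributions

Sensitivity maps destined for exposure analysis are first clamped at zero
(`prepare_exposure_map()`): most negative slopes are insignificant and are
treated as *no* climate penalty. Population counts are assigned to map
cells by nearest center (exactly conservative); weighted quantiles use the
left-continuous inverse CDF (smallest value whose cumulative normalised
weight reaches *p*) — deterministic and directly checkable against a
brute-force scan. The high-penalty threshold is the population-weighted
75th percentile of the full-record map, so by construction roughly 25% of
the population sits at or above it; rounded operational thresholds
(1 µg/m³/°C summer PM2.5, 0.5 µg/m³/°C annual PM2.5, 3 ppb/°C summer
ozone) can be supplied as overrides. Whether the archival convention
derived its threshold from the clamped or signed map is unstated; the
clamped map is used here, consistently with the no-penalty treatment, and
the signed map can be passed explicitly. Exceedance uses ≥; area weights
are cos-latitude cell areas, `(cell_deg · 111.32 km)² · cos(lat)` —
adequate for fractions at desk scale. Urban cells are those at or above
400 people/km² (≥, so exactly 400 is urban).

## Species attribution

Per-species (sulfate, nitrate, ammonium, organic aerosol, elemental
carbon) sensitivities reuse the identical aggregation filters, detrending
and pooling as total PM2.5; organic carbon mass is converted to organic
aerosol by the factor 2.1 before estimation. Contribution fractions
normalise the positive slopes; negative-slope species (a small negative
nitrate sensitivity is the canonical case) contribute zero and are
flagged excluded. On synthetic data where species exactly partition the
total and share the temperature draws at zero noise, species slopes sum
to the total slope to 1e-9 relative — with real, mismatched site networks
this identity does *not* hold, because different species are observed at
different places and times; the fractions remain interpretable as a
normalised decomposition, not an exact budget.

## Numerical choices and degenerate inputs

* Detrending requires ≥ 3 distinct years; pooled fits ≥ 3 pairs with
  positive temperature-anomaly variance; a degenerate (zero-variance)
  temperature series yields an NA-slope flagged estimate rather than an
  error at the map level, and an error at the pooled level.
* Bootstrap replicates with zero resampled temperature variance are
  skipped; more than 10% skipped aborts the fit.
* Cell/year sums are accumulated in double precision via centered
  cross-products; `lm()` is used in the tests as the independent
  cross-check, never in the hot path.
* All randomness flows through explicit integer seeds; sub-streams are
  derived by fixed offsets, so every generator and the bootstrap are
  bit-reproducible for a given seed.

## Problem sizes

The test-suite simulation studies use 20×30 grids × 17 years for cellwise
recovery (200 seeds), 8×8 × 17 for decadal-shift recovery (100 seeds), and
500 Monte-Carlo repeats at B = 1000 for bootstrap calibration;
`scripts/acceptance.R` scales the seed counts to 100/50/200. These sizes
give Monte-Carlo standard errors comfortably inside the asserted bands
while keeping a full run on one CPU in minutes.

## Worked example

```{r example, eval = FALSE}
cfg <- validate_config(list(scenario = "flat", seed = 3, n_lat = 6,
                            n_lon = 6, years = 2000:2010, n_sites = 6,
                            B = 200, min_years = 5,
                            period_early = 2000:2005,
                            period_late = 2006:2010))
run <- run_pipeline(cfg)
run$results$regional      # pooled slopes per region, bootstrap CIs
run$results$species       # per-species slopes and contribution fractions
autoplot(run$results$maps$pm_jja)
```

## Known limitations

The generator's iid noise understates the serial and spatial error
correlation of real ML-derived concentration fields; the four-region mask
is a geometric tercile/median split, not an administrative boundary; the
area weighting is planar-approximate; and no humidity, precipitation or
circulation covariates are modelled — the slope is a total derivative
with respect to summer-mean temperature, which is exactly what it is
meant to be, but it should not be read as a mechanistic partial effect.
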