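---
title: "Assessing whether coastal wetlands keep pace with water-level rise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing whether coastal wetlands keep pace with water-level rise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshpace)
```

## The question

Coastal wetlands survive rising water levels only if their surface gains
elevation at least as fast as the water rises. Monitoring networks pair a
water-level gauge (measuring relative water level, RWL, against a geodetic
datum) with a rod surface-elevation table (RSET) benchmark measuring wetland
surface-elevation change (SEC). `marshpace` turns such paired records into a
probabilistic statement per site: how likely is the water to be outpacing
the wetland, how often is the wetland surface actually flooded, and — given
a family of sea-level-rise projections — when do projected rates cross the
thresholds implied by the observed surface-elevation deficits?

## Data model and preprocessing

All elevations are stored in meters on a common datum; rates are reported
in mm/yr, converted only at reporting boundaries. Hourly gauge records are
averaged to daily means, daily means to calendar-month means, with each
aggregated period carrying a completeness fraction (observed records over
expected; month lengths and leap years are honored).

Two completeness filters gate the analysis:

* a month is retained only when its daily completeness strictly exceeds
  70% (a month at exactly 0.70 is dropped);
* a site is retained when at least 70% of the window's months survive
  (a site at exactly 0.70 is kept).

The asymmetric boundary conventions ("exceeding 70%" strict for months,
"below 70% excluded" inclusive for sites) are deliberate and tested.

Seasonality is removed by the climatology method: detrend a copy of the
monthly series by OLS, average the detrended values per calendar month,
mean-center the 12 offsets, and subtract them from the *raw* series, so the
trend is retained. A numerical subtlety: regressions use time in decimal
years, and the calendar-month grid is slightly non-uniform on that axis, so
a sampled annual cycle aliases a small spurious component (of order 0.5
mm/yr for a 10 cm cycle over a decade) into the raw OLS slope. Climatology
removal eliminates precisely this component — which is why the
deseasonalized slope is the better trend estimate, the operation changes
the slope slightly by design, and a single pass is idempotent only to the
sub-millimeter level. All regressions center time on the series midpoint
for conditioning; slopes are invariant to that choice.

## Trend inference with red-noise surrogates

Trends are ordinary least squares slopes. Significance accounts for serial
correlation by modeling monthly residuals as a first-order autoregressive
(AR(1)) process and generating 10,000 trendless red-noise surrogate series
with the fitted persistence; the two-sided p-value is the add-one fraction
`(k + 1) / (n + 1)` of surrogates whose slope magnitude reaches the
observed one, so p is never exactly zero. Surrogate paths start from the
stationary distribution (no burn-in bias) and are masked to the observed
months, preserving the sampling pattern. Biannual SEC series are too short
to support an AR(1) fit, so white-noise surrogates at the residual standard
deviation are used there.

The lag-1 sample autocorrelation of residuals from an intercept-plus-trend
fit is biased low by roughly `(2 + 4*phi)/n` (the classical small-sample
bias, doubled by the two absorbed regression parameters), and the residual
variance underestimates the marginal noise variance. Left uncorrected,
this makes the surrogate test reject trendless persistent noise at about
7.5% instead of 5% at `phi = 0.5`, `n = 156`. The inference path therefore
uses `fit_ar1(correct_bias = TRUE)`, which applies both corrections;
measured type-I error is then about 6%. The uncorrected estimator remains
the default return of `fit_ar1()` for descriptive use.

Deseasonalization interacts with the variance accounting in two further
ways, both handled explicitly. First, estimating and removing 12 monthly
climatology offsets deflates the residual variance by roughly one part in
the number of observed years; `fit_ar1(extra_dof = 11)` restores it (the
offsets behave like white-noise degrees of freedom because calendar months
sit a full AR(1) decorrelation length apart). Second, every bootstrap
replication re-estimates and removes the climatology from its own surrogate
path (the `month` argument of `trend_ensemble()` and `trend_p_value()`), so
the ensemble replicates the complete estimation chain rather than only the
final regression.

How the per-site trend *ensembles* are built is an interpretive choice: we
use a parametric residual bootstrap — fitted line plus one AR(1) surrogate
residual path, refit by OLS, 10,000 times — because it reuses the stated
noise model and directly yields a sampling distribution of the slope. Its
spread matches the closed-form OLS slope standard error in the white-noise
case, and on synthetic networks the true trend falls in the central 95%
interval for about 94% of sites (the residual shortfall is the
unpropagated sampling spread of the fitted AR(1) coefficient, a standard
plug-in bootstrap limitation).

## Differential vertical-land-motion correction

The gauge is anchored a few meters deep (typically 4–5 m) while the RSET
rod reaches ~20 m. When either instrument "floats" in compaction-prone
Holocene strata — i.e. does not reach the Holocene–Pleistocene interface —
the two subside differently and the RWL trend must be corrected before
comparison with SEC. The correction rate is modeled as a normal
distribution pinned at 1 and 4 mm/yr for its 5th and 95th percentiles
(mean 2.5, sd ≈ 0.912 mm/yr); negative draws are retained (the distribution
is not truncated), corrections are constant in time, and 10,000 seeded
draws are subtracted index-wise from the RWL trend ensemble. Correction
draws are sampled independently of the trend draws, so the corrected
ensemble variance is the sum of the two variances. Sites whose instruments
both reach the basement pass through unchanged.

Monthly water-surface *elevations* (with seasonality retained) are
corrected around the geodetic survey epoch:
`corrected(t) = raw(t) − rate × (t − survey_year)`, with the pivot at the
start of the survey year (default 2014.0). The Methods leave open whether
elevations are corrected per draw or with a single central rate; we use the
central rate for the elevation path (`vlm_mode = "central"` equivalent)
while the trend comparison propagates the full distribution; a `known`
mode substitutes externally supplied per-site rates, which is how
ground-truth validation runs are performed.

## Response classification

For each month the corrected water elevation is the mean tide; low and high
tide are the mean ∓/± half the annual tidal amplitude. Two probabilities
drive the classification:

* `p_rate` — the fraction of index-paired Monte Carlo draws where the
  corrected water-level trend strictly exceeds the SEC trend (identical
  degenerate ensembles therefore give 0, not 0.5; the tie behavior is
  documented rather than split);
* `p_flood` — the fraction of SEC measurement occasions where the wetland
  surface sits below the chosen tide level of the same month.

The seven categories partition the unit square: `p_rate ≥ 0.66` gives the
three give-up flavors (complete if `p_flood ≥ 0.90`, projected if
`≤ 0.10`, in progress otherwise); `0.33 ≤ p_rate < 0.66` gives keep-up
(dynamic if `p_flood > 0.10`, else stable); `p_rate < 0.33` gives catch-up
(`p_flood > 0.50`) or speed-up. The published verbal intervals overlap at
their endpoints; the conventions above make them a true partition, verified
by a grid sweep. "Safe" sites are everything outside the give-up branch.
Flooding is evaluated across measurement occasions only (not across Monte
Carlo draws); the alternative reading of the Methods — propagating
elevation uncertainty into flooding — is intentionally not the default, as
occasions-only matches the quoted comparison month by month.

The surface-elevation deficit of a site is the draw-wise difference
(corrected water-level trend minus SEC trend); cross-site percentiles
(25th, 50th by default) summarize the network. Subtracting a deficit
percentile from the observed geocentric sea-level (GSL) rise rate yields
the rise rate at which that fraction of sites would be in deficit; with
the published values (observed 10.5 mm/yr, deficits 8.1 and 3.7 mm/yr)
this reproduces 2.4 and 6.8 mm/yr. Projection curves — decadal rate curves
with a 1σ band, spatially averaged over coastal locations — are scanned
for the first grid year at or above each threshold, at the grid's native
decadal resolution (no interpolation, matching "by 2070"-style statements;
interpolation is deliberately not offered as a default). The low-confidence
projection tier is an alternative input file, not a different algorithm.

## The synthetic network generator

Because the real monitoring data require a download, the package ships a
generator whose outputs have the statistical structure the analysis
assumes, with recorded ground truth:

* water level, daily: intercept + trend + annual sinusoid (site-specific
  phase) + shared ocean signal (monthly AR(1), unit loading by default) +
  site monthly AR(1) noise + daily white noise, with uniform daily
  missingness and occasional whole-month dropouts;
* wetland surface, biannual: intercept + trend + white noise;
* a monthly reference GSL series carrying the same shared signal, so
  site-versus-reference correlations are meaningful;
* per-site metadata (gauge depth 4–5 m, rod depth 20 m, variable
  basement depth, tidal amplitude, organic fraction) drawn from stated
  ranges, with the differential VLM rate injected as an extra linear term
  in the water series only (gauges float; rods anchored), drawn from the
  same 1–4 mm/yr band the correction model uses.

Defaults emulate a 253-site network observed 2009–2021. Parameters the
source material does not state are fixed, once, at values a coastal
monitoring scientist would call realistic for a microtidal deltaic coast:
seasonal amplitude 100 mm; site AR(1) phi in (0.2, 0.6) with 25 mm monthly
innovations; shared signal phi 0.5 with 30 mm innovations (giving
site-reference correlations around 0.7); 5 mm daily noise; 15 mm SEC
noise; platform starting elevations uniform in (−0.20, 0.30) m about the
initial water surface, spanning regularly flooded to supratidal sites; 8%
daily missingness plus 3% month dropout, so the completeness filters see
both passing and failing cases. These are free parameters of the test
harness, not claims about any particular coast.

Ground truth records each site's generating trends, AR(1) coefficient,
differential VLM rate, and the category the classification rules assign to
the noise-free system (computed through the same aggregation and correction
code paths, so the noise-free limit agrees exactly). The generator is
seeded end to end: per-site streams derive from a fixed integer hash of
(master seed, site index, stage label), so regeneration is bit-identical
and independent of processing order.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: spatially correlated subsidence, storm
surges and prolonged river floods, vegetation dynamics, instrument
drift/re-leveling artifacts, and non-sinusoidal seasonality. Results on
synthetic networks validate the machinery, not the published regional
percentages, which require the real network.

## Problem sizes and determinism

The test suite and the acceptance script use sizes chosen to make Monte
Carlo tolerances meaningful while keeping runs desk-scale: 1,000
repetitions × 1,000 surrogates for type-I-error calibration (156-month
series), 200 sites × 1,000-member ensembles for coverage, 10,000 draws
wherever a single ensemble's quantiles are checked, and the full default
network (253 sites, 10,000 draws) for the end-to-end run. Every stochastic
step takes an explicit integer seed; the pipeline derives per-site,
per-stage sub-seeds from the master seed so that identical configuration
and seed give byte-identical outputs.

## Known limitations

* The AR(1) model is fitted per site; longer-memory or seasonal residual
  structure folds into an effective phi.
* The surrogate test's type-I error is ~6% rather than exactly 5%: the
  plug-in bias correction removes most, not all, of the anti-conservatism
  (estimation spread of phi remains unpropagated).
* Correlation significance between two series surrogates both sides
  independently; if the truth is one-sided coupling this is conservative.
* Flooding probabilities are step functions of at most ~26 biannual
  occasions, so they move in coarse increments at short records.
* Crossing years are reported at decadal resolution by design.
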