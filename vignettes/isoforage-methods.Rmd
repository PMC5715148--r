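---
title: "Continuous-surface isotope assignment: models, parameters and design"
author: "isoforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-surface isotope assignment: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoforage)
```

## The problem

Nesting marine turtles can be sampled in large numbers on the beach, but
their foraging grounds — where they spend the years between breeding
migrations — are scattered over thousands of kilometres of shelf. Tissue
stable-isotope ratios (δ¹³C, δ¹⁵N) integrate diet and location during the
foraging period, and across the Northwest Atlantic the two elements vary
geographically in distinct directions. `isoforage` implements the
continuous-surface approach to this inference: rather than classifying each
female into one of a handful of discrete regions, it produces a raster of
posterior support over the whole study grid for every individual, and builds
population-level summaries from those rasters.

## The assignment model

For each element, calibration animals with known foraging locations provide
point observations of tissue isotope values. An *isoscape* — a prediction
surface with a standard-error surface — is fitted to these points by
ordinary kriging with a variogram estimated by weighted least squares
(Cressie weights $n_k / \gamma_k^2$ on the binned empirical semivariogram).
Distances are great-circle (haversine), since the study region spans some
twenty degrees of latitude. Kriging here is an open surrogate for the
proprietary empirical Bayesian kriging used in some GIS workflows; the
downstream machinery needs only a mean raster and an error raster per
element, so results that depend on the interpolator agree approximately, not
bit-for-bit, with analyses run under other interpolators.

The per-cell error model is a bivariate normal. Its mean is the pair of
kriged predictions at the cell. Its covariance combines two sources assumed
independent:

* **Tissue spread.** Within each of the six broad calibration foraging
  areas, the sample variances of δ¹³C and δ¹⁵N and their correlation are
  computed; variances and correlations are then averaged across areas with
  equal weight (a sample-size-weighted average is available via
  `weighted = TRUE`). The pooled covariance is re-implied as
  $\bar r \sqrt{\bar v_C \bar v_N}$ because correlations, not raw
  covariances, are averaged. Note this pooled "among-individual" variance
  also absorbs genuine isotopic spread *within* each broad area, which makes
  the assignment model conservative (wider) by construction.
* **Interpolation error.** The squared kriging standard errors of the cell
  are added to the diagonal. The kriging model provides no cross-element
  error, so the off-diagonal carries the tissue covariance alone.

For individual $i$ with (epidermis-equivalent) values $x_i$ and cell $c$
with mean $\mu_c$ and covariance $\Sigma_c$, the cell density is
$\phi_2(x_i; \mu_c, \Sigma_c)$. Each individual's raster is rescaled by its
maximum, giving values in $[0, 1]$ with at least one cell exactly 1 (ties
are expected where the isoscapes are locally flat). The rescaled surface is
a likelihood surface under a flat prior over cells; no latitude-dependent
cell-area weighting is applied.

### Numerical choices

* Densities are computed in log space and the per-raster maximum is
  subtracted before exponentiating, so cells far from the individual's
  isotope values underflow to 0 gracefully instead of zeroing the raster.
* Cell covariance matrices are positive definite whenever $|\bar r| < 1$; a
  diagonal ridge of $10^{-8}$ is a safety net only and warns if triggered.
* Duplicate calibration coordinates are averaged before kriging (the system
  is singular otherwise) with a message; a near-singular system falls back
  to a ridged solve with a warning. Kriging weights are asserted to sum to 1
  at every prediction point (ordinary-kriging unbiasedness).
* Known-origin coordinates that resolve to a masked-out pixel snap to the
  nearest ocean cell within one cell — coastal capture positions often fall
  on land pixels at half-degree resolution.
* Variogram fitting uses box-constrained quasi-Newton iterations from three
  starting points; the default family is exponential (spherical and Gaussian
  are available).

## Population summaries

The *foraging importance index* is the cell-wise sum of normalized surfaces
over a cohort (optionally one season). Because surfaces are max-normalized,
the sum is a probability-weighted index of the evidence that a cell was
used, **not** a count of individuals — several cells can carry a full unit
from the same animal. *Reproductive importance indices* multiply each
surface by the individual's clutch size (eggs) or by its emergents
(hatched eggs minus dead and live hatchlings found at excavation) before
summing. The *emergence-rate surface* is the ratio of the emergent-weighted
to the egg-weighted index: algebraically the egg-weighted mean per-nest
emergence rate of the individuals placing mass on the cell, hence bounded by
the contributing nests' rates and in $[0, 1]$ wherever eggs are present.
This ratio construction is the package's design choice; it is the only
simple algebra of the two weighted indices that lands in $[0, 1]$.

Hotspot contribution tables sum an index over the cells whose centers fall
inside each of the seven hotspot polygons (cell-center membership is
deterministic; no area-fraction weighting at half-degree resolution), then
normalize either by the year's sample size (`by_n`, the annual-map
convention) or to column sums of one (`by_hotspot_total`, relative
contributions). Hotspot-by-year emergence rates are ratios of zonal sums of
the two weighted indices.

## Rank tests

Differences among hotspots across seasons are tested with the Friedman rank
sum test (years as blocks, hotspots as treatments) in the tie-corrected
form, which is algebraically identical to the classical
$12 \sum_j R_j^2 / (bk(k+1)) - 3b(k+1)$ statistic when no ties occur; the
implementation is cross-checked in the tests against `stats::friedman.test`
and an exhaustive within-block permutation oracle on small tables. Because
both normalizations divide each year column by a constant, `by_n` and
`by_hotspot_total` tables give identical rank statistics. All-pairs
post-hoc comparisons use Conover's Friedman-type statistic
$t = (R_i - R_j) / \sqrt{2(bA_1 - \sum_j R_j^2) / ((b-1)(k-1))}$ on
$(b-1)(k-1)$ degrees of freedom, with Benjamini–Hochberg adjustment over the
$k(k-1)/2$ pairs and a deterministic insert-and-absorb compact letter
display (letters assigned in the fixed hotspot display order).

## What the synthetic generator emulates — and what it does not

`defaultScenario()` encodes a nine-season study (2007–2015) on a 0.5°
Northwest Atlantic grid (23–45°N, 60–98°W reduced to 60–85°W), with per-year
cohort sizes 63, 71, 58, 70, 73, 103, 98, 73, 140 (total 749 females), nest
fate recorded for 56, 47, 33, 52, 50, 55, 83, 73, 64 of them per season
(total 513), and 227 known-origin calibration animals across six broad
areas. Seven hotspot source polygons feed year-varying mixture weights with
a stable east-Florida share of 0.31, synchronized southern pulses in 2007
and 2014, and northern pulses in 2009 and 2012. Clutch sizes are
$\mathcal N(113, 20^2)$ truncated at 1; hatched eggs are binomial in a
hotspot-specific emergence probability spanning 0.55 (north) to 0.80
(south); small dead/live-at-excavation counts (1% each) complete the nest
records. Tissue types are mixed (epidermis, unhatched egg, red blood cells
in proportions 543:156:50) and non-epidermis values are emitted through the
inverse of the conversion model, so the standard conversion step recovers
the epidermis currency exactly. All randomness flows from one seed; the
latent true hotspot of each female is written to a sidecar that no analysis
stage reads.

Design choices that required judgement, and why:

* **Gradient geometry.** The two elements' truth fields are planar gradients
  plus a smooth Gaussian-process anomaly (amplitude 0.2‰ at a 4° length
  scale, simulated on a coarse sub-grid and bilinearly refined). δ¹³C runs
  at −0.60‰ per degree latitude (plus 0.05 per degree longitude); δ¹⁵N runs
  at −0.50‰ per degree longitude (plus 0.10 per degree latitude), i.e.
  enriched nearshore, consistent with reported coastal δ¹⁵N enrichment.
  Near-orthogonal gradients make the bivariate isotope-to-location map
  invertible everywhere; with purely latitudinal gradients, same-latitude
  hotspot pairs (Bahamas vs Florida Keys) would be indistinguishable for any
  sample size.
* **Calibration-area geometry.** Areas are compact (2.5–3.5° boxes) and
  placed so that the hotspot regions are covered, the way tracked animals
  cover the real foraging range. This matters twice over: kriging errors
  are smallest where the calibration points are, and the pooled tissue
  variance absorbs within-area spatial spread — an area spanning $L$ degrees
  contributes $\approx L/\sqrt{12}$ degrees to the positional uncertainty of
  every assignment, regardless of how steep the gradients are.
* **Tissue noise.** Among-individual variance of 0.08‰² per element
  (sd ≈ 0.28‰, correlation 0.2) keeps the surfaces informative at the
  half-degree grid while remaining within the range reported for marine
  turtle tissues.

What passing tests on this generator do **not** show about real data: real
isoscapes are not planar, their anomalies are not stationary, real foraging
areas are not boxes with uniform occupancy, tissue noise is not homoscedastic
across areas, and the real calibration sample is not uniformly scattered.
The generator validates the machinery — estimator algebra, normalization,
aggregation, test statistics, end-to-end plumbing — not the ecological
fidelity of any particular isoscape.

### Statistical limits of composition recovery

Two properties of the study design bound what "parameter recovery" can mean
at these sample sizes. First, a season's realized hotspot composition is a
multinomial draw: with 63–140 females per year, the realized share of a
0.31-weight hotspot has a sampling standard deviation of 0.04–0.06, so
annual recovered shares cannot be expected to sit within ±0.05 of the
*generating weights* even if every female were assigned to her true hotspot.
Second, the importance index sums max-normalized surfaces, so each female
spreads mass into neighbouring hotspots; the implied mixing shrinks
composition estimates toward uniformity and leaves a systematic deficit of
about 0.05–0.07 on the largest (east Florida) share under the default
conditions. The acceptance suite therefore carries one deliberately strict
composition check that documents this limit, alongside the checks the
conditions do meet: per-hotspot emergence rates within ±0.05, high
calibration-validation medians that increase as tissue noise decreases, and
exact sampling totals.

## Problem sizes

The shipped tests run the full default study — 2,200 grid cells, 227
calibration animals, 749 assignment surfaces, nine seasons — in well under a
minute on one CPU; module tests use 1° grids and three-season cohorts. The
same default study backs `scripts/acceptance.R`.

## A small worked example

```{r example, eval = FALSE}
scn <- defaultScenario(seed = 1L)
res <- runPipeline(scn, quiet = TRUE)

res$validation$median          # surface value at known-origin cells
res$tests$female$friedman      # hotspot differences across nine seasons
res$tests$female$posthoc@letters
round(res$shareTable@values, 3)

rec <- recoveryDiagnostics(res, scn)
rec$maxRateError               # emergence-rate recovery
```

## Known limitations

* Ordinary kriging with a single WLS variogram per element; no local model
  averaging, no covariates, no universal kriging. The strong latitudinal
  trend is absorbed into a long-range variogram, which inflates prediction
  errors far from data (by design, this widens rather than sharpens
  assignments).
* A flat spatial prior over cells; no correction for cell-area change with
  latitude before summing.
* The conversion coefficients shipped with the package are synthetic
  placeholders (`inst/extdata/conversion_synthetic.yaml`); real analyses
  must supply the published regressions for their tissues.
* Hotspot polygons are inputs, not outputs: the package aggregates over
  supplied regions and does not detect hotspots.
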