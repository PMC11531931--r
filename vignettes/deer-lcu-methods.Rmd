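---
title: "Deer land cover utility scoring and its validation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deer land cover utility scoring and its validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerlcu)
```

## The scoring model

White-tailed deer in the agricultural Midwest favor edges where cover meets
forage: patches of forest and wetland provide shelter, food and fawning
sites, while the surrounding row crops, pasture and grassland supply
abundant seasonal food. The land cover utility (LCU) score quantifies this
configuration from a categorical 30 m land-cover raster in four steps.

1. **Remapping.** NLCD-style classes are grouped into *shelter/food*
   (deciduous/evergreen/mixed forest, woody and herbaceous wetlands) and
   *food* (shrub/scrub, grassland, pasture/hay, cultivated crops). All other
   classes — water, developed land, barren — are non-habitat. The code sets
   are configurable (`class_mapping()`) because class vocabularies differ
   between land-cover products; unlisted codes silently map to non-habitat.

2. **Patch qualification.** Patches are maximal 8-connected components
   (side *or* corner contact) of same-group cells. Patches under 0.02 km²
   are discarded — with 900 m² cells the smallest qualifying patch is 23
   cells, and the ≥ is closed, so 23 cells (20,700 m²) qualify and 22
   (19,800 m²) do not. Same-group cells within 500 m of a qualifying patch
   are retained anyway ("proximal inclusion"): deer are unimpeded by mild
   fragmentation, and 500 m is the radius of a circle with the average
   Illinois female home-range area (0.99 km²). Proximity is Euclidean
   between cell centers and the 500 m bound is closed. Cross-group
   proximity does not rescue cells.

3. **Distance-band scoring.** Every qualifying cell is scored by distance
   to the nearest *qualifying patch* of the opposite group (proximally
   included stragglers are not targets). Shelter/food cells score 1 up to
   500 m from food, 0.8 to 700 m, and 0.6 beyond — including when no food
   exists at all, so forest cores always count. Food cells score 1 under
   200 m from cover, then 0.8/0.6/0.4/0.2 in 75 m bands, and 0 past 500 m:
   the cores of expansive fields are effectively out of deer reach. The
   printed band edges leave 1 m gaps (e.g. "<500" then "501–700"); we close
   them as [0,500], (500,700], (700,∞) and [0,200), [200,275], (275,350],
   (350,425], (425,500], (500,∞) so every distance maps to exactly one
   score. On a 30 m lattice no attainable distance falls in the 500–501 m
   gap, so the choice is unobservable in practice. Scores are relative
   ranks, not absolute habitat values.

4. **Aggregation.** The LCU of a spatial unit is the sum of its member
   cells' scores divided by the unit's *total* declared area (km²),
   including water and developed land. Cells belong to the unit containing
   their center (standard zonal convention; ties on shared edges go to the
   unit reached by nudging the center a millionth of a cell down-left —
   deterministic and order-independent). Years stay separate rows; no
   averaging across land-cover years.

Distances come from an exact separable Euclidean distance transform
(lower-envelope algorithm), clipped to the raster extent — no padding, so
patches at the edge of small test grids are genuinely clipped.

## The validation model

The LCU is validated against *minimum deer density* — recorded mortalities
per km², a lower bound on true density — with a two-level Bayesian Gamma
regression with log link:

$$y_{it} \sim \mathrm{Gamma}(\nu,\ \nu/\mu_{it}), \qquad
\log \mu_{it} = \alpha + \beta_1\,\mathrm{LCU}_{it} + \beta_2\,\mathrm{NoHunt}_{it}
+ \beta_3\,\mathrm{PubHunt}_{it} + \beta_4\,y_{i,t-1} + u_i + v_t,$$

with independent (unnested) unit and year intercepts
$u_i \sim N(0, \sigma_u^2)$, $v_t \sim N(0, \sigma_v^2)$. A Gamma
likelihood respects the positive, right-skewed response. Covariates are
standardized by $(x - \bar x)/(2\,\mathrm{sd})$ on *training* moments
(80/20 split, seeded), making coefficients comparable across binary-like
and continuous inputs. On the log link a coefficient $\beta$ translates to
a proportional change $e^{|\beta|} - 1$ in density from a low to a high
covariate value.

### Sampler

No Stan-style engine is assumed: the package implements the posterior
sampler directly.

* Intercept, slopes, group SDs and shape: univariate slice sampling (no
  tuning parameters; the intercept and shape conditionals collapse to
  O(1) after one pass over the data).
* Unit and year intercepts: vectorized Metropolis-within-Gibbs — the
  conditionals are independent across groups, so all J proposals are
  accepted/rejected in parallel; proposal scales adapt toward 0.44
  acceptance during warmup only.
* Two "ridge" slice moves per iteration shift mass between the intercept
  and each random-effect block mean ($\alpha \to \alpha + d$, effects
  $-\,d$). The likelihood is invariant along this ridge, which plain Gibbs
  traverses extremely slowly; the move eliminates the classic centered-
  parameterization pathology and brings the intercept's effective sample
  size from under 1% to near 100%.

Priors are weakly informative and configurable: Student-t(3, 0, 2.5) on
the intercept, N(0, 5) on slopes, half-t(3, 0, 2.5) on group SDs,
Gamma(0.01, 0.01) on the shape. Defaults mirror the published sampler
settings (4 chains, 10,000 iterations, thinning 4); desk-scale runs use
3,000 iterations with 1,500 warmup, which pass the same gates.

### Diagnostics and summaries

Convergence is gated on split-Rhat ≤ 1.01 and ESS ratio ≥ 0.1 for all
monitored parameters (`check_convergence()`); both statistics are computed
in-package (split chains, Geyer-truncated autocorrelation sums). Bayesian
R² uses the model-based residual variance $\mu^2/\nu$ per draw — more
stable than draw-wise residuals — and reports the posterior median.
Held-out predictions use the posterior mean of $\mu$; random effects of
units or years unseen in training are set to zero (the population level),
a choice the source methodology leaves open.

## What the synthetic generators emulate — and what they do not

`generate_landscape()` thresholds Gaussian-smoothed white noise at the
class-proportion quantiles: seeded, proportion-exact, and with patch size
growing with the clustering parameter (default 8-cell diameter, roughly
the field/woodlot grain of an agricultural mosaic at 30 m). The default
mix is Illinois-like: 54% row crops, 17% forest, 11% developed/water.
The generator does *not* reproduce road networks, riparian corridors or
the strong north-south gradients of real Illinois land cover, so green
raster tests establish correctness of the scoring machinery, not realism
of any particular LCU magnitude.

`generate_units()` tiles the raster into PLSS-like squares: 54×54-cell
sections (2.62 km², matching the ~2.6 km² TRS median; a section is one
square mile), 6×6-section townships, and 2×2-township county blocks —
county blocks are scaled down relative to real counties (~1567 km²) so
desk-size rasters contain several. Nesting is exact; edge tiles may be
partial.

`simulate_density_panel()` is the generative mirror of the regression:
covariates are standard normal on the post-2-SD-scaling scale, so true
coefficients are directly comparable to the published magnitudes; the
default truth is the published TRS-level posterior means (intercept
−0.084; coefficients 0.724 prior-year density, 0.344 LCU, 0.21 no-hunt,
0.075 public-hunt) with σ_unit = σ_year = 0.3 and shape 5 — a
moderate-noise regime stated once and not revisited. Recovery of these
parameters demonstrates that the fitting machinery is unbiased in the
published regime; it cannot certify the published real-data R² or
prediction medians, which depend on the non-public surveillance data.

## Numerical choices and edge cases

* Distance transform: exact squared-distance lower envelope; `Inf` where
  no target exists (scored 0.6 for shelter/food, 0 for food).
* Patch labels are deterministic (first-encounter order, column-major);
  tests compare labelings as partitions, never label values.
* Score sums are multiples of 0.2; parent/child conservation is exact in
  exact arithmetic and verified on the ×5 integer scale (floating-point
  addition order otherwise produces ~1e-13 noise).
* LCU tables are written with `%.17g`, so CSV round-trips reproduce
  doubles bit-for-bit.
* Empty habitat groups, all-nodata grids, empty target masks, zero radius
  and zero min-area all degenerate gracefully (K = 0 patches, all-`Inf`
  distances, mask-only qualification, all patches qualifying).
* The response must be strictly positive: a zero density row is an error,
  matching the Gamma support — callers should offset true zeros upstream
  if their mortality source produces them.

## Known limitations

* Raster I/O is the plain-text ESRI ASCII dialect only; no GeoTIFF reader
  is bundled (the surrounding toolchain lacks an offline geospatial
  stack), and no reprojection — inputs must already be in a projected
  meter CRS.
* The sampler is single-machine, pure R; it is comfortable at ~5,000 rows
  and ~500 random intercepts (tens of seconds) but is not built for
  hundred-thousand-row panels.
* Prediction intervals are not reported, only point predictions and their
  absolute-error summaries.
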