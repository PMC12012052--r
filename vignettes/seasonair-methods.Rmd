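---
title: "Methods: spatio-seasonal air pollution analysis and health impact assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-seasonal air pollution analysis and health impact assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonair)
```

`seasonair` implements an analysis chain for gridded seasonal
concentration fields of NO₂ and PM₂.₅: aggregation to administrative
sectors, summer-to-winter ratio stratification, distance-to-road
profiling, a WHO-guideline preventable-fraction health impact
assessment with Monte Carlo uncertainty, socio-economic disparity
curves, and a car-ownership changepoint analysis. This vignette
describes the models, the tunable parameters, the synthetic-data
generator used for validation, and the numerical choices made where the
design was genuinely open.

## Exposure aggregation

Concentration rasters (µg/m³; one layer per pollutant × season, with
winter, spring, summer, autumn as the seasonal resolution) are
aggregated to sectors by the unweighted arithmetic mean of member-cell
values (`zonal_mean()`), the standard "zonal statistics" operation.
Cells contribute equally: membership is exclusive and cells have uniform
size, so no area weighting is needed. NODATA cells are excluded from
every mean, and a sector consisting only of NODATA cells is an error
rather than a silent `NaN`.

The **annual sector mean is the unweighted mean of the four seasonal
means**. Seasonal rasters are themselves aggregates of monthly model
output, and seasonal contribution shares are reported on a scale where
the four seasons sum to 100%, which presumes equal season weighting;
month-length weighting would change annual means by well under 1% and is
not implemented.

**Seasonal shares** (`seasonal_shares()`) divide each season's
population-weighted mean sector concentration by the sum over seasons.
Population weighting reflects *residential* exposure; an unweighted
variant (`weighted = FALSE`) is available for sensitivity because
area-based shares are an equally defensible reading. Zero-population
sectors are allowed on input (flagged with a warning) and drop out of
weighted summaries through their zero weight.

## Summer/winter ratios

The seasonal-dilution metric is the ratio of the mean summer
concentration to the mean winter concentration. For a stratum *k* (a
land-cover class, a degree-of-urbanisation class, or any cell
partition), `stratified_ratio()` computes **the ratio of stratum means,
not the mean of cellwise ratios** — a single fraction of aggregate
concentrations. The cellwise alternative (`cellwise = TRUE`) is kept
behind a flag for sensitivity; the two differ when winter concentrations
vary strongly within a stratum.

Uncertainty is a nonparametric **bootstrap over cells** (default B =
1000, percentile 2.5/97.5, seeded). Published stratum tables in this
literature sometimes print brackets whose lower bound is exactly 0.00,
which suggests min–max ranges across sectors rather than confidence
intervals; both are computable from the output, but the bootstrap CI is
the default and the method is recorded in the result. The "winter ±"
dispersion column is the standard deviation across stratum cells.

Ratios are invariant under multiplying both seasonal fields by a
positive constant, and a stratum covering the whole grid reproduces the
overall ratio exactly; both properties are enforced by tests.

## Distance to roads

`distance_transform()` computes the Euclidean distance from each cell
center to the nearest road cell center on a uniform cost surface and
divides by the maximum distance on the grid, so distances live in
[0, 1]. The normalisation makes profile positions like "distance =
0.05" interpretable as a fraction of the maximum road distance without
committing to map units; no cost-path routing over the road network is
attempted. `distance_profile()` smooths concentration against
normalised distance with the package LOESS and also returns an ordinary
linear fit for reference. `percent_decline()` reports
`100·(c₀ − c_d)/c₀` between any two points on a profile.

## Local regression

All smoothing uses one self-contained LOESS implementation
(`loess_fit()`), so smoother behaviour is part of the tested surface
rather than delegated to a plotting layer:

- **Neighbourhood**: the `⌈span·n⌉` nearest observations per evaluation
  point; distance ties are broken by lower index, which makes the fit
  deterministic under permutation of tied points.
- **Weights**: tricube `w = (1 − (d/d_max)³)³`, where `d_max` is the
  distance of the furthest included neighbour (whose weight is therefore
  0). If fewer than three positive weights remain, the included window
  receives a tiny floor weight so the local polynomial stays estimable;
  a singular local design (all in-window x equal) falls back to a
  `1e-10` ridge.
- **Fit**: weighted least squares for a polynomial of degree 1
  (default) or 2, centered at the evaluation point; the fitted value is
  the local intercept. With degree 1, exactly linear data are reproduced
  to machine precision at any span.
- **Standard errors**: `se(x₀) = σ·‖l(x₀)‖` from the local hat vector
  `l` and a single global residual variance `σ² = RSS/(n − tr(L))`
  estimated from the fit at the data points. The 95% band is
  `fit ± 1.96·se`. No robustness iterations are performed.
- **No extrapolation**: evaluation outside the observed x range is an
  error.
- Defaults `span = 0.75`, `degree = 1` are the conventional smoother
  settings; they are exposed in the run configuration and echoed in all
  outputs because no single span is right for every profile.

Tests check probe evaluations against explicit weighted normal
equations, affine equivariance, near-interpolation as the span shrinks
on noise-free data, and agreement with `stats::loess` (which serves
only as an independent cross-check, never as the implementation).

## Preventable fraction

Health impact uses exposure–response functions for long-term all-cause
mortality, configured per pollutant as a relative risk per 10 µg/m³
with a 95% CI plus a WHO guideline value. Defaults (`default_erf()`)
are the ELAPSE meta-analysis estimates — NO₂ 1.045 [1.026, 1.065],
PM₂.₅ 1.118 [1.060, 1.179] — with the 2021 WHO long-term guidelines of
10 and 5 µg/m³.

For each sector, the annual mean concentration is converted to the
exposure increment `CON`, the RR is rescaled log-linearly, and the
preventable fraction follows:

\[
RR_{exp} = \exp\left(\frac{\ln RR_{10}}{10}\, CON\right), \qquad
PF = 1 - \frac{1}{RR_{exp}}
\]

**Counterfactual convention.** The default is
`CON = max(annual mean − guideline, 0)`: the excess over the guideline,
which is the only reading under which a sector already at the guideline
has PF = 0 — as a guideline-attainment counterfactual requires. Because
the source methodology can also be read as using the raw concentration
in `CON`, `counterfactual = "zero"` switches to that literal reading;
the mode is recorded in every output. Relative risks below 1 (possible
only with synthetic configurations) are clipped to PF = 0 with a
warning rather than reported as negative fractions.

**Uncertainty.** `RR10` is drawn from a triangular distribution with
mode at the point estimate and support on the 95% CI — the conventional
three-point description of a point-estimate-plus-interval — via the
inverse CDF applied to seeded uniforms, which keeps the Monte Carlo
reproducible and monotone in the underlying uniforms. Default 10,000
iterations. The sector and national CIs are 2.5/97.5 percentiles over
iterations; the point estimate uses the mode, so it is seed-free.
A degenerate triangular (all three parameters equal) reproduces the
deterministic PF with a zero-width interval.

**National aggregation** is the population-weighted mean of sector PFs,
applied per iteration. Because PF is nonlinear in concentration, this
differs slightly from the PF of the population-weighted mean exposure;
the weighted-mean-of-PFs form follows the aggregation as stated
("population-weighted sum over sectors"), and the alternative can be
computed directly from the sector table if needed.

## Disparity curves and the accessibility turning point

`deprivation_curves()` smooths sector metrics (annual means and
summer/winter ratios per pollutant) against the deprivation decile,
separately per degree-of-urbanisation class. Deciles are treated as
numeric 1..10 — the curves are read as gradients along the deprivation
axis, matching how such figures are drawn — and evaluation is restricted
to deciles present in the class. Strata with fewer than 5 sectors or
fewer than 3 distinct deciles are skipped with a warning.

`turning_point()` operationalises the visual notion of "the score where
car ownership starts to drop" as an explicit, testable rule:

1. fit the package LOESS of cars per household against the score
   (default `span = 0.15`, degree 1 — small enough to resolve a kink);
2. differentiate the fitted curve by finite differences on a 200-point
   grid;
3. report the smallest score at which the derivative falls below
   `−0.5 × max|derivative|` **and stays below it for the rest of the
   range**.

Two refinements make the rule robust. First, the rule is applied on the
interior 90% of the evaluation grid (`trim = 0.05` per end): local
derivative estimates inside boundary half-windows are noisy — score
pile-ups at the top of the scale produced spurious derivative spikes
that inflated the reference maximum — while a genuine regime change at
the extreme boundary is not meaningfully detectable anyway. Second,
`detected = FALSE` is returned when the sustained crossing starts at the
first interior grid point (a curve that declines from the outset has no
plateau-then-drop regime change, e.g. globally linear data) or when the
curve is numerically constant. Pre- and post-slopes come from ordinary
straight-line fits on either side of the detected point. The span,
threshold fraction and trim are all arguments.

With the defaults, the estimator's bias on noise-free piecewise-linear
data is below 0.1 score units for changepoints between 3 and 9, and
planted changepoints of 5.0 and 8.0 are recovered within ±0.3 across 20
generator seeds (300 sectors); both behaviours are locked in by tests.

## The synthetic region generator

Real inputs for this kind of study (high-resolution dispersion-model
rasters, census sector tables) are distributed on request rather than
deposited, so validation rests on a generator whose every parameter is
planted and recorded (`region_spec()`, `simulate_region()`).

**Concentration fields.** Each pollutant × season surface is
`background + increment · exp(−d/decay_scale) + noise`, with `d` the
cell's Euclidean distance to the nearest road cell. Seasonal levels are
anchored on winter: the planted summer/winter ratio is exact at `d = 0`
(`planted_ratio_road`) and in the `d → ∞` limit
(`planted_ratio_background`), before noise. Spring and autumn sit at the
midpoint between winter and summer, reflecting their intermediate
character; exact intermediate levels are not critical to any downstream
contract. Defaults mirror the Belgian seasonal contrasts this design
emulates: NO₂ road ratio 0.78 and background 0.46, PM₂.₅ 0.56 and 0.45,
winter backgrounds of 18 (NO₂) and 14 (PM₂.₅) µg/m³. Noise is i.i.d.
Gaussian per cell (default sd 0.5 µg/m³), clipped at a 0.1 µg/m³ floor
so ratios stay defined.

**Sectors.** The grid is partitioned into `n_sectors` contiguous
regions by rectangular tiling perturbed with random merges of adjacent
tiles — irregular real-world sector shapes would add no testable
structure. Populations are rounded Gaussians around 500 (the
characteristic size of the smallest census unit this emulates). Land
cover uses a reduced 6-class palette (urban fabric, road/rail,
industry, arable, pasture, forest) assigned by jittered distance band —
enough classes to exercise stratification without a full land-cover
nomenclature. Degree of urbanisation (1/2/3) follows tertiles of mean
road distance. Deprivation deciles are assigned by reverse rank of a
score that, in urban sectors, tracks standardised winter NO₂ with
strength `deprivation_no2_slope` plus unit noise — so decile 1 (most
deprived) concentrates where NO₂ is highest, the gradient the disparity
module must recover — while non-urban sectors get noise-only scores.
Ranking over all sectors guarantees decile coverage. The Mobiscore-like
accessibility score decreases with road distance on a 0–10 scale, and
cars per household follow the exact piecewise-linear rule
`plateau + post_slope · max(score − changepoint, 0)` plus noise, with
**no clipping**: clipping at zero would destroy the planted slope in
the tail for low changepoints, and recovering that slope is precisely
what the changepoint validation requires.

**Seeding.** One master seed; field noise draws come from a stream
seeded with it (pollutants in spec order, seasons winter → autumn), and
sector attributes from a stream at `seed + 1` (partition merges, land
cover jitter, population, deprivation noise, accessibility noise, car
noise, in that order). Regeneration with the same spec is bit-identical.

**What passing tests do and do not show.** The generator plants the
*statistical structure* the pipeline claims to recover: exponential
road-distance decay, multiplicative seasonality, a deprivation–NO₂
gradient, a piecewise-linear ownership curve, Gaussian noise. Real
fields have correlated (non-i.i.d.) errors, multiple interacting source
types, non-exponential dispersion kernels and irregular sector
geometry. Parameter recovery here therefore demonstrates correctness of
the estimators under their stated model, not robustness to every
real-data pathology.

## File formats and conventions

- Grid convention everywhere: row 1 is the north edge; cell (r, c) has
  its center at `(x_origin + (c − 0.5)·cell, y_origin − (r − 0.5)·cell)`.
- ESRI ASCII grids are the primary raster format (text, exact
  round-trip at the written precision, default 6 significant digits).
  `.tif` files are single-band float TIFFs written via the `tiff`
  package with min–max scaling and a JSON sidecar carrying
  georeferencing, the value scale and NODATA cells, since the
  underlying writer stores samples on a [0, 1] scale and carries no geo
  tags.
- Sector↔cell linkage is by explicit membership table, keeping geometry
  computations out of the analysis path; `rasterise_sectors()` offers
  cell-center point-in-polygon (even-odd rule) rasterisation of GeoJSON
  polygons for data delivered as geometry. When a membership table has
  no per-cell land cover, cells inherit their sector's class.
- Inputs are assumed on one common grid; no CRS reprojection.

## Problem sizes used in validation

The test-suite defaults are sized for completeness of coverage rather
than scale: structural checks use grids around 20×30 with ~10–40
sectors; oracle-equivalence checks use 50×50 grids; Monte Carlo
calibration uses 10⁵ triangular draws and PF runs of 10,000 iterations;
changepoint recovery uses 50×60 grids with 300 sectors across 20 seeds;
and the end-to-end acceptance run uses the default 60×80 grid with 120
sectors. The same estimators run unchanged on larger inputs — all
operations are vectorised with at most O(cells × roads) distance work
and O(n²) LOESS hat computations per fit.

## Known limitations

- Ozone, month-level temporal structure, multi-year trends and
  mortality-count/DALY computation are out of scope; the analysis stops
  at the preventable fraction.
- The distance transform is straight-line distance on a uniform cost
  surface, not network routing; road classes are not distinguished.
- LOESS bandwidths are fixed per run (no cross-validation), and the
  changepoint detector assumes a single plateau-then-decline regime;
  multiple regime changes would report only the first sustained one.
- The turning-point estimate needs a few hundred paired observations
  for stability at the ±0.3 level; with many fewer sectors the detected
  point can drift or the regime change may fall inside the trimmed
  boundary region.
- Synthetic validation covers the estimators' stated models, as
  discussed above, not every property of real dispersion fields.
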