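# seasonair

Spatio-seasonal air pollution analysis and health impact assessment for
NO₂ and PM₂.₅, in R.

Ambient concentrations of nitrogen dioxide and fine particulate matter
are strongly seasonal — winter levels in temperate Western Europe are
roughly double the summer levels — but the *strength* of that seasonality
varies in space. Near busy roads, persistent traffic emissions keep the
summer-to-winter concentration ratio close to 1.0, while rural background
locations dilute to half their winter level. This spatial structure
matters for public health policy: locations with weak seasonal dilution
stay above WHO guideline values all year, and they are not occupied at
random — deprived urban populations are concentrated in exactly those
high-NO₂ areas. `seasonair` packages the full analysis chain for this
kind of study:

- **Exposure aggregation** — zonal means of gridded seasonal
  concentration fields over administrative sectors (`zonal_mean()`),
  population-weighted summaries, seasonal contribution shares
  (`seasonal_shares()`).
- **Seasonal ratio analysis** — summer/winter ratios per sector
  (`sector_ratio()`) and stratified by land cover or degree of
  urbanisation with bootstrap CIs (`stratified_ratio()`), where the
  stratum ratio for class *k* is

  ```
  ratio(k) = mean summer concentration over cells of class k
             ─────────────────────────────────────────────────
             mean winter concentration over the same cells
  ```

- **Distance-to-road profiles** — normalised Euclidean distance
  transform (`distance_transform()`), LOESS concentration profiles with
  confidence bands (`distance_profile()`), and percent-decline summaries
  (`percent_decline()`).
- **Health impact assessment** — preventable fraction of all-cause
  mortality under the counterfactual of meeting the 2021 WHO long-term
  guidelines (10 µg/m³ NO₂, 5 µg/m³ PM₂.₅). A literature relative risk
  per 10 µg/m³ (`RR10`, defaults from the ELAPSE meta-analysis) is
  rescaled to each sector's excess exposure `CON` and converted to a
  preventable fraction:

  ```
  RR_exposure = exp( ln(RR10) / 10 × CON )        PF = 1 − 1 / RR_exposure
  ```

  Uncertainty is propagated by Monte Carlo (default 10,000 iterations)
  drawing `RR10` from a triangular distribution with mode at the point
  estimate and support on its 95% CI (`pf_with_uncertainty()`). National
  figures are population-weighted means of sector PFs.
- **Socio-economic disparities** — LOESS curves of exposure and seasonal
  ratio against deprivation decile, stratified by degree of urbanisation
  (`deprivation_curves()`), and a changepoint detector for the
  accessibility score at which car ownership starts to fall
  (`turning_point()`).
- **Synthetic region generator** — `region_spec()` / `simulate_region()`
  build a fully synthetic study region (seasonal rasters + sector table)
  with planted, recorded parameters, so every stage of the pipeline can
  be validated against known ground truth.

All user-facing functions take data frames first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`. A
self-contained LOESS implementation (`loess_fit()`, tricube weights,
local linear/quadratic fits, pointwise standard errors) backs every
smoother so its behaviour is testable.

## Worked example

A complete run on a synthetic region (60×80 cells, 120 sectors, one
vertical road; planted summer/winter ratios 0.78 on the road and 0.46 in
the NO₂ background):

```r
library(seasonair)

cfg <- run_config(synthetic = list(seed = 1),
                  bootstrap = list(B = 1000, seed = 2),
                  mc = list(n_iter = 10000, seed = 3))
res <- run_pipeline(cfg, quiet = TRUE)
res
#> <pipeline_result>
#>   NO2 national PF 2.27% [1.55-3.01]
#>   PM25 national PF 6.04% [3.87-8.20]
#>   winter exposure shares: NO2 32.9%, PM25 34.2%
#>   car-ownership turning point at score 8.27
```

2.27% of mortality attributable to NO₂ in the synthetic region would be
prevented by meeting the WHO guideline (Monte Carlo 95% CI 1.55–3.01%);
winter contributes about a third of annual residential exposure; and car
ownership starts dropping at an accessibility score of ≈8.3 (the
generator planted the changepoint at 8.0).

Summer/winter ratios by degree of urbanisation show the expected
gradient — urban sectors dilute least in summer:

```r
res$ratio_degurba[res$ratio_degurba$pollutant == "NO2", ]
#>   stratum winter_mean winter_sd ratio ci_low ci_high area_share
#> 1 1              23.9     5.88  0.604  0.599   0.610      0.354
#> 2 2              18.1     0.532 0.460  0.459   0.462      0.309
#> 3 3              18.0     0.505 0.460  0.459   0.461      0.338
```

`run_pipeline(cfg, out_dir = "out")` additionally writes every table as
CSV plus a JSON manifest (seeds, settings, package version) from which
the run can be reproduced exactly. A thin command-line wrapper with
`simulate` / `aggregate` / `ratios` / `hia` / `disparities` / `run`
subcommands is installed at `inst/cli/seasonair`.

## Documentation

The methods vignette (`vignettes/seasonair-methods.Rmd`) describes the
models and their assumptions, the synthetic generator's design, every
numerical choice (neighbourhood rules, boundary handling, tie-breaks)
and the package's known limitations.
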