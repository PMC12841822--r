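# climexrf

Joint species-distribution modelling of a host plant (*Cupressus*) and
its bark-beetle pest (*Phloeosinus cupressi*), for ecologists and
biosecurity analysts who need climate-driven suitability maps and
habitat-area accounts under current and future climates.

Two models are combined:

* **A mechanistic ecoclimatic-index engine** (CLIMEX-style) scores host
  suitability per grid cell and year on 0–100. Weekly growth is the
  product of trapezoidal temperature and soil-moisture responses,
  `GI_w = TI(t_w) · MI(m_w)` with thresholds `DV0 ≤ DV1 ≤ DV2 ≤ DV3`
  (°C) and `SM0 ≤ SM1 ≤ SM2 ≤ SM3` (bucket fractions); cold/heat/dry/wet
  stresses accumulate weekly at fixed rates beyond their thresholds and
  cap at 100. The Ecoclimatic Index is
  `EI = GIA · Π_x (1 − S_x/100)`, `GIA = 100 · mean(GI_w)`.
  Physiological parameters can be calibrated to occurrence records by a
  real-coded genetic algorithm (`climex_fit()`), returning a fitted
  model with the usual `print`/`summary`/`coef`/`predict`/`plot`
  methods.
* **A correlative random-forest model** scores pest suitability from the
  19 bioclimatic predictors, after Pearson (|r| > 0.8) and LASSO
  screening, evaluated by AUC, the True Skill Statistic and Cohen's
  Kappa over 10 stratified 70/30 splits (`sdm_rf()`, also a fitted-model
  class with `predict` onto rasters).

Downstream, the pest map is restricted to the host's range
(`host_mask()`, `apply_mask()`: cells with host `EI = 0` become
unsuitable), classified into five levels by exact Jenks natural breaks
(`jenks_breaks()`, `classify_raster()`), differenced between epochs
(`difference_map()`), and summarised as spherical-geometry habitat areas
and percent changes per region (`cell_area()`, `area_report()`).

A seed-deterministic synthetic-world generator
(`make_synthetic_climate()`, `warm_future()`,
`sample_occurrences_from_ei()`, `sample_presences_logistic()`,
`make_region_masks()`) supplies gridded climate with latitudinal and
seasonal structure, bioclim layers, occurrences drawn from known
suitability surfaces, and region masks, so the entire pipeline runs and
is tested without any data download. Gridded I/O uses long-format CSV
(`lon, lat, variable, month, value`); see the methods vignette
(`vignettes/methods.Rmd`) for the models, assumptions and design
choices in detail.

## Worked example

```r
library(climexrf)

world  <- make_synthetic_climate(world_spec(seed = 1))   # 90 x 180, 2 deg
host   <- climex_run(world)                              # EI per cell
host
#> Ecoclimatic index grid: 90 x 180 cells
#>   EI > 0 in 4883 of 16200 valid cells; max EI 97.8

bio  <- compute_bioclim(world)
recs <- sample_presences_logistic(bio, c(bio19 = 3, bio7 = -3),
                                  n_presence = 150, n_absence = 150, seed = 11)
pest <- sdm_rf(extract_predictors(bio, recs), seed = 1)
pest
#> Random-forest suitability model
#>   predictors: bio7, bio19
#>   10 stratified 70/30 splits: AUC 0.915, TSS 0.744, Kappa 0.744

masked  <- apply_mask(predict(pest, bio), host_mask(host))
current <- classify_raster(masked)                       # 5 Jenks classes
future  <- classify_raster(
  apply_mask(predict(pest, compute_bioclim(warm_future(world, 2))),
             host_mask(climex_run(warm_future(world, 2)))),
  breaks = current$breaks)
area_report(current, future, make_region_masks(world, 5))
```

The suitability map is classified into
unsuitable/very-low/low/medium/high on natural breaks computed from the
current epoch and reused for the future epoch; the report lists, per
region and globally, suitable areas (classes above unsuitable, in
10^4 km^2) for both epochs and the percent change
`(future − current)/current · 100`, printed to one decimal per region
and two for the global total. On printed worked-example pairs the same
arithmetic gives, e.g., `percent_change(590.59, 748.19, digits = 1)` =
`26.7` and `percent_change(8616, 10165, digits = 2)` = `17.98`.

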