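---
title: "Mechanistic and correlative niche modelling with climexrf: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic and correlative niche modelling with climexrf: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climexrf)
```

`climexrf` models the joint climatic niche of a host plant (a cypress,
genus *Cupressus*) and its bark-beetle pest (*Phloeosinus cupressi*) with
two complementary models, and combines them into classified suitability
maps and per-region habitat-area accounts. This vignette explains the
models, the choices behind every tunable constant, what the synthetic-data
generator does and does not emulate, and the numerical design of the
implementation.

## 1. The mechanistic host model

The host model is an ecoclimatic-index engine in the CLIMEX tradition. It
consumes gridded monthly climate (daily Tmin/Tmax, monthly rainfall,
relative humidity at 09:00 and 15:00) and steps each grid cell through a
52-week year.

**Weekly forcing.** Monthly values are interpolated to weeks: state
variables (temperatures, humidity) piecewise-linearly between mid-month
anchors (wrapping across the year boundary), fluxes (rainfall) by
allocating each month's total to overlapping weeks in proportion to days,
which conserves annual totals exactly. The year is 52 weeks of 365/52
days; leap years are not modelled. The engine's driving temperature is
the weekly mean `(tmin + tmax) / 2`. The two humidity observations are
averaged into a single series; beyond the rainfall term of the water
balance, humidity does not enter the engine (the model family's moisture
response is mediated by soil moisture, and nothing in the host's biology
here argues for an additional direct humidity response).

**Growth.** Each week contributes a growth index `GI = TI * MI`, the
product of two trapezoidal responses:

* the temperature index `TI(t)` is 0 at or below `DV0`, rises linearly to
  1 at `DV1`, stays 1 through `DV2`, and falls to 0 at `DV3`;
* the moisture index `MI(m)` has the same shape over the soil-moisture
  thresholds `SM0..SM3`.

The trapezoid is the family's standard response shape; only the corner
values are biological parameters. The annual growth index is
`GIA = 100 * mean(GI)`.

The defaults (see `climex_params()`) are the fitted host values:
`DV0 = -15` degC (winter survival limit), `DV1 = 13.6` and `DV2 = 20.4`
degC (optimum bounds derived from climate normals of two reference
cypress stands), `DV3 = 45` degC (summer extreme of the native range),
`SM0 = 0.05` (permanent wilting point), `SM1 = 0.5`, `SM2 = 0.9`,
`SM3 = 1.5` (Mediterranean / temperate / semi-arid template values).

**Soil moisture.** Moisture is a single bucket, expressed as a fraction
of a `capacity_mm = 100` mm store, updated weekly by
`m' = clamp(m + (rain - Epot) / capacity, 0, 2)` with the
temperature-proxy evapotranspiration `Epot = max(0, 0.8 t)` mm/week. The
proxy slope, capacity and cap of 2 (a ponding/runoff margin above field
capacity) are engine constants, exposed as arguments: they are chosen so
that the `SM0..SM3` thresholds span values the bucket can actually
attain under realistic rainfall. They are deliberately simple — the
engine needs a moisture state with the right qualitative dynamics, not a
hydrological model.

**The stationary orbit.** The weekly update is a clamped shift
`x -> min(2, max(0, x + n_w))`, and the composition of the 52 weekly maps
folds in closed form to `x -> min(A, max(B, x + D))`. Its fixed point —
`A` when the annual drift `D > 0`, `B` when `D < 0`, the interval
midpoint in the measure-zero neutral case `D = 0` where every state in
`[B, A]` is periodic — is the exact stationary annual orbit, and the
engine starts the recorded year there. This replaces the usual "repeat
the year until the state converges" spin-up: iterative spin-up converges
at a rate proportional to `|D|`, so cells with a near-balanced water
budget retain their (arbitrary) initial condition for hundreds of
simulated years, whereas the closed form is exact for every cell at the
cost of one extra pass over the weeks. Initial-condition independence of
the moisture trajectory is therefore structural, and the test suite
checks both the fixed-point property and that dry- and saturated-start
iterations converge onto the computed orbit.

**Stress.** Four stresses accumulate weekly in proportion to threshold
exceedance: cold below `TTCS = -15` degC at rate 0.125/week/degC, heat
above `TTHS = 45` degC at 0.015, dry below `SMDS = 0.05` at 0.005, wet
above `SMWS = 1.5` at 0.012. Rates are used by magnitude (the
convention prints cold and dry rates with a negative sign). The annual
sum is capped at 1 and scaled to 0..100. The four stresses combine
multiplicatively into the Ecoclimatic Index

`EI = GIA * (1 - CS/100)(1 - HS/100)(1 - DS/100)(1 - WS/100)`,

clamped to [0, 100], so a single saturated stress forces `EI = 0` — the
behaviour expected of "unsuitable" cells. A linear weekly increment with
an annual cap is the simplest accumulation scheme consistent with a
cumulative stress measure; no nonlinear segment is used near the
thresholds because no data here would identify one.

## 2. Calibration by genetic algorithm

`climex_fit()` fits a configurable subset of the parameters (by default
the growth thresholds `DV0..DV3`, `SM0..SM3`, keeping the
literature-anchored stress settings fixed) to presence records. Records
are split 75/25 into a training set used by the objective and a held-out
set used only to report test coverage.

The spec-level goal — predict suitable area agreeing with the records
while not overpredicting — is encoded by `climex_fitness()`:
`coverage - penalty_weight * suitable_area_fraction`, with coverage the
fraction of presence cells with `EI > 0`, the penalty the area-weighted
fraction of valid cells with `EI > 0`, and `penalty_weight = 0.3` so
that eliminating all overprediction can repay at most a 30-point
coverage loss.

That binary objective alone cannot identify the optimum interval:
`EI > 0` depends only on the outer thresholds, so `DV1`, `DV2`, `SM1`
and `SM2` would drift freely. The GA therefore maximises the fitness
plus `likelihood_weight = 0.25` times a point-process log-likelihood
contrast, `mean(log EI)` at training presences minus `log(mean EI)` over
valid cells (EI floored at 1e-3). If presences arise with probability
proportional to EI — exactly how the synthetic sampler generates them,
and the natural idealisation of density-dependent occurrence data — this
contrast is the per-record log-likelihood up to a constant, and its
maximiser is consistent for the full parameter vector, interior corners
included. The cell mean (not the area-weighted mean) is used because
records are modelled as draws of grid cells. Setting
`likelihood_weight = 0` recovers the pure coverage-area objective.

The search itself is a standard real-coded GA: tournament selection of
size 2, uniform crossover (rate 0.9), per-gene Gaussian mutation (rate
0.2, sd one tenth of the parameter's range) clipped to bounds, elitism,
and an order-repair step that sorts each threshold group after mutation
(idempotent on ordered vectors). Defaults are a population of 30 for 80
generations — deliberately generous, because the likelihood ridge along
`DV1`/`DV2` is shallow (a few 1e-4 of the objective across several
degrees) and exploiting it needs late-generation refinement. A fitness
evaluation on the default 90 x 180 world costs ~0.15 s because the
forcing (weekly temperatures and the moisture orbit) is
parameter-independent and precomputed once.

The calibration experiment the acceptance checks run: sample 6,625
records (the size of the real host's cleaned occurrence dataset) from
the EI surface of the true parameters on the default synthetic world,
refit with the GA, and require `DV1`/`DV2` within 3 degC and a Jaccard
overlap of at least 0.7 between true and fitted `EI > 0` ranges. At a
few hundred records the experiment is underpowered for the interior
corners (the likelihood carries ~0.002 nats per record across the
plausible `DV1` range, because where winter temperatures sit on the
rising segment the wet-season bucket often saturates and `MI = 0` masks
the response); at the realistic dataset size the profile peaks at the
true values.

## 3. The correlative pest model

The pest stage is presence/pseudo-absence classification on the 19
standard bioclimatic summaries (`compute_bioclim()` derives them from
monthly climate; quarters are any three consecutive calendar months,
wrapping December-January-February, ties to the earliest start).

* `dedupe_occurrences()` removes records identical to 1e-4 degrees;
  `rarefy_occurrences()` thins greedily in input order to a minimum
  great-circle spacing (haversine, 6371 km radius). Greedy
  order-dependent thinning is documented behaviour — the upstream GIS
  tool it mirrors does not specify an order.
* `generate_pseudo_absences()` draws points uniformly over valid cells,
  at least `buffer_km` (default 50 km) from every presence.
* `pearson_filter()` walks `bio1..bio19` in order and drops any variable
  correlated above 0.8 (absolute Pearson) with an already-retained one —
  of a correlated pair the earlier variable is kept, a deterministic
  tie-break. `lasso_screen()` then fits an L1-penalised logistic model
  (penalty by 5-fold CV, 1-SE rule) and keeps the nonzero coefficients;
  if it keeps nothing, the pipeline falls back to the Pearson-retained
  set with a warning.
* `sdm_rf()` fits random forests (500 trees) over 10 repeated stratified
  70/30 splits. "10-fold cross-validation with 70% training" is read as
  10 stratified random 70/30 splits: literal 10-fold partitions would
  contradict the 70/30 ratio. Metrics per split: rank-statistic AUC, the
  True Skill Statistic at the TSS-maximising threshold (ties to the
  lowest threshold), and Cohen's Kappa at that same threshold. "TSS" is
  the True Skill Statistic (sensitivity + specificity - 1, range -1..1).
  Variable importance is permutation importance (mean decrease in
  accuracy), averaged over splits, floored at zero and normalised to
  percentages; the prediction model is refit on all records.

## 4. Maps, masking and areas

`jenks_breaks()` computes exact natural breaks by dynamic programming
over the sorted values (minimal within-class sum of squared deviations,
ties toward the lower break); breaks are the smallest member of each
upper class, and `classify_raster()` assigns half-open intervals
`[b_i, b_{i+1})` to the five levels unsuitable / very low / low / medium
/ high, so a value equal to a break belongs to the class above. For
rasters with more than 3,000 finite values the DP runs on an
evenly-spaced subsample of the sorted values — the standard approach for
large rasters; the subsampled optimum is indistinguishable in practice
and the exact path is available via `max_n`.

The host constrains the pest: `host_mask()` is the strict indicator
`EI > 0`, and `apply_mask()` removes pest suitability where the host
cannot persist; such cells classify as "unsuitable" (they are not
nodata — the distinction matters for area accounting). Current and
future maps are classified on the breaks of the current epoch so
ordinal differences (`difference_map()`, future code minus current
code, -4..+4) are comparable; per-epoch breaks remain available by
passing `breaks = NULL`.

Areas use the exact spherical formula
`A = R^2 (sin(top) - sin(bottom)) * dlon` per cell (R = 6371 km), so a
full grid integrates to the sphere's surface to rounding error.
`area_report()` sums areas per region and class for two epochs and
reports percent changes; "suitable" means every class above unsuitable
(`min_class = 1`), a definition exposed as an argument because the
boundary between "very low" and "unsuitable" is a reporting convention,
not a biological one. Continental percent changes are conventionally
printed to one decimal (two for the global total).

## 5. The synthetic world

`make_synthetic_climate()` builds a deterministic, seeded world with the
statistical structure the pipeline assumes, on a 2-degree 90 x 180 grid
by default:

* annual-mean temperature `27 - 0.55 |lat|` degC with per-cell Gaussian
  offsets (sd 0.5), sinusoidal seasonality with amplitude growing to 15
  degC at the poles (July peak in the north, January in the south) plus
  per-cell amplitude noise (sd 2 degC, emulating continentality), and a
  per-cell diurnal half-range (mean 5, sd 3 degC);
* annual precipitation peaked at the equator (1300 mm) and at
  mid-latitudes (500 mm at 45 deg) over a 500 mm background, log-normal
  per-cell factors (log-sd 0.3), distributed over months with a per-cell
  seasonality: winter-wet outside the tropics, summer-wet (monsoonal)
  within 15 degrees of the equator, with sd 0.25 noise on the
  parameter;
* humidity tied to monthly rainfall.

These choices make the default parameterisation produce a mid-latitude
suitable belt (the wet tropics fail on moisture saturation, the poles on
temperature and cold stress, the subtropical interiors on drought) and
give the bioclim layers partially independent signals: amplitude and
diurnal noise decorrelate the annual temperature range (bio7) from the
latitudinal mean-temperature gradient (bio1) and from temperature
seasonality (bio4), and the mixed winter-wet/summer-wet seasonality
decorrelates coldest-quarter precipitation (bio19) from the wettest
month (bio13). Without that structure the screening stage would
(correctly) collapse the predictor set and no correlative recovery
experiment would be possible — real climatologies carry exactly these
independent signals (continentality, storm-track position, monsoon
regimes).

What the generator does **not** emulate: spatial autocorrelation of the
noise fields (cells are independent), orography, land/sea contrast,
realistic GCM change patterns (the future scenario is a uniform shift
and rainfall scaling), and observation biases in occurrence data beyond
what rarefaction handles. Tests passing on this world therefore
demonstrate the correctness and statistical behaviour of the pipeline,
not the realism of any particular map.

`warm_future()` (+2 degC by default) is used for the qualitative
warming property: the area-weighted |latitude| centroid of the host's
`EI > 0` range moves poleward in both hemispheres.

Region masks are rectangular longitude bands over the middle 80% of
latitude rows — continent stand-ins sufficient for testing area
accounting conservation and symmetry.

## 6. Numerical choices and degenerate inputs

* Trapezoids: exactly 0 at and outside the outer corners, exactly 1 on
  the optimum; degenerate equal corners collapse to steps.
* Stress sums cap at 1 before scaling; EI clamps to [0, 100].
* Weekly rain allocation conserves annual totals to machine precision;
  the 0.5% contract in the tests is slack for accumulated rounding.
* `jenks_breaks()` needs at least k distinct finite values and errors
  otherwise; constant predictor columns are dropped from screening with
  a warning (their correlation is undefined).
* All-nodata cells propagate NA through every stage; masked-but-valid
  cells classify as unsuitable (see above).
* Every stochastic step (world generation, sampling, pseudo-absences,
  GA, CV folds, forests) takes an explicit integer seed and is
  bit-reproducible given it.

## 7. Problem sizes used by the checks

The acceptance checks run the calibration experiment at the full default
world (90 x 180 cells, 6,625 sampled records, population 30, 80
generations — a few minutes on one CPU thanks to the precomputed
forcing) and the correlative experiment at 150 presences + 150
pseudo-absences with 10 splits of 500 trees. Unit tests use coarser
worlds (24 x 48 to 30 x 60) where the property under test does not
depend on resolution.
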