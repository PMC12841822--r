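# Seed-deterministic synthetic world: gridded monthly climate with
# latitudinal and seasonal structure, derived bioclim layers, occurrences
# sampled from a known suitability surface, and rectangular region masks.
# Every generator is deterministic for a fixed seed and writes/reads
# through the package's standard containers.

#' Specification of a synthetic world
#'
#' The default world is a 2-degree global grid with: sea-level annual-mean
#' temperature `t_eq - t_lapse * |lat|` degC; seasonal amplitude growing to
#' `seas_amp` degC at the poles (warm peak in July north of the equator,
#' January south); per-cell Gaussian variation of the annual mean
#' (`noise_sd`), of the seasonal amplitude (`amp_noise_sd`, emulating
#' continentality) and of the diurnal half-range (`diurnal_sd` around
#' `diurnal`); and annual precipitation peaked at the equator and again at
#' mid-latitudes, log-normally perturbed per cell, distributed over months
#' with a per-cell seasonality whose sign (winter-wet versus summer-wet)
#' varies with latitude. These knobs exist so the bioclim layers carry
#' partially independent temperature-range and winter-rainfall signals, as
#' real climatologies do.
#'
#' @param nlat,nlon grid shape (default 90 x 180, i.e. 2-degree cells).
#' @param t_eq sea-level annual mean at the equator, degC.
#' @param t_lapse meridional gradient, degC per degree latitude.
#' @param seas_amp seasonal amplitude at the poles, degC.
#' @param noise_sd per-cell sd of the annual-mean temperature offset, degC.
#' @param amp_noise_sd per-cell sd of the seasonal amplitude, degC.
#' @param diurnal,diurnal_sd mean and per-cell sd of the diurnal
#'   half-range, degC.
#' @param precip_eq,precip_mid,precip_base equatorial peak, mid-latitude
#'   (45 deg) peak and background annual precipitation, mm.
#' @param precip_lsd per-cell log-sd of the annual precipitation factor.
#' @param season_wet_amp amplitude of the monthly precipitation seasonality
#'   in (0, 1); `season_noise_sd` is its per-cell sd.
#' @param season_noise_sd per-cell sd of the seasonality parameter.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   world.
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(nlat = 90, nlon = 180, t_eq = 27, t_lapse = 0.55,
                       seas_amp = 15, noise_sd = 0.5, amp_noise_sd = 2,
                       diurnal = 5, diurnal_sd = 3,
                       precip_eq = 1300, precip_mid = 500, precip_base = 500,
                       precip_lsd = 0.3, season_wet_amp = 0.6,
                       season_noise_sd = 0.25, seed = 1L) {
  stopifnot(nlat >= 2, nlon >= 2)
  structure(as.list(environment()), class = "world_spec")
}

#' Generate a synthetic monthly climate grid
#'
#' Realises the world described by a [world_spec()]: 12 monthly layers of
#' tmin/tmax/rain and 09:00/15:00 relative humidity on a regular grid, with
#' hemispherically phase-shifted sinusoidal seasonality. Deterministic per
#' seed.
#'
#' @param spec a [world_spec()].
#' @return a [climate_grid()].
#' @export
make_synthetic_climate <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  nlat <- spec$nlat; nlon <- spec$nlon
  lat <- seq(-90 + 90 / nlat, 90 - 90 / nlat, length.out = nlat)
  lon <- seq(-180 + 180 / nlon, 180 - 180 / nlon, length.out = nlon)
  L <- matrix(abs(lat), nlat, nlon)

  t_mean <- spec$t_eq - spec$t_lapse * L +
    matrix(stats::rnorm(nlat * nlon, 0, spec$noise_sd), nlat, nlon)
  amp <- pmax(0, spec$seas_amp * L / 90 +
                matrix(stats::rnorm(nlat * nlon, 0, spec$amp_noise_sd), nlat, nlon))
  diurnal <- pmax(0.5, matrix(stats::rnorm(nlat * nlon, spec$diurnal,
                                           spec$diurnal_sd), nlat, nlon))

  p_annual <- (spec$precip_base + spec$precip_eq * exp(-(L / 15)^2) +
                 spec$precip_mid * exp(-((L - 45) / 12)^2)) *
    exp(matrix(stats::rnorm(nlat * nlon, 0, spec$precip_lsd), nlat, nlon))

  # seasonality of rain: winter-wet (positive) in the subtropics and
  # mid-latitudes, summer-wet (negative, monsoonal) in the tropics
  s_base <- ifelse(L < 15, -spec$season_wet_amp, spec$season_wet_amp)
  s <- pmin(0.95, pmax(-0.95, s_base +
                         matrix(stats::rnorm(nlat * nlon, 0, spec$season_noise_sd),
                                nlat, nlon)))

  south <- matrix(lat < 0, nlat, nlon)
  arr <- function() array(NA_real_, c(nlat, nlon, 12))
  tmin <- arr(); tmax <- arr(); rain <- arr(); rh09 <- arr(); rh15 <- arr()
  for (m in 1:12) {
    # warm-season phase: July peak in the north, January in the south
    phase <- cos(2 * pi * (m - 7) / 12)
    phase_cell <- ifelse(south, -phase, phase)
    tavg_m <- t_mean + amp * phase_cell
    tmin[, , m] <- tavg_m - diurnal
    tmax[, , m] <- tavg_m + diurnal
    # winter phase factor: +1 in midwinter, -1 in midsummer
    rain[, , m] <- p_annual / 12 * (1 - s * phase_cell)
    rh <- pmin(100, pmax(5, 40 + 0.45 * rain[, , m]))
    rh09[, , m] <- rh
    rh15[, , m] <- pmax(5, rh - 12)
  }
  climate_grid(lat, lon, tmin, tmax, rain, rh09, rh15)
}

#' Apply a uniform warming / precipitation scaling to a climate grid
#'
#' A deliberately simple future scenario: all temperatures shifted by
#' `delta_t` degC and all monthly precipitation scaled by `precip_factor`.
#' Humidity is left unchanged.
#'
#' @param grid a [climate_grid()].
#' @param delta_t uniform temperature change, degC (default +2).
#' @param precip_factor multiplicative precipitation change (default 1).
#' @return the warmed [climate_grid()].
#' @export
warm_future <- function(grid, delta_t = 2, precip_factor = 1) {
  stopifnot(inherits(grid, "climate_grid"))
  if (precip_factor < 0) stop("precip_factor must be non-negative")
  climate_grid(grid$lat, grid$lon, grid$tmin + delta_t, grid$tmax + delta_t,
               grid$rain * precip_factor, grid$rh09, grid$rh15,
               mask = grid$mask)
}

#' Sample presence records from an EI surface
#'
#' Draws `n` cells with probability proportional to their EI and jitters
#' each point uniformly within its cell. This produces occurrence records
#' whose density follows a known suitability surface, the input for
#' parameter-recovery experiments.
#'
#' @param ei an `ei_grid`/[climex_run()] object with some EI > 0.
#' @param n number of records.
#' @param seed integer RNG seed.
#' @return an [occurrence_set()] of presences.
#' @export
sample_occurrences_from_ei <- function(ei, n, seed = 1L) {
  if (n == 0) return(occurrence_set(numeric(0), numeric(0)))
  w <- ei$ei
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("EI surface is identically zero; nothing to sample")
  set.seed(seed)
  cells <- sample(length(w), n, replace = TRUE, prob = as.vector(w))
  nlat <- length(ei$lat)
  row <- (cells - 1) %% nlat + 1
  col <- (cells - 1) %/% nlat + 1
  dlat <- axis_step(ei$lat); dlon <- axis_step(ei$lon)
  lat <- pmin(90, pmax(-90, ei$lat[row] + stats::runif(n, -dlat / 2, dlat / 2)))
  lon <- ei$lon[col] + stats::runif(n, -dlon / 2, dlon / 2)
  lon <- ((lon + 180) %% 360) - 180
  occurrence_set(lon, lat, label = "presence", source_id = "synthetic_ei")
}

#' Sample presence/absence records from a logistic model on bioclim layers
#'
#' Standardises the named layers over valid cells, forms the linear
#' predictor from `coefficients`, maps it through the logistic function to
#' a per-cell presence probability, and samples `n_presence` cells with
#' probability proportional to p and `n_absence` cells proportional to
#' 1 - p, jittered within cells. The coefficient structure is therefore the
#' ground truth that a correlative model fitted to these records should
#' recover.
#'
#' @param bioclim a [compute_bioclim()] grid.
#' @param coefficients named numeric vector, names in `bio1..bio19`.
#' @param n_presence,n_absence record counts.
#' @param seed integer RNG seed.
#' @param intercept intercept of the linear predictor (default 0).
#' @return an [occurrence_set()] with both labels.
#' @export
sample_presences_logistic <- function(bioclim, coefficients, n_presence,
                                      n_absence, seed = 1L, intercept = 0) {
  stopifnot(inherits(bioclim, "bioclim_grid"))
  vars <- names(coefficients)
  if (!all(vars %in% dimnames(bioclim$layers)[[3]])) {
    stop("coefficient names must be bioclim layer names")
  }
  valid <- which(bioclim$mask)
  eta <- rep(intercept, length(valid))
  for (v in vars) {
    x <- bioclim$layers[, , v][valid]
    if (stats::sd(x) == 0 && coefficients[[v]] != 0) {
      stop("layer '", v, "' has zero variance but a nonzero coefficient")
    }
    z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    eta <- eta + coefficients[[v]] * z
  }
  p <- stats::plogis(eta)
  set.seed(seed)
  draw <- function(nn, w, lab, tag) {
    if (nn == 0) return(NULL)
    if (sum(w) <= 0) stop("degenerate probabilities for ", lab)
    cells <- valid[sample(length(valid), nn, replace = TRUE, prob = w)]
    nlat <- length(bioclim$lat)
    row <- (cells - 1) %% nlat + 1
    col <- (cells - 1) %/% nlat + 1
    dlat <- axis_step(bioclim$lat); dlon <- axis_step(bioclim$lon)
    lat <- pmin(90, pmax(-90, bioclim$lat[row] +
                           stats::runif(nn, -dlat / 2, dlat / 2)))
    lon <- bioclim$lon[col] + stats::runif(nn, -dlon / 2, dlon / 2)
    lon <- ((lon + 180) %% 360) - 180
    occurrence_set(lon, lat, label = lab, source_id = tag)
  }
  pres <- draw(n_presence, p, "presence", "synthetic_logistic")
  abs_ <- draw(n_absence, 1 - p, "pseudo_absence", "synthetic_logistic")
  out <- rbind(pres, abs_)
  structure(out, class = c("occurrence_set", "data.frame"))
}

#' Rectangular region masks ("continents") on a grid
#'
#' Splits an inset portion of the grid (80% of rows, all columns) into
#' `n_regions` equal-width, disjoint longitude bands labelled `1..n`.
#' Because the bands share latitude rows, equal-width bands have exactly
#' equal spherical areas.
#'
#' @param grid any object with `lat`/`lon` axes.
#' @param n_regions number of regions (>= 1).
#' @return integer label matrix `[nlat, nlon]`, 0 outside all regions.
#' @export
make_region_masks <- function(grid, n_regions) {
  stopifnot(n_regions >= 1)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (n_regions > nlon) stop("more regions than longitude columns")
  rows <- seq(max(1, round(0.1 * nlat)), min(nlat, round(0.9 * nlat)))
  edges <- floor(seq(0, nlon, length.out = n_regions + 1))
  lab <- matrix(0L, nlat, nlon)
  for (r in seq_len(n_regions)) {
    cols <- (edges[r] + 1):edges[r + 1]
    lab[rows, cols] <- r
  }
  lab
}
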