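# Mechanistic ecoclimatic suitability engine. Per cell and week the model
# evaluates a temperature index (TI) and soil-moisture index (MI), both
# trapezoidal in [0, 1]; their product is the weekly growth index. The
# annual growth index GIA is 100 * mean(GI). Cold/heat/dry/wet stress
# accumulates weekly in proportion to threshold exceedance and caps at 100.
# The Ecoclimatic Index combines both: EI = GIA * prod(1 - S/100).

# Trapezoid over corners a <= b <= c <= d: 0 at/below a and at/above d,
# 1 on [b, c], linear between. Degenerate equal corners collapse to steps.
trapezoid <- function(x, a, b, c, d) {
  up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
  down <- if (d > c) (d - x) / (d - c) else as.numeric(x <= c)
  y <- pmin(pmax(pmin(up, down), 0), 1)
  y[x <= a | x >= d] <- 0
  dim(y) <- dim(x)
  y
}

#' Weekly temperature index
#'
#' Trapezoidal 0-1 response of growth to weekly temperature: 0 at or below
#' `DV0` and at or above `DV3`, 1 on the optimum `[DV1, DV2]`, linear in
#' between.
#'
#' @param t_week weekly mean temperature, degC (vectorised).
#' @param p a [climex_params()].
#' @return values in \[0, 1\].
#' @export
temperature_index <- function(t_week, p = climex_params()) {
  trapezoid(t_week, p[["DV0"]], p[["DV1"]], p[["DV2"]], p[["DV3"]])
}

#' Weekly soil-moisture index
#'
#' Trapezoidal 0-1 response to the soil-moisture state, with corners
#' `SM0..SM3` (fractions of bucket capacity).
#'
#' @param m soil-moisture state (vectorised), >= 0.
#' @param p a [climex_params()].
#' @return values in \[0, 1\].
#' @export
moisture_index <- function(m, p = climex_params()) {
  trapezoid(m, p[["SM0"]], p[["SM1"]], p[["SM2"]], p[["SM3"]])
}

#' One weekly step of the soil-moisture bucket
#'
#' A single-layer bucket of capacity `capacity_mm`: moisture (expressed as a
#' fraction of capacity) gains the week's rainfall and loses a
#' temperature-proxy potential evapotranspiration
#' `Epot = max(0, 0.8 * t_week)` mm/week, clamped to `[0, sm_cap]`. The
#' state can exceed 1 (ponding/runoff range) up to `sm_cap`.
#'
#' @param m_prev previous moisture state (fraction of capacity), >= 0.
#' @param rain_week rainfall, mm/week, >= 0.
#' @param t_week weekly mean temperature, degC.
#' @param capacity_mm bucket capacity in mm (default 100).
#' @param sm_cap upper clamp of the moisture state (default 2).
#' @return new moisture state.
#' @export
soil_moisture_step <- function(m_prev, rain_week, t_week,
                               capacity_mm = 100, sm_cap = 2) {
  if (any(rain_week < 0)) stop("rain_week must be non-negative")
  if (any(m_prev < 0)) stop("m_prev must be non-negative")
  epot <- pmax(0, 0.8 * t_week)
  pmin(sm_cap, pmax(0, m_prev + (rain_week - epot) / capacity_mm))
}

#' Annual growth index from 52 weekly growth indices
#'
#' @param gi_weekly numeric vector of 52 weekly growth indices in \[0, 1\].
#' @return GIA in \[0, 100\]: `100 * mean(gi_weekly)`.
#' @export
annual_growth_index <- function(gi_weekly) {
  if (length(gi_weekly) != 52) stop("gi_weekly must have 52 entries")
  100 * mean(gi_weekly)
}

#' Annual cold/heat/dry/wet stress indices
#'
#' Each stress accumulates weekly as `|rate| * max(0, exceedance)` where the
#' exceedance is `TTCS - t` (cold), `t - TTHS` (heat), `SMDS - m` (dry) and
#' `m - SMWS` (wet); the annual sum is capped at 1 and scaled to \[0, 100\].
#' Rates are taken by magnitude, so the conventional negative signs on the
#' cold and dry rates are immaterial.
#'
#' @param tavg_weekly 52 weekly mean temperatures, degC.
#' @param m_weekly 52 weekly soil-moisture states.
#' @param p a [climex_params()].
#' @return named vector `c(CS, HS, DS, WS)`, each in \[0, 100\].
#' @export
stress_indices <- function(tavg_weekly, m_weekly, p = climex_params()) {
  if (length(tavg_weekly) != 52 || length(m_weekly) != 52) {
    stop("weekly series must have 52 entries")
  }
  acc <- function(rate, exceed) 100 * min(1, sum(abs(rate) * pmax(0, exceed)))
  c(CS = acc(p[["THCS"]], p[["TTCS"]] - tavg_weekly),
    HS = acc(p[["THHS"]], tavg_weekly - p[["TTHS"]]),
    DS = acc(p[["HDS"]], p[["SMDS"]] - m_weekly),
    WS = acc(p[["HWS"]], m_weekly - p[["SMWS"]]))
}

#' Ecoclimatic index from growth and stress
#'
#' `EI = GIA * prod(1 - S/100)`, clamped to \[0, 100\]; any saturated stress
#' (S = 100) forces EI = 0.
#'
#' @param gia annual growth index in \[0, 100\].
#' @param stresses numeric vector of the four stress indices in \[0, 100\].
#' @return EI in \[0, 100\].
#' @export
ecoclimatic_index <- function(gia, stresses) {
  pmin(100, pmax(0, gia * prod(1 - stresses / 100)))
}

#' Full annual index calculation for a single cell
#'
#' Runs the weekly model on explicit 52-week forcing series: soil-moisture
#' spin-up, weekly TI/MI/GI, GIA, stress accumulation and EI. Mainly a
#' transparent single-cell view of what [climex_run()] does on a grid.
#'
#' @param tavg_weekly,rain_weekly 52-week temperature (degC) and rainfall
#'   (mm/week) series.
#' @param p a [climex_params()].
#' @param capacity_mm,sm_cap bucket constants, see [soil_moisture_step()].
#' @return list with `TIw`, `MIw`, `GIw`, `m` (52-vectors), `GIA`,
#'   `stresses` (CS/HS/DS/WS) and `EI`.
#' @export
climex_cell <- function(tavg_weekly, rain_weekly, p = climex_params(),
                        capacity_mm = 100, sm_cap = 2) {
  if (length(tavg_weekly) != 52 || length(rain_weekly) != 52) {
    stop("weekly series must have 52 entries")
  }
  m <- spinup_moisture(matrix(rain_weekly, 1), matrix(tavg_weekly, 1),
                       capacity_mm, sm_cap)[1, ]
  TIw <- temperature_index(tavg_weekly, p)
  MIw <- moisture_index(m, p)
  GIw <- TIw * MIw
  GIA <- annual_growth_index(GIw)
  S <- stress_indices(tavg_weekly, m, p)
  list(TIw = TIw, MIw = MIw, GIw = GIw, m = m, GIA = GIA, stresses = S,
       EI = ecoclimatic_index(GIA, S))
}

# Stationary annual moisture orbit of the bucket, computed exactly.
#
# Each weekly update is the clamped shift x -> min(sm_cap, max(0, x + n_w)).
# Compositions of such maps stay of the form x -> min(A, max(B, x + D)), so
# folding the 52 weekly steps gives the closed form of the whole annual
# map. Its fixed point is A when the annual drift D > 0, B when D < 0, and
# (for the measure-zero neutral case D = 0, where every state in [B, A] is
# periodic) the canonical midpoint (A + B) / 2. Starting the year at that
# fixed point yields the exact periodic orbit every initial condition is
# attracted to, with no spin-up iteration.
#
# rain/tavg are [cell, 52] matrices; returns the [cell, 52] trajectory
# (state recorded after each week's update).
spinup_moisture <- function(rain, tavg, capacity_mm = 100, sm_cap = 2) {
  nc <- nrow(rain)
  net <- (rain - pmax(0.8 * tavg, 0)) / capacity_mm
  A <- rep(Inf, nc); B <- rep(-Inf, nc); D <- rep(0, nc)
  for (w in 1:52) {
    n <- net[, w]
    A <- pmin(sm_cap, pmax(A + n, 0))
    B <- pmin(sm_cap, pmax(B + n, 0))
    D <- D + n
  }
  m <- ifelse(D > 0, A, ifelse(D < 0, B, (A + B) / 2))
  M <- matrix(NA_real_, nc, 52)
  for (w in 1:52) {
    m <- pmin(sm_cap, pmax(m + net[, w], 0))
    M[, w] <- m
  }
  M
}

# Precomputed, parameter-independent forcing for repeated engine runs on
# one climate grid: weekly temperature and the converged soil-moisture
# trajectory for every valid cell. Used heavily by the GA calibration.
climex_forcing <- function(climate, capacity_mm = 100, sm_cap = 2) {
  stopifnot(inherits(climate, "climate_grid"))
  wk <- monthly_to_weekly(climate)
  nlat <- length(climate$lat); nlon <- length(climate$lon)
  valid <- which(climate$mask)
  tavg <- matrix(wk$tavg, nlat * nlon, 52)[valid, , drop = FALSE]
  rain <- matrix(wk$rain, nlat * nlon, 52)[valid, , drop = FALSE]
  m <- spinup_moisture(rain, tavg, capacity_mm, sm_cap)
  structure(list(lat = climate$lat, lon = climate$lon, mask = climate$mask,
                 valid = valid, tavg = tavg, moisture = m,
                 area = cell_area_matrix(climate)[valid]),
            class = "climex_forcing")
}

# Vectorised annual indices on precomputed forcing. Returns per-valid-cell
# vectors; the exported climex_run() reshapes them onto the grid.
forcing_indices <- function(forcing, p) {
  ti <- temperature_index(forcing$tavg, p)
  mi <- moisture_index(forcing$moisture, p)
  gia <- 100 * rowMeans(ti * mi)
  cap <- function(x) 100 * pmin(1, x)
  cs <- cap(rowSums(abs(p[["THCS"]]) * pmax(p[["TTCS"]] - forcing$tavg, 0)))
  hs <- cap(rowSums(abs(p[["THHS"]]) * pmax(forcing$tavg - p[["TTHS"]], 0)))
  ds <- cap(rowSums(abs(p[["HDS"]]) * pmax(p[["SMDS"]] - forcing$moisture, 0)))
  ws <- cap(rowSums(abs(p[["HWS"]]) * pmax(forcing$moisture - p[["SMWS"]], 0)))
  ei <- pmin(100, pmax(0, gia * (1 - cs / 100) * (1 - hs / 100) *
                         (1 - ds / 100) * (1 - ws / 100)))
  list(gia = gia, cs = cs, hs = hs, ds = ds, ws = ws, ei = ei)
}

#' Run the ecoclimatic engine over a climate grid
#'
#' Per valid cell: monthly-to-weekly interpolation, soil-moisture spin-up
#' (the annual cycle is repeated until the start-of-year state changes by
#' less than 1e-6, at most 10 cycles), weekly growth indices, annual stress
#' accumulation and the Ecoclimatic Index. Deterministic; nodata cells
#' propagate as NA.
#'
#' @param climate a [climate_grid()] (or a prebuilt internal forcing object).
#' @param p a [climex_params()].
#' @param capacity_mm,sm_cap soil bucket constants, see
#'   [soil_moisture_step()].
#' @return an object of class `climex_run` (which also inherits `ei_grid`):
#'   `lat`, `lon`, and matrices `ei`, `gia`, `cs`, `hs`, `ds`, `ws`.
#' @export
climex_run <- function(climate, p = climex_params(),
                       capacity_mm = 100, sm_cap = 2) {
  forcing <- if (inherits(climate, "climex_forcing")) climate
             else climex_forcing(climate, capacity_mm, sm_cap)
  idx <- forcing_indices(forcing, p)
  nlat <- length(forcing$lat); nlon <- length(forcing$lon)
  put <- function(v) {
    m <- matrix(NA_real_, nlat, nlon)
    m[forcing$valid] <- v
    m
  }
  structure(list(lat = forcing$lat, lon = forcing$lon, ei = put(idx$ei),
                 gia = put(idx$gia), cs = put(idx$cs), hs = put(idx$hs),
                 ds = put(idx$ds), ws = put(idx$ws)),
            class = c("climex_run", "ei_grid"))
}

#' @export
print.climex_run <- function(x, ...) {
  v <- x$ei[!is.na(x$ei)]
  cat("Ecoclimatic index grid:", length(x$lat), "x", length(x$lon),
      "cells\n  EI > 0 in", sum(v > 0), "of", length(v), "valid cells;",
      "max EI", round(max(v), 1), "\n")
  invisible(x)
}

#' Write an EI grid as CSV (lon, lat, ei)
#'
#' @param ei an `ei_grid`/`climex_run` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ei_csv <- function(ei, path) {
  ok <- which(!is.na(ei$ei), arr.ind = TRUE)
  utils::write.csv(data.frame(lon = ei$lon[ok[, 2]], lat = ei$lat[ok[, 1]],
                              ei = ei$ei[ok]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
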