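# Gridded monthly climate: container, validation, CSV I/O, weekly
# interpolation and the 19 standard bioclimatic summaries.

CLIMATE_VARS <- c("tmin", "tmax", "rain", "rh09", "rh15")
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
WEEK_LEN <- 365 / 52

#' Monthly climate grid
#'
#' Container for gridded monthly climate driving the ecoclimatic engine:
#' daily minimum and maximum temperature (degC), monthly precipitation (mm)
#' and relative humidity (%) observed at 09:00 and 15:00, on a regular
#' lat/lon grid (cell-centre registration, WGS84 decimal degrees).
#'
#' @param lat,lon ascending regular axes of cell-centre coordinates.
#' @param tmin,tmax,rain,rh09,rh15 numeric arrays `[nlat, nlon, 12]`.
#' @param mask optional logical matrix `[nlat, nlon]`; `FALSE` marks nodata
#'   cells. Defaults to cells with complete data in all variables.
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(lat, lon, tmin, tmax, rain, rh09, rh15, mask = NULL) {
  check_axes(lat, lon)
  dims <- c(length(lat), length(lon), 12L)
  vars <- list(tmin = tmin, tmax = tmax, rain = rain, rh09 = rh09, rh15 = rh15)
  for (v in names(vars)) {
    if (!identical(dim(vars[[v]]), as.integer(dims))) {
      stop("variable '", v, "' must be a [nlat, nlon, 12] array")
    }
  }
  complete <- apply(!is.na(tmin) & !is.na(tmax) & !is.na(rain) &
                      !is.na(rh09) & !is.na(rh15), c(1, 2), all)
  if (is.null(mask)) mask <- complete else mask <- mask & complete
  g <- structure(list(lat = lat, lon = lon, tmin = tmin, tmax = tmax,
                      rain = rain, rh09 = rh09, rh15 = rh15, mask = mask),
                 class = "climate_grid")
  validate_climate_grid(g)
  g
}

#' @export
print.climate_grid <- function(x, ...) {
  cat("Monthly climate grid:", length(x$lat), "x", length(x$lon), "cells,",
      sum(x$mask), "valid\n")
  cat("  lat", min(x$lat), "..", max(x$lat), " lon", min(x$lon), "..",
      max(x$lon), " step", axis_step(x$lat), "deg\n")
  invisible(x)
}

# Enforce the physical invariants on valid cells; names the first offending
# cell so bad input files are diagnosable.
validate_climate_grid <- function(g) {
  idx <- which(g$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(invisible(g))
  for (m in 1:12) {
    tmin <- g$tmin[, , m][g$mask]; tmax <- g$tmax[, , m][g$mask]
    rain <- g$rain[, , m][g$mask]
    rh <- cbind(g$rh09[, , m][g$mask], g$rh15[, , m][g$mask])
    bad <- which(tmax < tmin)
    if (length(bad)) {
      stop(sprintf("tmax < tmin at cell (lat=%g, lon=%g), month %d",
                   g$lat[idx[bad[1], 1]], g$lon[idx[bad[1], 2]], m))
    }
    bad <- which(rain < 0)
    if (length(bad)) {
      stop(sprintf("negative rain at cell (lat=%g, lon=%g), month %d",
                   g$lat[idx[bad[1], 1]], g$lon[idx[bad[1], 2]], m))
    }
    bad <- which(rh < 0 | rh > 100)
    if (length(bad)) {
      stop(sprintf("relative humidity outside [0, 100] near cell (lat=%g), month %d",
                   g$lat[idx[((bad[1] - 1) %% nrow(rh)) + 1, 1]], m))
    }
  }
  invisible(g)
}

#' Read a monthly climate grid from long-format CSV
#'
#' Expects columns `lon, lat, variable, month, value` with variables
#' `tmin, tmax, rain, rh09, rh15` and months 1..12. Cells absent from the
#' file are nodata. Axes are inferred from the coordinates present and must
#' form a regular grid.
#'
#' @param path CSV file path.
#' @return a [climate_grid()].
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "variable", "month", "value")
  if (!all(need %in% names(d))) {
    stop("climate CSV must have columns: ", paste(need, collapse = ", "))
  }
  missing_vars <- setdiff(CLIMATE_VARS, unique(d$variable))
  if (length(missing_vars)) {
    stop("climate CSV is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  lat <- as.numeric(sort(unique(d$lat)))
  lon <- as.numeric(sort(unique(d$lon)))
  if (length(lat) > 1) axis_step(lat)
  if (length(lon) > 1) axis_step(lon)
  if (length(lat) < 2 || length(lon) < 2) {
    stop("climate CSV must cover at least a 2 x 2 grid")
  }
  arr <- function() array(NA_real_, c(length(lat), length(lon), 12))
  vars <- stats::setNames(lapply(CLIMATE_VARS, function(v) arr()), CLIMATE_VARS)
  row <- match(d$lat, lat); col <- match(d$lon, lon)
  if (any(d$month < 1 | d$month > 12)) stop("month outside 1..12")
  for (v in CLIMATE_VARS) {
    sel <- d$variable == v
    vars[[v]][cbind(row[sel], col[sel], d$month[sel])] <- d$value[sel]
  }
  climate_grid(lat, lon, vars$tmin, vars$tmax, vars$rain, vars$rh09, vars$rh15)
}

#' Write a monthly climate grid to long-format CSV
#'
#' Inverse of [read_climate_csv()]; nodata cells are omitted.
#'
#' @param grid a [climate_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  idx <- which(grid$mask, arr.ind = TRUE)
  rows <- do.call(rbind, lapply(CLIMATE_VARS, function(v) {
    do.call(rbind, lapply(1:12, function(m) {
      data.frame(lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
                 variable = v, month = m, value = grid[[v]][, , m][grid$mask])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- weekly interpolation ---------------------------------------------------

# Midpoint day-of-year of each calendar month (365-day year).
month_mid_days <- function() cumsum(c(0, MONTH_DAYS[-12])) + MONTH_DAYS / 2

# 12 x 52 weight matrix: piecewise-linear interpolation from mid-month
# anchors to week midpoints, wrapping across the year boundary. Used for
# state variables (temperature, humidity).
state_interp_weights <- function() {
  mids <- month_mid_days()
  W <- matrix(0, 12, 52)
  wk_mid <- (seq_len(52) - 0.5) * WEEK_LEN
  for (w in seq_len(52)) {
    t <- wk_mid[w]
    if (t < mids[1]) {
      m0 <- 12; m1 <- 1; t0 <- mids[12] - 365; t1 <- mids[1]
    } else if (t >= mids[12]) {
      m0 <- 12; m1 <- 1; t0 <- mids[12]; t1 <- mids[1] + 365
    } else {
      m0 <- max(which(mids <= t)); m1 <- m0 + 1
      t0 <- mids[m0]; t1 <- mids[m1]
    }
    f <- (t - t0) / (t1 - t0)
    W[m0, w] <- W[m0, w] + (1 - f)
    W[m1, w] <- W[m1, w] + f
  }
  W
}

# 12 x 52 allocation matrix for fluxes: the fraction of each month's total
# assigned to each week, proportional to overlapping days. Columns of the
# transpose sum to 1 per month, so annual totals are conserved exactly.
flux_alloc_weights <- function() {
  starts <- cumsum(c(0, MONTH_DAYS[-12]))
  ends <- starts + MONTH_DAYS
  A <- matrix(0, 12, 52)
  for (w in seq_len(52)) {
    w0 <- (w - 1) * WEEK_LEN; w1 <- w * WEEK_LEN
    ov <- pmax(0, pmin(ends, w1) - pmax(starts, w0))
    A[, w] <- ov / MONTH_DAYS
  }
  A
}

#' Interpolate monthly climate to a 52-week series
#'
#' Temperatures and humidity are interpolated piecewise-linearly between
#' mid-month anchor values (wrapping across the year boundary); monthly
#' precipitation is divided across the weeks overlapping each month in
#' proportion to days, which conserves the annual total exactly. The year is
#' 52 weeks of 365/52 days. The single humidity series is the mean of the
#' 09:00 and 15:00 observations.
#'
#' @param grid a [climate_grid()].
#' @return an object of class `weekly_series` with arrays `tavg`, `tmin`,
#'   `tmax` (degC), `rain` (mm/week) and `rh` (%) of shape `[nlat, nlon, 52]`.
#' @export
monthly_to_weekly <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  W <- state_interp_weights(); A <- flux_alloc_weights()
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  flat <- function(a) matrix(a, nlat * nlon, 12)   # [cell, month]
  shape <- function(m) array(m, c(nlat, nlon, 52))
  tminw <- flat(grid$tmin) %*% W
  tmaxw <- flat(grid$tmax) %*% W
  rhw <- ((flat(grid$rh09) + flat(grid$rh15)) / 2) %*% W
  rainw <- flat(grid$rain) %*% A
  nod <- !grid$mask
  out <- list(lat = grid$lat, lon = grid$lon,
              tavg = shape((tminw + tmaxw) / 2), tmin = shape(tminw),
              tmax = shape(tmaxw), rain = shape(rainw), rh = shape(rhw))
  for (v in c("tavg", "tmin", "tmax", "rain", "rh")) {
    out[[v]][array(nod, c(nlat, nlon, 52))] <- NA_real_
  }
  out$mask <- grid$mask
  structure(out, class = "weekly_series")
}

# --- bioclimatic summaries --------------------------------------------------

#' Compute the 19 standard bioclimatic layers
#'
#' Derives bio1..bio19 from monthly temperature and precipitation using the
#' standard definitions: annual means/extremes, seasonality, and
#' quarter-based summaries where a quarter is any 3 consecutive calendar
#' months (wrapping Dec-Jan-Feb), with ties broken toward the earliest start
#' month. bio4 is 100 times the standard deviation of monthly mean
#' temperature; bio15 is the coefficient of variation of monthly
#' precipitation in percent (0 when the annual total is 0).
#'
#' @param grid a [climate_grid()].
#' @return an object of class `bioclim_grid` with `layers[nlat, nlon, 19]`
#'   (dimnames `bio1..bio19`) and the nodata mask of `grid`.
#' @export
compute_bioclim <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  nlat <- length(grid$lat); nlon <- length(grid$lon); nc <- nlat * nlon
  tmin <- matrix(grid$tmin, nc, 12); tmax <- matrix(grid$tmax, nc, 12)
  prec <- matrix(grid$rain, nc, 12)
  tavg <- (tmin + tmax) / 2

  # 12 wrap-around quarters: quarter q = months q, q+1, q+2 (mod 12)
  qsum <- function(m) {
    sapply(1:12, function(q) rowSums(m[, ((q - 1):(q + 1)) %% 12 + 1, drop = FALSE]))
  }
  qt <- qsum(tavg) / 3      # quarter mean temperature [cell, 12]
  qp <- qsum(prec)          # quarter precipitation sum

  first_max <- function(m) max.col(m, ties.method = "first")
  first_min <- function(m) max.col(-m, ties.method = "first")
  pick <- function(m, q) m[cbind(seq_len(nrow(m)), q)]

  warmest <- first_max(qt); coldest <- first_min(qt)
  wettest <- first_max(qp); driest <- first_min(qp)

  b <- matrix(NA_real_, nc, 19)
  b[, 1] <- rowMeans(tavg)
  b[, 2] <- rowMeans(tmax - tmin)
  b[, 4] <- apply(tavg, 1, stats::sd) * 100
  b[, 5] <- apply(tmax, 1, max)
  b[, 6] <- apply(tmin, 1, min)
  b[, 7] <- b[, 5] - b[, 6]
  b[, 3] <- ifelse(b[, 7] > 0, b[, 2] / b[, 7] * 100, NA_real_)
  b[, 8] <- pick(qt, wettest)
  b[, 9] <- pick(qt, driest)
  b[, 10] <- pick(qt, warmest)
  b[, 11] <- pick(qt, coldest)
  b[, 12] <- rowSums(prec)
  b[, 13] <- apply(prec, 1, max)
  b[, 14] <- apply(prec, 1, min)
  pm <- rowMeans(prec)
  b[, 15] <- ifelse(pm > 0, apply(prec, 1, stats::sd) / pm * 100, 0)
  b[, 16] <- pick(qp, wettest)
  b[, 17] <- pick(qp, driest)
  b[, 18] <- pick(qp, warmest)
  b[, 19] <- pick(qp, coldest)

  layers <- array(b, c(nlat, nlon, 19),
                  dimnames = list(NULL, NULL, paste0("bio", 1:19)))
  layers[array(!grid$mask, c(nlat, nlon, 19))] <- NA_real_
  structure(list(lat = grid$lat, lon = grid$lon, layers = layers,
                 mask = grid$mask), class = "bioclim_grid")
}

#' @export
print.bioclim_grid <- function(x, ...) {
  cat("Bioclim grid:", length(x$lat), "x", length(x$lon), "cells, 19 layers\n")
  invisible(x)
}
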