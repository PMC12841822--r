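# Shared grid helpers: regular lat/lon axes, cell geometry, nodata handling.

EARTH_RADIUS_KM <- 6371

#' Spherical area of a regular lat/lon grid cell
#'
#' Area of the cell whose centre sits at `lat_center` and whose extent is
#' `dlat` by `dlon` degrees, using the exact spherical band formula
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_{top} - \sin\phi_{bottom})} on a
#' sphere of radius 6371 km. Cell edges are clipped at the poles.
#'
#' @param lat_center latitude of the cell centre, degrees in \[-90, 90\].
#' @param dlat,dlon cell extent in degrees (latitude, longitude).
#' @return cell area in km^2; vectorised over `lat_center`.
#' @examples
#' cell_area(0, 1, 1)       # equatorial 1-degree cell, ~12364 km^2
#' cell_area(60, 1, 1)      # ~half the equatorial area
#' @export
cell_area <- function(lat_center, dlat, dlon) {
  stopifnot(all(is.finite(lat_center)), all(abs(lat_center) <= 90),
            dlat >= 0, dlon >= 0)
  top <- pmin(90, lat_center + dlat / 2) * pi / 180
  bot <- pmax(-90, lat_center - dlat / 2) * pi / 180
  EARTH_RADIUS_KM^2 * (dlon * pi / 180) * (sin(top) - sin(bot))
}

# Matrix of per-cell areas (km^2) for an object carrying $lat / $lon axes.
cell_area_matrix <- function(grid) {
  dlat <- axis_step(grid$lat)
  dlon <- axis_step(grid$lon)
  a <- cell_area(grid$lat, dlat, dlon)
  matrix(a, nrow = length(grid$lat), ncol = length(grid$lon))
}

axis_step <- function(axis) {
  if (length(axis) < 2) stop("axis needs at least two coordinates")
  d <- diff(axis)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    stop("axis must be strictly increasing with a constant step")
  }
  d[1]
}

check_axes <- function(lat, lon) {
  axis_step(lat)
  axis_step(lon)
  if (any(lat < -90 | lat > 90)) stop("latitude axis outside [-90, 90]")
  if (any(lon < -180 | lon >= 180)) stop("longitude axis outside [-180, 180)")
  invisible(TRUE)
}

# Map lon/lat point coordinates to (row, col) cell indices; NA when a point
# falls outside the grid extent (cell-centre registration, half-open cells).
cell_index <- function(grid, lon, lat) {
  dlat <- axis_step(grid$lat)
  dlon <- axis_step(grid$lon)
  row <- floor((lat - (grid$lat[1] - dlat / 2)) / dlat) + 1
  col <- floor((lon - (grid$lon[1] - dlon / 2)) / dlon) + 1
  row[row < 1 | row > length(grid$lat)] <- NA_integer_
  col[col < 1 | col > length(grid$lon)] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grids are not co-registered (axes differ)")
  invisible(TRUE)
}
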