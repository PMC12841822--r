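# Occurrence records: ingestion, de-duplication, spatial rarefaction and
# pseudo-absence generation. Distances are great-circle (haversine) on a
# 6371 km sphere.

#' Occurrence record set
#'
#' A data frame of georeferenced records with columns `lon`, `lat`,
#' `label` (`"presence"` or `"pseudo_absence"`) and `source_id`.
#'
#' @param lon,lat coordinates, degrees; `lon` in \[-180, 180), `lat` in
#'   \[-90, 90\].
#' @param label record class, recycled.
#' @param source_id provenance tag, recycled.
#' @return an object of classes `occurrence_set` and `data.frame`.
#' @export
occurrence_set <- function(lon, lat, label = "presence", source_id = NA_character_) {
  bad <- which(lon < -180 | lon >= 180 | lat < -90 | lat > 90 |
                 !is.finite(lon) | !is.finite(lat))
  if (length(bad)) {
    stop(sprintf("record %d has coordinates out of range (lon=%g, lat=%g)",
                 bad[1], lon[bad[1]], lat[bad[1]]))
  }
  label <- rep_len(as.character(label), length(lon))
  if (!all(label %in% c("presence", "pseudo_absence"))) {
    stop("label must be 'presence' or 'pseudo_absence'")
  }
  structure(data.frame(lon = lon, lat = lat, label = label,
                       source_id = rep_len(as.character(source_id), length(lon)),
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

#' Read occurrences from CSV
#'
#' Accepts the package's four-column format (`lon, lat, label, source_id`)
#' or a presence-only two-column table (`lon, lat`), in which case `label`
#' defaults to `"presence"`.
#'
#' @param path CSV file path.
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(d))) {
    stop("occurrence CSV needs 'lon' and 'lat' columns")
  }
  occurrence_set(d$lon, d$lat,
                 label = if ("label" %in% names(d)) d$label else "presence",
                 source_id = if ("source_id" %in% names(d)) d$source_id else NA)
}

#' Write occurrences to CSV
#'
#' @param x an [occurrence_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove duplicate occurrence records
#'
#' Records whose coordinates agree to `digits` decimal degrees (default
#' 1e-4 degrees) and share a label are collapsed to the first record, in
#' stable input order; the first record's original coordinates are kept.
#'
#' @param x an [occurrence_set()].
#' @param digits rounding used for the duplicate test (default 4).
#' @return the deduplicated [occurrence_set()].
#' @export
dedupe_occurrences <- function(x, digits = 4) {
  stopifnot(inherits(x, "occurrence_set"))
  key <- paste(round(x$lon, digits), round(x$lat, digits), x$label)
  x[!duplicated(key), , drop = FALSE]
}

#' Spatially rarefy occurrence records
#'
#' Greedy thinning in input order: a record is kept if and only if it lies
#' at least `min_distance_km` (great-circle) from every previously kept
#' record. Idempotent; `min_distance_km = 0` is the identity.
#'
#' @param x an [occurrence_set()].
#' @param min_distance_km minimum pairwise distance to enforce, km.
#' @return the thinned [occurrence_set()].
#' @export
rarefy_occurrences <- function(x, min_distance_km) {
  stopifnot(inherits(x, "occurrence_set"))
  if (min_distance_km < 0) stop("min_distance_km must be non-negative")
  n <- nrow(x)
  if (n <= 1 || min_distance_km == 0) return(x)
  keep <- logical(n)
  keep[1] <- TRUE
  for (i in 2:n) {
    kept <- which(keep)
    d <- geosphere::distHaversine(cbind(x$lon[i], x$lat[i]),
                                  cbind(x$lon[kept], x$lat[kept]),
                                  r = EARTH_RADIUS_KM * 1000)
    keep[i] <- all(d >= min_distance_km * 1000)
  }
  x[keep, , drop = FALSE]
}

#' Generate pseudo-absence records
#'
#' Draws `n` points uniformly over the valid cells of a grid (jittered
#' within the cell), rejecting any draw closer than `buffer_km` to a
#' presence record. Deterministic for a fixed `seed`. Fails after
#' `10000 * n` rejected draws, which signals an infeasible buffer.
#'
#' @param grid any grid object with `lat`, `lon` and a logical `mask`
#'   (e.g. a [climate_grid()]).
#' @param presences an [occurrence_set()] of presences to buffer against.
#' @param n number of pseudo-absences to place.
#' @param buffer_km exclusion radius around every presence (default 50).
#' @param seed integer RNG seed.
#' @return an [occurrence_set()] of `n` records labelled `pseudo_absence`.
#' @export
generate_pseudo_absences <- function(grid, presences, n, buffer_km = 50,
                                     seed = 1L) {
  stopifnot(n >= 1)
  valid <- which(grid$mask, arr.ind = TRUE)
  if (nrow(valid) == 0) stop("grid has no valid cells")
  dlat <- axis_step(grid$lat); dlon <- axis_step(grid$lon)
  pres_xy <- cbind(presences$lon, presences$lat)
  set.seed(seed)
  out_lon <- numeric(0); out_lat <- numeric(0)
  draws <- 0L; limit <- 10000 * n
  while (length(out_lon) < n) {
    batch <- min(4L * n, limit - draws)
    if (batch <= 0) {
      stop("could not place ", n, " pseudo-absences after ", limit,
           " draws; buffer_km is likely infeasible for this extent")
    }
    draws <- draws + batch
    i <- sample(nrow(valid), batch, replace = TRUE)
    lon <- grid$lon[valid[i, 2]] + stats::runif(batch, -dlon / 2, dlon / 2)
    lat <- grid$lat[valid[i, 1]] + stats::runif(batch, -dlat / 2, dlat / 2)
    lat <- pmin(90, pmax(-90, lat))
    lon <- ((lon + 180) %% 360) - 180
    if (nrow(pres_xy)) {
      ok <- vapply(seq_len(batch), function(j) {
        d <- geosphere::distHaversine(c(lon[j], lat[j]), pres_xy,
                                      r = EARTH_RADIUS_KM * 1000)
        all(d >= buffer_km * 1000)
      }, TRUE)
    } else ok <- rep(TRUE, batch)
    out_lon <- c(out_lon, lon[ok]); out_lat <- c(out_lat, lat[ok])
  }
  occurrence_set(out_lon[seq_len(n)], out_lat[seq_len(n)],
                 label = "pseudo_absence", source_id = "pseudo")
}
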