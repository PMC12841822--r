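# Natural-breaks classification, host masking, change maps and
# latitude-weighted area accounting.

SUIT_LABELS <- c("unsuitable", "very_low", "low", "medium", "high")

#' Jenks natural breaks
#'
#' Exact natural-breaks optimisation by dynamic programming over the sorted
#' values: the partition of the data into `k` contiguous classes minimising
#' the total within-class sum of squared deviations. Ties are broken toward
#' the lower break. Returns the `k - 1` interior break values, each the
#' smallest value of the class above it, so classification with half-open
#' intervals `[b_i, b_{i+1})` reproduces the optimal partition.
#'
#' For inputs longer than `max_n` the DP runs on a deterministic
#' evenly-spaced subsample of the sorted values (quantile skeleton), the
#' standard practice for classifying large rasters.
#'
#' @param values numeric vector with at least `k` distinct finite values.
#' @param k number of classes (default 5).
#' @param max_n largest problem size solved exactly (default 3000).
#' @return increasing numeric vector of `k - 1` breaks.
#' @export
jenks_breaks <- function(values, k = 5, max_n = 3000) {
  x <- sort(values[is.finite(values)])
  if (length(unique(x)) < k) {
    stop("need at least ", k, " distinct finite values for ", k, " classes")
  }
  if (length(x) > max_n) {
    x <- x[unique(round(seq(1, length(x), length.out = max_n)))]
    if (length(unique(x)) < k) stop("subsample lost too many distinct values")
  }
  n <- length(x)
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  s1p <- c(0, s1); s2p <- c(0, s2)   # prefix sums shifted by one
  # D[c, i]: minimal cost of splitting x[1..i] into c classes
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)    # start index of the last class
  D[1, ] <- s2 - s1^2 / seq_len(n)
  for (c in 2:k) {
    for (i in c:n) {
      j <- c:i                       # candidate start of class c
      ssq_tail <- (s2[i] - s2p[j]) - (s1[i] - s1p[j])^2 / (i - j + 1)
      cost <- D[c - 1, j - 1] + ssq_tail
      best <- which.min(cost)        # first minimum -> lowest break
      D[c, i] <- cost[best]
      B[c, i] <- j[best]
    }
  }
  breaks <- numeric(k - 1)
  i <- n
  for (c in k:2) {
    breaks[c - 1] <- x[B[c, i]]
    i <- B[c, i] - 1
  }
  breaks
}

#' Classify a suitability raster into five levels
#'
#' Applies natural breaks (computed from the raster's finite values when
#' `breaks` is not given) with half-open intervals: a cell with value below
#' the first break is `unsuitable`; a value equal to a break belongs to the
#' class above it. Nodata propagates; cells flagged by [apply_mask()] are
#' classified `unsuitable`.
#'
#' @param suitability a `suitability_raster` (see [predict.sdm_rf()]) or
#'   any grid object with a `prob` (or `ei`) matrix.
#' @param breaks increasing numeric vector of `k - 1` interior breaks;
#'   computed by [jenks_breaks()] when `NULL`.
#' @param k number of classes when computing breaks (default 5).
#' @return an object of class `classified_raster`: `lat`, `lon`, integer
#'   `codes` matrix (0 = unsuitable .. 4 = high), `breaks`, `labels`.
#' @export
classify_raster <- function(suitability, breaks = NULL, k = 5) {
  vals <- if (!is.null(suitability$prob)) suitability$prob else suitability$ei
  if (is.null(vals)) stop("no 'prob' or 'ei' values to classify")
  if (is.null(breaks)) breaks <- jenks_breaks(vals, k = k)
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
  codes <- matrix(NA_integer_, nrow(vals), ncol(vals))
  ok <- !is.na(vals)
  codes[ok] <- rowSums(outer(vals[ok], breaks, ">=" ))
  masked <- attr(suitability, "masked")
  if (!is.null(masked)) codes[masked & is.na(vals)] <- 0L
  structure(list(lat = suitability$lat, lon = suitability$lon,
                 codes = codes, breaks = breaks,
                 labels = SUIT_LABELS[seq_len(length(breaks) + 1)]),
            class = "classified_raster")
}

#' @export
print.classified_raster <- function(x, ...) {
  cat("Classified raster (", paste(x$labels, collapse = "/"), ")\n", sep = "")
  cat("  breaks:", paste(signif(x$breaks, 4), collapse = ", "), "\n")
  tab <- table(factor(x$codes, levels = seq_along(x$labels) - 1, labels = x$labels))
  print(tab)
  invisible(x)
}

#' Host-presence mask from an EI grid
#'
#' 1 where the host model gives EI > 0, 0 where EI = 0; nodata propagates.
#'
#' @param ei an `ei_grid`/[climex_run()] object.
#' @return a `binary_mask` object with a 0/1 `values` matrix.
#' @export
host_mask <- function(ei) {
  v <- ei$ei
  m <- matrix(NA_integer_, nrow(v), ncol(v))
  m[!is.na(v)] <- as.integer(v[!is.na(v)] > 0)
  structure(list(lat = ei$lat, lon = ei$lon, values = m),
            class = "binary_mask")
}

#' Restrict a suitability raster to a binary mask
#'
#' Cells where the mask is 0 lose their suitability value (they classify as
#' `unsuitable` downstream); cells where the mask is 1 are unchanged.
#'
#' @param suitability a `suitability_raster`.
#' @param mask a [host_mask()] result on the same grid.
#' @return the masked `suitability_raster`, carrying a `masked` attribute
#'   used by [classify_raster()].
#' @export
apply_mask <- function(suitability, mask) {
  stop_if_grid_mismatch(suitability, mask)
  out <- suitability
  drop <- !is.na(mask$values) & mask$values == 0
  out$prob[drop] <- NA_real_
  prev <- attr(suitability, "masked")
  if (is.null(prev)) prev <- matrix(FALSE, nrow(drop), ncol(drop))
  attr(out, "masked") <- prev | drop
  out
}

#' Ordinal difference map between two classified rasters
#'
#' Per cell: future class code minus current class code, in \[-4, 4\].
#' Both rasters must share the grid and class coding.
#'
#' @param current,future [classify_raster()] results.
#' @return a grid object with a `diff` matrix.
#' @export
difference_map <- function(current, future) {
  stop_if_grid_mismatch(current, future)
  if (!identical(current$labels, future$labels)) {
    stop("rasters use different class codings")
  }
  structure(list(lat = current$lat, lon = current$lon,
                 diff = future$codes - current$codes),
            class = "difference_map")
}

#' Percent change between two quantities
#'
#' `(future - current) / current * 100`, optionally rounded.
#'
#' @param current,future the two values (vectorised).
#' @param digits optional rounding.
#' @return percent change.
#' @export
percent_change <- function(current, future, digits = NULL) {
  p <- (future - current) / current * 100
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Per-region habitat-area accounting across two epochs
#'
#' Sums spherical cell areas per region and suitability class for two
#' classified rasters, reports "suitable" totals (classes at or above
#' `min_class`, default everything above `unsuitable`) and the percent
#' change per region. Areas are reported in 1e4 km^2.
#'
#' @param current,future [classify_raster()] results on the same grid.
#' @param regions a region labelling: integer matrix (0 = no region) as
#'   produced by [make_region_masks()], or a list of disjoint logical
#'   matrices.
#' @param min_class lowest class counted as suitable (default 1 =
#'   `very_low`).
#' @return an object of class `area_report`: data frame `by_class`
#'   (region x class x epoch areas), data frame `totals` with suitable
#'   areas and `pct_change` per region plus a `global` row.
#' @export
area_report <- function(current, future, regions, min_class = 1) {
  stop_if_grid_mismatch(current, future)
  if (is.list(regions) && !is.matrix(regions)) {
    lab <- matrix(0L, length(current$lat), length(current$lon))
    for (i in seq_along(regions)) {
      ri <- regions[[i]]
      if (any(lab[ri] != 0)) stop("region masks overlap")
      lab[ri] <- i
    }
    regions <- lab
  }
  if (!all(dim(regions) == dim(current$codes))) {
    stop("region labelling does not match the raster grid")
  }
  area <- cell_area_matrix(current) / 1e4   # 1e4 km^2
  nreg <- max(regions)
  labels <- current$labels
  rows <- list()
  totals <- list()
  for (r in seq_len(nreg)) {
    in_r <- regions == r
    for (ep in c("current", "future")) {
      codes <- if (ep == "current") current$codes else future$codes
      for (cl in seq_along(labels) - 1) {
        a <- sum(area[in_r & !is.na(codes) & codes == cl])
        rows[[length(rows) + 1]] <- data.frame(
          region = r, epoch = ep, class = labels[cl + 1], area = a)
      }
    }
    suit <- function(codes) sum(area[in_r & !is.na(codes) & codes >= min_class])
    a_cur <- suit(current$codes); a_fut <- suit(future$codes)
    totals[[r]] <- data.frame(region = as.character(r),
                              current = a_cur, future = a_fut,
                              pct_change = percent_change(a_cur, a_fut))
  }
  by_class <- do.call(rbind, rows)
  totals <- do.call(rbind, totals)
  g_cur <- sum(totals$current); g_fut <- sum(totals$future)
  totals <- rbind(totals, data.frame(region = "global", current = g_cur,
                                     future = g_fut,
                                     pct_change = percent_change(g_cur, g_fut)))
  structure(list(by_class = by_class, totals = totals,
                 min_class = min_class, units = "1e4 km^2"),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("Habitat area report (areas in 1e4 km^2; suitable = classes >=",
      x$min_class, ")\n")
  t <- x$totals
  t$current <- round(t$current, 2); t$future <- round(t$future, 2)
  t$pct_change <- ifelse(t$region == "global", round(t$pct_change, 2),
                         round(t$pct_change, 1))
  print(t, row.names = FALSE)
  invisible(x)
}

#' Write an area report to JSON
#'
#' @param x an `area_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_area_report_json <- function(x, path) {
  jsonlite::write_json(list(units = x$units, min_class = x$min_class,
                            by_class = x$by_class, totals = x$totals),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
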