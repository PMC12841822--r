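# Small in-code fixtures shared across the suite. Everything is generated
# deterministically; nothing is read from disk.

# A climate grid where every cell has the same 12-month cycle.
uniform_climate <- function(tmin, tmax, rain, rh = 60, nlat = 2, nlon = 2,
                            lat0 = 10, lon0 = 10, step = 2) {
  lat <- lat0 + step * (seq_len(nlat) - 1)
  lon <- lon0 + step * (seq_len(nlon) - 1)
  rep12 <- function(v) {
    v <- rep_len(v, 12)
    array(rep(v, each = nlat * nlon), c(nlat, nlon, 12))
  }
  climate_grid(lat, lon, rep12(tmin), rep12(tmax), rep12(rain),
               rep12(rh), rep12(rh))
}

# A small noisy synthetic world used where full 2-degree resolution is
# unnecessary.
small_world_spec <- function(seed = 7) {
  world_spec(nlat = 30, nlon = 60, seed = seed)
}

# Constructed favourable weekly forcing: mild temperatures inside the
# optimum and a wet/dry seasonal rainfall cycle with a small net annual
# deficit, so the moisture orbit is unique (it clamps dry briefly) and
# sweeps through the optimum range twice a year.
favourable_weekly <- function() {
  list(tavg = rep(17, 52), rain = rep(c(20, 6), each = 26))
}

# Brute-force Jenks oracle: enumerate every split of the sorted values
# into k contiguous classes and return the minimal within-class SSE and
# the first (lowest-break) argmin partition.
jenks_oracle <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssq <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1, k - 1)
  best <- Inf; best_breaks <- NULL
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (c in seq_len(k)) tot <- tot + ssq(x[(cuts[c] + 1):cuts[c + 1]])
    if (tot < best - 1e-12) {
      best <- tot
      best_breaks <- x[splits[, j] + 1]
    }
  }
  list(sse = best, breaks = best_breaks)
}

# Within-class SSE realised by a set of interior breaks (half-open rule).
breaks_sse <- function(values, breaks) {
  x <- sort(values)
  cls <- rowSums(outer(x, breaks, ">="))
  sum(tapply(x, cls, function(v) sum((v - mean(v))^2)))
}
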