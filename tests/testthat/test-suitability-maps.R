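test_that("natural breaks match brute-force enumeration on small sets", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), k = 2)
  expect_equal(b, 10)   # the gap between the two clusters

  # k equal to the number of distinct values: every value its own class
  b2 <- jenks_breaks(c(4, 8, 15), k = 3)
  expect_equal(b2, c(8, 15))

  expect_error(jenks_breaks(c(1, 1, 2), k = 3), "distinct")

  # exhaustive-partition oracle over random sets
  set.seed(11)
  cases <- list(list(n = 20, k = 2), list(n = 25, k = 3), list(n = 30, k = 4),
                list(n = 40, k = 5), list(n = 24, k = 6), list(n = 60, k = 3))
  for (cs in cases) {
    x <- round(runif(cs$n, 0, 100), 1)
    got <- jenks_breaks(x, k = cs$k)
    oracle <- jenks_oracle(x, cs$k)
    expect_equal(breaks_sse(x, got), oracle$sse, tolerance = 1e-9)
    expect_equal(got, oracle$breaks)
  }
})

test_that("subsampled breaks approximate the exact optimum on large inputs", {
  set.seed(12)
  x <- c(rnorm(2000, 0), rnorm(2000, 8), rnorm(2000, 16))
  fast <- jenks_breaks(x, k = 3, max_n = 1500)
  exact <- jenks_breaks(x, k = 3, max_n = length(x))
  expect_lt(max(abs(fast - exact)), 0.5)
})

test_that("classification uses half-open intervals with an unsuitable floor", {
  sr <- structure(list(lat = c(10, 12), lon = c(0, 2),
                       prob = matrix(c(0.05, 0.2, 0.45, 0.9), 2, 2)),
                  class = "suitability_raster")
  cl <- classify_raster(sr, breaks = c(0.1, 0.3, 0.5, 0.8))
  expect_equal(cl$codes, matrix(c(0L, 1L, 2L, 4L), 2, 2))
  # boundary value goes to the class above
  sr$prob[1, 1] <- 0.3
  cl2 <- classify_raster(sr, breaks = c(0.1, 0.3, 0.5, 0.8))
  expect_equal(cl2$codes[1, 1], 2L)
  expect_error(classify_raster(sr, breaks = c(0.5, 0.1)), "increasing")

  # hand-tallied histogram on a known raster
  set.seed(13)
  vals <- matrix(runif(400), 20, 20)
  sr3 <- structure(list(lat = seq(1, 39, 2), lon = seq(1, 39, 2), prob = vals),
                   class = "suitability_raster")
  brk <- c(0.2, 0.4, 0.6, 0.8)
  cl3 <- classify_raster(sr3, breaks = brk)
  expect_equal(as.vector(table(cl3$codes)),
               as.vector(table(rowSums(outer(as.vector(vals), brk, ">=")))))
})

test_that("the host mask is a strict EI > 0 indicator", {
  ei <- structure(list(lat = c(0, 2), lon = c(0, 2),
                       ei = matrix(c(0, 0.001, 50, NA), 2, 2)),
                  class = "ei_grid")
  hm <- host_mask(ei)
  expect_equal(hm$values[1, 1], 0L)
  expect_equal(hm$values[2, 1], 1L)
  expect_equal(hm$values[1, 2], 1L)
  expect_true(is.na(hm$values[2, 2]))
})

test_that("masking removes suitability exactly where the mask is zero", {
  lat <- c(0, 2); lon <- c(0, 2)
  sr <- structure(list(lat = lat, lon = lon,
                       prob = matrix(c(0.9, 0.8, 0.7, 0.6), 2, 2)),
                  class = "suitability_raster")
  ones <- structure(list(lat = lat, lon = lon, values = matrix(1L, 2, 2)),
                    class = "binary_mask")
  expect_equal(apply_mask(sr, ones)$prob, sr$prob)

  zeros <- ones; zeros$values[] <- 0L
  expect_true(all(is.na(apply_mask(sr, zeros)$prob)))

  checker <- ones; checker$values <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  masked <- apply_mask(sr, checker)
  expect_equal(masked$prob[1, 1], 0.9)
  expect_equal(masked$prob[2, 2], 0.6)
  expect_true(is.na(masked$prob[2, 1]) && is.na(masked$prob[1, 2]))
  # apply_mask never increases suitability
  expect_true(all(is.na(masked$prob) | masked$prob <= sr$prob))
  # masked cells classify as unsuitable, not nodata
  cl <- classify_raster(masked, breaks = c(0.1, 0.3, 0.5, 0.8))
  expect_equal(cl$codes[2, 1], 0L)

  other <- structure(list(lat = c(10, 12), lon = lon, values = matrix(1L, 2, 2)),
                     class = "binary_mask")
  expect_error(apply_mask(sr, other), "co-registered")
})

test_that("difference maps are ordinal future-minus-current", {
  mk <- function(codes) structure(list(lat = c(0, 2), lon = c(0, 2),
                                       codes = codes, breaks = 1:4,
                                       labels = climexrf:::SUIT_LABELS),
                                  class = "classified_raster")
  cur <- mk(matrix(c(0L, 1L, 4L, 2L), 2, 2))
  expect_true(all(difference_map(cur, cur)$diff == 0))
  fut <- mk(matrix(c(4L, 0L, 0L, 3L), 2, 2))
  d <- difference_map(cur, fut)$diff
  expect_equal(d, matrix(c(4L, -1L, -4L, 1L), 2, 2))
})

test_that("spherical cell areas integrate to the globe and scale with latitude", {
  lat <- seq(-89.5, 89.5, 1)
  total <- sum(cell_area(lat, 1, 1)) * 360
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-3)
  expect_equal(cell_area(0, 1, 0), 0)
  expect_equal(cell_area(60, 1, 1) / cell_area(0, 1, 1), 0.5, tolerance = 0.01)
})

test_that("percent change reproduces printed worked examples and reciprocity", {
  expect_equal(percent_change(590.59, 748.19, digits = 1), 26.7)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(8616, 10165, digits = 2), 17.98)
  p1 <- percent_change(83, 112); p2 <- percent_change(112, 83)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1)
})

test_that("area accounting conserves totals across classes and regions", {
  w <- make_synthetic_climate(small_world_spec())
  run_cur <- climex_run(w)
  run_fut <- climex_run(warm_future(w, 2))
  cl_cur <- classify_raster(structure(run_cur, class = "ei_grid"))
  cl_fut <- classify_raster(structure(run_fut, class = "ei_grid"),
                            breaks = cl_cur$breaks)
  regions <- make_region_masks(w, 3)
  rep <- area_report(cl_cur, cl_fut, regions)

  # class sums reconcile with suitable + unsuitable totals per region
  bc <- rep$by_class
  for (r in 1:3) {
    cur_cls <- bc[bc$region == r & bc$epoch == "current", ]
    suit <- sum(cur_cls$area[cur_cls$class != "unsuitable"])
    expect_equal(suit, rep$totals$current[rep$totals$region == as.character(r)],
                 tolerance = 1e-9)
  }
  # disjoint regions sum to the global total
  g <- rep$totals[rep$totals$region == "global", ]
  expect_equal(sum(rep$totals$current[rep$totals$region != "global"]),
               g$current, tolerance = 1e-9)
  expect_equal(g$pct_change, percent_change(g$current, g$future))

  # overlapping masks are rejected
  m1 <- regions > 0; m2 <- regions == 1
  expect_error(area_report(cl_cur, cl_fut, list(m1, m2)), "overlap")
})
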