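p_default <- climex_params()

test_that("temperature index is a trapezoid over the fitted thresholds", {
  expect_equal(temperature_index(-20, p_default), 0)     # below DV0
  expect_equal(temperature_index(-15, p_default), 0)     # at DV0
  expect_equal(temperature_index(17, p_default), 1)      # inside [DV1, DV2]
  expect_equal(temperature_index(13.6, p_default), 1)
  expect_equal(temperature_index(20.4, p_default), 1)
  expect_equal(temperature_index(-0.7, p_default), 0.5)  # midpoint of rise
  expect_equal(temperature_index(45, p_default), 0)      # at DV3
  expect_equal(temperature_index(32.7, p_default), 0.5)  # midpoint of fall
  # bounded, piecewise-linear, exactly 0/1 outside/inside on a dense scan
  t <- seq(-40, 60, by = 0.25)
  ti <- temperature_index(t, p_default)
  expect_true(all(ti >= 0 & ti <= 1))
  expect_true(all(ti[t <= -15 | t >= 45] == 0))
  expect_true(all(ti[t >= 13.6 & t <= 20.4] == 1))
})

test_that("moisture index is a trapezoid over the soil-moisture thresholds", {
  expect_equal(moisture_index(2.0, p_default), 0)        # above SM3
  expect_equal(moisture_index(0.7, p_default), 1)        # inside [SM1, SM2]
  expect_equal(moisture_index(0.275, p_default), 0.5)    # midpoint of rise
  expect_equal(moisture_index(0.05, p_default), 0)
  expect_equal(moisture_index(1.2, p_default), 0.5)      # midpoint of fall
})

test_that("soil-moisture bucket update follows the stated balance", {
  # rain equal to evapotranspiration leaves the state unchanged
  expect_equal(soil_moisture_step(0.6, rain_week = 0.8 * 15, t_week = 15), 0.6)
  # lower clamp
  expect_equal(soil_moisture_step(0, rain_week = 0, t_week = 30), 0)
  # hand evaluation of the balance
  expect_equal(soil_moisture_step(0.5, 30, 10, capacity_mm = 100), 0.72)
  # upper clamp at sm_cap
  expect_equal(soil_moisture_step(1.95, 200, 0, capacity_mm = 100), 2)
  expect_error(soil_moisture_step(0.5, -1, 10), "non-negative")
})

test_that("annual growth index is the scaled mean of weekly growth", {
  expect_equal(annual_growth_index(rep(1, 52)), 100)
  expect_equal(annual_growth_index(rep(0, 52)), 0)
  expect_equal(annual_growth_index(rep(c(1, 0), each = 26)), 50)
  expect_error(annual_growth_index(rep(1, 51)), "52")
})

test_that("stress accumulation is linear in exceedance and caps at 100", {
  mild_t <- rep(10, 52); mid_m <- rep(0.7, 52)
  expect_equal(stress_indices(mild_t, mid_m, p_default),
               c(CS = 0, HS = 0, DS = 0, WS = 0))
  # 10 weeks at -16 degC: 0.125 * 1 * 10 = 1.25, capped at 1 -> CS = 100
  t_cold <- mild_t; t_cold[1:10] <- -16
  expect_equal(stress_indices(t_cold, mid_m, p_default)[["CS"]], 100)
  # 5 weeks at moisture 1.6: 0.012 * 0.1 * 5 = 0.006 -> WS = 0.6
  m_wet <- mid_m; m_wet[1:5] <- 1.6
  expect_equal(stress_indices(mild_t, m_wet, p_default)[["WS"]], 0.6)
})

test_that("the ecoclimatic index combines growth and stress multiplicatively", {
  expect_equal(ecoclimatic_index(50, c(0, 0, 0, 0)), 50)
  expect_equal(ecoclimatic_index(80, c(100, 0, 0, 0)), 0)
  expect_equal(ecoclimatic_index(80, c(50, 0, 0, 0)), 40)
  # monotone non-increasing in each stress, non-decreasing in growth
  for (i in 1:4) {
    s <- rep(20, 4); s_hi <- s; s_hi[i] <- 60
    expect_lt(ecoclimatic_index(70, s_hi), ecoclimatic_index(70, s))
  }
  expect_gt(ecoclimatic_index(80, rep(20, 4)), ecoclimatic_index(40, rep(20, 4)))
})

test_that("single-cell engine gives high EI under favourable forcing", {
  fw <- favourable_weekly()
  cell <- climex_cell(fw$tavg, fw$rain)
  expect_gt(cell$EI, 30)
  expect_true(all(cell$GIw == cell$TIw * cell$MIw))
  expect_lte(cell$EI, cell$GIA)
})

test_that("grid engine zeroes polar and desert cells and bounds EI", {
  polar <- uniform_climate(tmin = -25, tmax = -17, rain = 30)
  run_p <- climex_run(polar)
  expect_true(all(run_p$ei == 0))

  desert <- uniform_climate(tmin = 22, tmax = 38, rain = 0)
  run_d <- climex_run(desert)
  expect_true(all(run_d$ei == 0))

  w <- make_synthetic_climate(small_world_spec())
  run_w <- climex_run(w)
  ok <- !is.na(run_w$ei)
  expect_true(all(run_w$ei[ok] >= 0 & run_w$ei[ok] <= 100))
  expect_true(all(run_w$ei[ok] <= run_w$gia[ok] + 1e-9))
})

test_that("uniform heating above the heat-stress threshold kills all cells", {
  w <- make_synthetic_climate(small_world_spec())
  hot <- warm_future(w, delta_t = 90)   # every weekly temperature > 45 degC
  run <- climex_run(hot)
  expect_true(all(run$ei[!is.na(run$ei)] == 0))
})

test_that("the stationary moisture orbit is periodic and attracts any start", {
  w <- make_synthetic_climate(world_spec(nlat = 8, nlon = 10, seed = 2))
  wk <- monthly_to_weekly(w)
  nc <- 8 * 10
  tavg <- matrix(wk$tavg, nc, 52); rain <- matrix(wk$rain, nc, 52)
  M <- climexrf:::spinup_moisture(rain, tavg)
  net <- (rain - pmax(0.8 * tavg, 0)) / 100

  # exact periodicity: one more year starting from the orbit reproduces it
  m <- M[, 52]
  M2 <- matrix(NA_real_, nc, 52)
  for (wkk in 1:52) {
    m <- pmin(2, pmax(m + net[, wkk], 0))
    M2[, wkk] <- m
  }
  expect_lt(max(abs(M2 - M)), 1e-12)

  # independence of the initial state: iterating the weekly balance from a
  # dry and a saturated start converges onto the same orbit
  iterate <- function(init, cycles) {
    m <- rep(init, nc)
    for (k in seq_len(cycles)) for (wkk in 1:52) {
      m <- pmin(2, pmax(m + net[, wkk], 0))
    }
    m
  }
  expect_lt(max(abs(iterate(0, 30) - M[, 52])), 1e-6)
  expect_lt(max(abs(iterate(2, 30) - M[, 52])), 1e-6)
})

test_that("engine parameters survive a config-file round trip", {
  p <- climex_params(DV1 = 12, SM2 = 0.85)
  path <- withr::local_tempfile(fileext = ".conf")
  write_climex_params(p, path)
  p2 <- read_climex_params(path)
  expect_equal(unclass(p2), unclass(p))
  expect_error(climex_params(DV0 = 10, DV1 = 5), "DV0 <= DV1")
  expect_error(climex_params(SM1 = 0.9, SM2 = 0.5), "SM0 <= SM1")
})
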