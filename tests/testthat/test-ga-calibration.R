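# A small world shared by the calibration tests: coarse enough that a
# fitness evaluation is a few milliseconds.
ga_world <- local({
  w <- make_synthetic_climate(world_spec(nlat = 24, nlon = 48, seed = 21))
  f <- climexrf:::climex_forcing(w)
  list(climate = w, forcing = f, truth = climex_run(f))
})

test_that("fitness is coverage minus the weighted suitable-area fraction", {
  # a uniformly favourable 2x2 world with one nodata cell: 3 valid cells,
  # all suitable, both presences covered
  tmin <- array(12, c(2, 2, 12)); tmax <- array(22, c(2, 2, 12))
  # seasonal rain oscillating about the evapotranspiration demand keeps the
  # moisture bucket cycling through the optimum instead of hitting a clamp
  rain_m <- 59 + 25 * cos(2 * pi * (0:11) / 12)
  rain <- array(rep(rain_m, each = 4), c(2, 2, 12))
  rh <- array(60, c(2, 2, 12))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  g <- climate_grid(c(10, 12), c(10, 12), tmin, tmax, rain, rh, rh, mask = mask)
  occ <- occurrence_set(c(10, 10), c(10, 12))
  expect_equal(climex_fitness(climex_params(), occ, g, penalty_weight = 0),
               1)
  expect_equal(climex_fitness(climex_params(), occ, g, penalty_weight = 0.5),
               0.5)
  # parameters that zero EI everywhere score 0 (cold world below DV0)
  cold <- climate_grid(c(10, 12), c(10, 12), tmin - 60, tmax - 60, rain,
                       rh, rh, mask = mask)
  expect_equal(climex_fitness(climex_params(), occ, cold, penalty_weight = 0.5),
               0)
  expect_error(
    climex_fitness(climex_params(),
                   occurrence_set(10, 10, label = "pseudo_absence"), g),
    "presence")
})

test_that("parameter repair restores ordering and is idempotent", {
  b <- climexrf:::default_parameter_bounds()
  x <- unclass(climex_params())
  x["DV1"] <- 30; x["DV2"] <- 5            # disordered
  r <- climexrf:::repair_params(x, b)
  expect_true(all(diff(r[c("DV0", "DV1", "DV2", "DV3")]) >= 0))
  expect_identical(climexrf:::repair_params(r, b), r)
  # already-ordered vectors are untouched
  x2 <- unclass(climex_params())
  expect_identical(climexrf:::repair_params(x2, b), x2)
})

test_that("a degenerate GA returns the repaired initial individual", {
  occ <- sample_occurrences_from_ei(ga_world$truth, 30, seed = 2)
  cfg <- ga_config(population_size = 1, generations = 0, seed = 9)
  fit <- climex_fit(occ, ga_world$forcing, config = cfg)
  expect_s3_class(fit$parameters, "climex_params")
  expect_length(fit$fitness_trace, 1)
  # the individual obeys the ordering invariants by construction
  p <- coef(fit)
  expect_true(all(diff(p[c("DV0", "DV1", "DV2", "DV3")]) >= 0))
  expect_true(all(diff(p[c("SM0", "SM1", "SM2", "SM3")]) >= 0))
})

test_that("elitism makes the best objective non-decreasing and seeds reproduce", {
  occ <- sample_occurrences_from_ei(ga_world$truth, 60, seed = 3)
  cfg <- ga_config(population_size = 10, generations = 8, seed = 4)
  fit <- climex_fit(occ, ga_world$forcing, config = cfg)
  expect_true(all(diff(fit$fitness_trace) >= 0))
  fit2 <- climex_fit(occ, ga_world$forcing, config = cfg)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$fitness_trace, fit2$fitness_trace)

  # a different seed gives a similar (within 5%) final objective
  cfg3 <- ga_config(population_size = 10, generations = 8, seed = 5)
  fit3 <- climex_fit(occ, ga_world$forcing, config = cfg3)
  f1 <- tail(fit$fitness_trace, 1); f3 <- tail(fit3$fitness_trace, 1)
  expect_lt(abs(f1 - f3), 0.05 * max(abs(f1), abs(f3), 1))
})

test_that("held-out coverage and overprediction are reported on [0, 1]", {
  occ <- sample_occurrences_from_ei(ga_world$truth, 80, seed = 6)
  cfg <- ga_config(population_size = 12, generations = 10, seed = 7)
  fit <- climex_fit(occ, ga_world$forcing, config = cfg)
  expect_equal(fit$n_train, 60)   # 75% of 80
  expect_equal(fit$n_test, 20)
  for (v in c("train_coverage", "test_coverage", "overprediction")) {
    expect_gte(fit[[v]], 0); expect_lte(fit[[v]], 1)
  }
  # the returned parameters respect the declared bounds
  p <- coef(fit)
  for (nm in cfg$free) {
    b <- cfg$parameter_bounds[[nm]]
    expect_gte(p[[nm]], b[1]); expect_lte(p[[nm]], b[2])
  }
})

test_that("calibration on a coarse world recovers the suitable region", {
  occ <- sample_occurrences_from_ei(ga_world$truth, 120, seed = 8)
  cfg <- ga_config(population_size = 16, generations = 25, seed = 9)
  fit <- climex_fit(occ, ga_world$forcing, config = cfg)
  pred <- climex_run(ga_world$forcing, fit$parameters)
  a <- ga_world$truth$ei > 0; b <- pred$ei > 0
  expect_gte(sum(a & b) / sum(a | b), 0.7)
  expect_gte(fit$test_coverage, 0.9)
})
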