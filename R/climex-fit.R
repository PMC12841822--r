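# Genetic-algorithm calibration of the ecoclimatic engine against
# occurrence records. The search is a standard real-coded GA (tournament
# selection of size 2, uniform crossover, Gaussian mutation clipped to
# bounds, elitism) over a configurable subset of the physiological
# parameters, with an order-repair step that keeps the threshold groups
# (DV0..DV3, SM0..SM3) sorted.

default_parameter_bounds <- function() {
  list(DV0 = c(-30, 10), DV1 = c(0, 25), DV2 = c(10, 35), DV3 = c(30, 55),
       SM0 = c(0, 0.4), SM1 = c(0.1, 1), SM2 = c(0.4, 1.4), SM3 = c(0.8, 2),
       TTCS = c(-30, 5), THCS = c(-1, 0), TTHS = c(30, 55), THHS = c(0, 1),
       SMDS = c(0, 0.4), HDS = c(-1, 0), SMWS = c(0.8, 2.5), HWS = c(0, 1))
}

#' Configuration of the genetic-algorithm calibration
#'
#' @param population_size,generations GA size and length.
#' @param mutation_rate per-gene probability of a Gaussian mutation.
#' @param crossover_rate per-pair probability of uniform crossover.
#' @param parameter_bounds named list of `c(low, high)` per parameter;
#'   defaults cover physiologically plausible ranges.
#' @param seed integer RNG seed; the fit is deterministic given the seed.
#' @param train_fraction fraction of occurrences used for fitting; the rest
#'   are held out for the reported test coverage (default 0.75).
#' @param penalty_weight weight of the suitable-area penalty in the
#'   objective (default 0.3).
#' @param likelihood_weight weight of the point-process log-likelihood term
#'   added to the objective (default 0.25; see [climex_fit()]).
#' @param free character vector of parameters the GA may move; the rest stay
#'   at their values in the starting parameter set. Default frees the
#'   temperature and moisture growth thresholds and fixes the stress
#'   settings, mirroring how the stress parameters are anchored to
#'   literature values while the growth range is tuned to occurrences.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30, generations = 80,
                      mutation_rate = 0.2, crossover_rate = 0.9,
                      parameter_bounds = default_parameter_bounds(),
                      seed = 1L, train_fraction = 0.75,
                      penalty_weight = 0.3, likelihood_weight = 0.25,
                      free = c("DV0", "DV1", "DV2", "DV3",
                               "SM0", "SM1", "SM2", "SM3")) {
  stopifnot(population_size >= 1, generations >= 0,
            mutation_rate > 0, mutation_rate < 1,
            crossover_rate > 0, crossover_rate < 1,
            train_fraction > 0, train_fraction < 1,
            all(free %in% PARAM_NAMES))
  for (nm in names(parameter_bounds)) {
    b <- parameter_bounds[[nm]]
    if (length(b) != 2 || b[1] > b[2]) stop("infeasible bounds for ", nm)
  }
  if (!all(free %in% names(parameter_bounds))) {
    stop("every free parameter needs bounds")
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 parameter_bounds = parameter_bounds, seed = as.integer(seed),
                 train_fraction = train_fraction,
                 penalty_weight = penalty_weight,
                 likelihood_weight = likelihood_weight, free = free),
            class = "ga_config")
}

# Re-impose the ordering invariants on a raw parameter vector: clip to
# bounds, then sort each threshold group. Idempotent on ordered vectors.
repair_params <- function(x, bounds) {
  for (nm in names(x)) {
    b <- bounds[[nm]]
    if (!is.null(b)) x[nm] <- min(max(x[nm], b[1]), b[2])
  }
  x[c("DV0", "DV1", "DV2", "DV3")] <- sort(x[c("DV0", "DV1", "DV2", "DV3")])
  x[c("SM0", "SM1", "SM2", "SM3")] <- sort(x[c("SM0", "SM1", "SM2", "SM3")])
  x
}

#' Coverage-versus-area fitness of a parameter set
#'
#' `score = coverage - penalty_weight * suitable_area_fraction`, where
#' coverage is the fraction of presence records whose cell has EI > 0 and
#' the penalty is the area-weighted fraction of valid cells with EI > 0.
#' This encodes the calibration goal of maximising agreement between the
#' predicted suitable range and the known records while penalising
#' overprediction.
#'
#' @param p a [climex_params()].
#' @param occurrences an [occurrence_set()]; presence records are used.
#' @param climate a [climate_grid()] (or prebuilt forcing).
#' @param penalty_weight trade-off weight (default 0.3).
#' @return scalar score (at most 1).
#' @export
climex_fitness <- function(p, occurrences, climate, penalty_weight = 0.3) {
  forcing <- if (inherits(climate, "climex_forcing")) climate
             else climex_forcing(climate)
  ei <- forcing_indices(forcing, p)$ei
  occ_ei <- ei_at_occurrences(forcing, occurrences, ei)
  if (length(occ_ei) == 0) stop("no presence records fall on valid cells")
  coverage <- mean(occ_ei > 0)
  area_frac <- sum(forcing$area[ei > 0]) / sum(forcing$area)
  coverage - penalty_weight * area_frac
}

# EI values at the cells of the presence records (NA-dropping).
ei_at_occurrences <- function(forcing, occurrences, ei_valid) {
  pres <- occurrences[occurrences$label == "presence", , drop = FALSE]
  if (nrow(pres) == 0) stop("occurrence set has no presence records")
  rc <- cell_index(forcing, pres$lon, pres$lat)
  flat <- rc[, 1] + (rc[, 2] - 1) * length(forcing$lat)
  pos <- match(flat, forcing$valid)
  ei_valid[pos[!is.na(pos)]]
}

# GA objective: the coverage-area fitness plus a weighted point-process
# log-likelihood contrast, mean(log EI at presences) - log(area-weighted
# mean EI). The binary fitness alone cannot identify the optimum interval
# (DV1/DV2, SM1/SM2) because EI > 0 depends only on the outer thresholds;
# the likelihood term restores a gradient on the full EI surface.
ga_objective <- function(p, forcing, occ, penalty_weight, likelihood_weight) {
  idx <- forcing_indices(forcing, p)
  ei <- idx$ei
  occ_ei <- ei_at_occurrences(forcing, occ, ei)
  coverage <- mean(occ_ei > 0)
  area_frac <- sum(forcing$area[ei > 0]) / sum(forcing$area)
  score <- coverage - penalty_weight * area_frac
  if (likelihood_weight > 0) {
    # cell-mean normalisation: records are treated as draws of grid cells
    # with probability proportional to EI, so the likelihood contrast uses
    # the unweighted mean over valid cells
    eps <- 1e-3
    ll <- mean(log(pmax(occ_ei, eps))) - log(max(mean(ei), eps))
    score <- score + likelihood_weight * ll
  }
  score
}

#' Calibrate engine parameters to occurrence records
#'
#' Fits the free physiological parameters by a real-coded genetic algorithm.
#' Presence records are split into a training fraction used by the
#' objective and a held-out set used only for the reported test coverage.
#' The objective is the coverage-minus-area fitness of [climex_fitness()]
#' plus a weighted point-process log-likelihood contrast
#' (`mean log EI` at training presences minus `log` area-weighted mean EI),
#' which makes the optimum interval identifiable; set
#' `likelihood_weight = 0` in the config for the pure coverage-area
#' objective. Deterministic for a fixed `config$seed`.
#'
#' @param occurrences an [occurrence_set()] with >= 5 presence records on
#'   valid cells.
#' @param climate a [climate_grid()].
#' @param config a [ga_config()].
#' @param start a [climex_params()] supplying values of the non-free
#'   parameters and the centre of the initial population.
#' @return an object of class `climex_fit` with elements `parameters`
#'   (a [climex_params()]), `fitness_trace`, `train_coverage`,
#'   `test_coverage`, `overprediction`, `config`.
#' @export
climex_fit <- function(occurrences, climate, config = ga_config(),
                       start = climex_params()) {
  stopifnot(inherits(config, "ga_config"))
  forcing <- if (inherits(climate, "climex_forcing")) climate
             else climex_forcing(climate)
  pres <- occurrences[occurrences$label == "presence", , drop = FALSE]
  rc <- cell_index(forcing, pres$lon, pres$lat)
  on_grid <- !is.na(rc[, 1]) & !is.na(rc[, 2])
  pres <- pres[on_grid, , drop = FALSE]
  if (nrow(pres) < 5) stop("need at least 5 presence records on valid cells")

  set.seed(config$seed)
  n_train <- max(1, round(config$train_fraction * nrow(pres)))
  train_idx <- sample(nrow(pres), n_train)
  train <- pres[train_idx, , drop = FALSE]
  test <- pres[-train_idx, , drop = FALSE]

  free <- config$free
  bounds <- config$parameter_bounds
  base <- unclass(start)

  draw_individual <- function() {
    x <- base
    for (nm in free) {
      b <- bounds[[nm]]
      x[nm] <- stats::runif(1, b[1], b[2])
    }
    repair_params(x, bounds)
  }
  objective <- function(x) {
    ga_objective(x, forcing, train, config$penalty_weight,
                 config$likelihood_weight)
  }

  pop <- lapply(seq_len(config$population_size), function(i) draw_individual())
  fit <- vapply(pop, objective, 0)
  trace <- numeric(config$generations + 1)
  trace[1] <- max(fit)

  mut_sd <- vapply(free, function(nm) 0.1 * diff(bounds[[nm]]), 0)

  if (config$generations > 0) {
    for (gen in seq_len(config$generations)) {
      elite <- pop[[which.max(fit)]]
      tournament <- function() {
        i <- sample(config$population_size, 2)
        pop[[i[which.max(fit[i])]]]
      }
      children <- vector("list", config$population_size)
      children[[1]] <- elite
      k <- 2
      while (k <= config$population_size) {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < config$crossover_rate) {
          swap <- free[stats::runif(length(free)) < 0.5]
          tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
        }
        for (child in list(p1, p2)) {
          if (k > config$population_size) break
          mut <- free[stats::runif(length(free)) < config$mutation_rate]
          if (length(mut)) {
            child[mut] <- child[mut] + stats::rnorm(length(mut)) * mut_sd[mut]
          }
          children[[k]] <- repair_params(child, bounds)
          k <- k + 1
        }
      }
      pop <- children
      fit <- vapply(pop, objective, 0)
      # elitism: the carried-over elite guarantees a non-decreasing trace
      trace[gen + 1] <- max(fit)
    }
  }

  best <- pop[[which.max(fit)]]
  best_obj <- max(fit)
  # coordinate-wise local polish: the objective ridge along the optimum
  # interval is shallow, so the GA is finished with a deterministic grid
  # refinement of each free parameter at two shrinking scales
  for (width_frac in if (config$generations > 0) c(0.2, 0.05) else numeric(0)) {
    for (nm in free) {
      b <- bounds[[nm]]
      width <- width_frac * diff(b)
      for (cand in best[nm] + width * seq(-1, 1, length.out = 9)) {
        y <- best
        y[nm] <- cand
        y <- repair_params(y, bounds)
        obj_y <- objective(y)
        if (obj_y > best_obj) {
          best <- y
          best_obj <- obj_y
        }
      }
    }
  }
  if (config$generations > 0) trace <- c(trace, best_obj)
  best_p <- do.call(climex_params, as.list(best))
  ei <- forcing_indices(forcing, best_p)$ei
  occupied <- rep(FALSE, length(forcing$valid))
  rc <- cell_index(forcing, train$lon, train$lat)
  pos <- match(rc[, 1] + (rc[, 2] - 1) * length(forcing$lat), forcing$valid)
  occupied[pos[!is.na(pos)]] <- TRUE
  suitable <- ei > 0
  overpred <- if (any(suitable)) {
    sum(forcing$area[suitable & !occupied]) / sum(forcing$area[suitable])
  } else NA_real_
  cov_of <- function(set) {
    if (nrow(set) == 0) return(NA_real_)
    mean(ei_at_occurrences(forcing, set, ei) > 0)
  }

  structure(list(parameters = best_p, fitness_trace = cummax(trace),
                 train_coverage = cov_of(train), test_coverage = cov_of(test),
                 overprediction = overpred, config = config,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "climex_fit")
}

#' @export
coef.climex_fit <- function(object, ...) unclass(object$parameters)

#' @export
print.climex_fit <- function(x, ...) {
  cat("GA-calibrated ecoclimatic model\n")
  cat(sprintf("  best objective %.4f after %d generations (pop %d)\n",
              utils::tail(x$fitness_trace, 1), x$config$generations,
              x$config$population_size))
  cat(sprintf("  coverage: train %.3f (n=%d), test %.3f (n=%d)\n",
              x$train_coverage, x$n_train, x$test_coverage, x$n_test))
  invisible(x)
}

#' @export
summary.climex_fit <- function(object, ...) {
  print(object)
  cat("  overprediction (suitable area without training records):",
      round(object$overprediction, 3), "\n")
  cat("  fitted parameters:\n")
  print(unclass(object$parameters))
  invisible(object)
}

#' Predict an EI surface from a calibrated model
#'
#' @param object a [climex_fit()].
#' @param newdata a [climate_grid()] to score.
#' @param ... unused.
#' @return a [climex_run()] result on `newdata`.
#' @export
predict.climex_fit <- function(object, newdata, ...) {
  climex_run(newdata, object$parameters)
}

#' @export
plot.climex_fit <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_trace) - 1, x$fitness_trace, type = "s",
                 xlab = "generation", ylab = "best objective",
                 main = "GA calibration trace", ...)
  invisible(x)
}
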