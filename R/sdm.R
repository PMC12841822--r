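# Correlative suitability modelling: predictor extraction at record
# locations, collinearity screening (Pearson, then LASSO), random-forest
# fitting with repeated stratified 70/30 splits, threshold-based evaluation
# (AUC / TSS / Kappa) and raster prediction.

#' Extract bioclim predictor values at occurrence records
#'
#' Samples all 19 layers at each record's grid cell. Records falling on
#' nodata cells or outside the grid are dropped.
#'
#' @param bioclim a [compute_bioclim()] result.
#' @param occurrences an [occurrence_set()].
#' @return a data frame with columns `bio1..bio19` and `label`.
#' @export
extract_predictors <- function(bioclim, occurrences) {
  stopifnot(inherits(bioclim, "bioclim_grid"))
  rc <- cell_index(bioclim, occurrences$lon, occurrences$lat)
  ok <- !is.na(rc[, 1]) & !is.na(rc[, 2])
  vars <- dimnames(bioclim$layers)[[3]]
  out <- as.data.frame(stats::setNames(lapply(vars, function(v) {
    bioclim$layers[, , v][rc[ok, , drop = FALSE]]
  }), vars))
  out$label <- occurrences$label[ok]
  out <- out[stats::complete.cases(out[, vars]), , drop = FALSE]
  if (nrow(out) == 0) stop("no records fall on valid cells")
  out
}

#' Screen predictors by pairwise Pearson correlation
#'
#' Walks the predictor columns in their natural order and drops a variable
#' iff its absolute Pearson correlation with any already-retained variable
#' exceeds `threshold`; of a correlated pair the earlier variable is kept.
#' The retained set therefore has all pairwise `|r| <= threshold`.
#' Constant columns have undefined correlations and are dropped with a
#' warning.
#'
#' @param table data frame of numeric predictors (a `label` column, if
#'   present, is ignored).
#' @param threshold correlation cut-off (default 0.8).
#' @return character vector of retained variable names.
#' @export
pearson_filter <- function(table, threshold = 0.8) {
  vars <- setdiff(names(table), "label")
  if (nrow(table) < 3) stop("need at least 3 rows to estimate correlations")
  retained <- character(0)
  for (v in vars) {
    x <- table[[v]]
    if (stats::sd(x) == 0) {
      warning("dropping constant predictor '", v, "' (correlation undefined)")
      next
    }
    r <- if (length(retained)) {
      abs(stats::cor(x, table[retained]))
    } else numeric(0)
    if (all(r <= threshold)) retained <- c(retained, v)
  }
  retained
}

#' Screen predictors by L1-penalised logistic regression
#'
#' Fits a LASSO logistic model on standardised predictors with the penalty
#' chosen by 5-fold cross-validation (1-SE rule) and returns the variables
#' with nonzero coefficients. With a strong penalty the set may be empty;
#' callers are expected to fall back to the unscreened set in that case
#' (see [sdm_rf()]).
#'
#' @param table data frame of numeric predictors.
#' @param labels factor or character vector with two classes, aligned with
#'   `table` rows.
#' @param seed integer RNG seed for the CV folds.
#' @return character vector of variables with nonzero coefficients.
#' @export
lasso_screen <- function(table, labels, seed = 1L) {
  vars <- setdiff(names(table), "label")
  y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("labels must contain two classes")
  x <- as.matrix(table[, vars, drop = FALSE])
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5,
                          standardize = TRUE)
  beta <- stats::coef(cv, s = "lambda.1se")[-1, 1]
  names(beta)[beta != 0]
}

#' Threshold-based evaluation of presence/absence scores
#'
#' AUC is computed from the rank statistic (equivalent to the area under
#' the ROC curve, ties averaged). The classification threshold is the one
#' maximising the True Skill Statistic `TSS = sensitivity + specificity - 1`
#' over all candidate thresholds (ties resolved toward the lowest
#' threshold); Cohen's Kappa is reported at that same threshold.
#'
#' @param scores numeric scores in \[0, 1\] (higher = more presence-like).
#' @param labels vector with exactly two classes; the positive class is
#'   `"presence"` if present, otherwise the alphabetically last level.
#' @return list with `auc`, `tss`, `kappa`, `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
evaluate_scores <- function(scores, labels) {
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("labels must contain exactly two classes")
  pos_class <- if ("presence" %in% classes) "presence" else classes[2]
  pos <- y == pos_class
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cand <- sort(unique(scores))
  thr <- c(cand, Inf)   # predict positive iff score >= threshold
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  tss <- sens + spec - 1
  i <- which.max(tss)   # first maximum = lowest threshold
  t_best <- thr[i]
  pred <- scores >= t_best
  po <- mean(pred == pos)
  pe <- mean(pred) * mean(pos) + mean(!pred) * mean(!pos)
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  list(auc = auc, tss = tss[i], kappa = kappa,
       sensitivity = sens[i], specificity = spec[i], threshold = t_best)
}

#' Random-forest suitability model with repeated stratified splits
#'
#' Screens the predictors (Pearson filter, then LASSO with fallback to the
#' Pearson-retained set when LASSO keeps nothing), then runs `folds`
#' repeated stratified random 70/30 splits: a forest of `ntree` trees is
#' grown on each training split and evaluated on the held-out records with
#' [evaluate_scores()]. Permutation variable importance is averaged over
#' the split models, floored at zero and normalised to percentages. The
#' returned model for prediction is refit on all records.
#'
#' @param table data frame of predictors plus a `label` column, as produced
#'   by [extract_predictors()], or predictors only with `labels` given.
#' @param labels optional vector of record classes.
#' @param folds number of repeated splits (default 10).
#' @param train_frac training fraction per split (default 0.7).
#' @param ntree trees per forest (default 500).
#' @param seed integer RNG seed; fixed seed gives reproducible fits.
#' @param screen logical: apply the Pearson + LASSO screen (default TRUE).
#' @param pearson_threshold cut-off for [pearson_filter()] (default 0.8).
#' @return an object of class `sdm_rf` with elements `model`, `variables`,
#'   `evaluation` (per-fold data frame plus means), `importance` (percent,
#'   sums to 100), `folds`, `train_frac`.
#' @export
sdm_rf <- function(table, labels = NULL, folds = 10, train_frac = 0.7,
                   ntree = 500, seed = 1L, screen = TRUE,
                   pearson_threshold = 0.8) {
  if (is.null(labels)) {
    if (!"label" %in% names(table)) stop("supply 'labels' or a label column")
    labels <- table$label
  }
  y <- factor(as.character(labels))
  if (nlevels(y) != 2) stop("labels must contain exactly two classes")
  if (min(table(y)) < 2) stop("need at least 2 records per class")
  pos_class <- if ("presence" %in% levels(y)) "presence" else levels(y)[2]
  x_all <- table[, setdiff(names(table), "label"), drop = FALSE]

  vars <- names(x_all)
  if (screen) {
    vars <- pearson_filter(x_all, pearson_threshold)
    lvars <- lasso_screen(x_all[, vars, drop = FALSE], y, seed = seed)
    if (length(lvars) == 0) {
      warning("LASSO retained no variables; falling back to the ",
              "Pearson-screened set")
    } else vars <- lvars
  }
  x <- x_all[, vars, drop = FALSE]

  set.seed(seed)
  ev <- vector("list", folds)
  imp <- matrix(0, length(vars), folds, dimnames = list(vars, NULL))
  for (f in seq_len(folds)) {
    tr <- unlist(lapply(split(seq_along(y), y), function(i) {
      sample(i, max(1, round(train_frac * length(i))))
    }), use.names = FALSE)
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop("a class is absent from a split; stratification failed")
    }
    rf <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                     ntree = ntree, importance = TRUE)
    scores <- stats::predict(rf, x[te, , drop = FALSE],
                             type = "prob")[, pos_class]
    e <- evaluate_scores(scores, as.character(y[te]))
    ev[[f]] <- data.frame(fold = f, auc = e$auc, tss = e$tss, kappa = e$kappa)
    imp[, f] <- randomForest::importance(rf, type = 1)[vars, 1]
  }
  per_fold <- do.call(rbind, ev)
  means <- colMeans(per_fold[, c("auc", "tss", "kappa")])

  raw <- pmax(rowMeans(imp), 0)
  importance <- if (sum(raw) > 0) 100 * raw / sum(raw) else
    stats::setNames(rep(100 / length(vars), length(vars)), vars)

  final <- randomForest::randomForest(x, y, ntree = ntree, importance = TRUE)
  structure(list(model = final, variables = vars, pos_class = pos_class,
                 evaluation = list(per_fold = per_fold, mean = as.list(means)),
                 importance = importance, folds = folds,
                 train_frac = train_frac, seed = seed),
            class = "sdm_rf")
}

#' @export
print.sdm_rf <- function(x, ...) {
  m <- x$evaluation$mean
  cat("Random-forest suitability model\n")
  cat("  predictors:", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("  %d stratified %.0f/%.0f splits: AUC %.3f, TSS %.3f, Kappa %.3f\n",
              x$folds, 100 * x$train_frac, 100 * (1 - x$train_frac),
              m$auc, m$tss, m$kappa))
  invisible(x)
}

#' @export
summary.sdm_rf <- function(object, ...) {
  print(object)
  cat("  per-fold metrics:\n")
  print(object$evaluation$per_fold, row.names = FALSE)
  cat("  variable importance (%):\n")
  print(round(sort(object$importance, decreasing = TRUE), 2))
  invisible(object)
}

#' @export
plot.sdm_rf <- function(x, ...) {
  imp <- sort(x$importance)
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "importance (%)",
                    main = "Variable importance", ...)
  invisible(x)
}

#' Predict a suitability raster (or record scores) from a fitted model
#'
#' With a `bioclim_grid` as `newdata`, returns per-cell presence
#' probabilities with nodata propagated; with a data frame, returns a
#' probability vector.
#'
#' @param object an [sdm_rf()].
#' @param newdata a [compute_bioclim()] grid or a data frame containing the
#'   model's predictor columns.
#' @param ... unused.
#' @return a `suitability_raster` (elements `lat`, `lon`, `prob`) or a
#'   numeric vector.
#' @export
predict.sdm_rf <- function(object, newdata, ...) {
  if (inherits(newdata, "bioclim_grid")) {
    have <- dimnames(newdata$layers)[[3]]
    missing_layer <- setdiff(object$variables, have)
    if (length(missing_layer)) {
      stop("bioclim grid lacks layer(s): ", paste(missing_layer, collapse = ", "))
    }
    valid <- which(newdata$mask)
    df <- as.data.frame(lapply(object$variables, function(v) {
      newdata$layers[, , v][valid]
    }))
    names(df) <- object$variables
    prob <- matrix(NA_real_, length(newdata$lat), length(newdata$lon))
    ok <- stats::complete.cases(df)
    p <- stats::predict(object$model, df[ok, , drop = FALSE],
                        type = "prob")[, object$pos_class]
    prob[valid[ok]] <- p
    structure(list(lat = newdata$lat, lon = newdata$lon, prob = prob),
              class = "suitability_raster")
  } else {
    missing_col <- setdiff(object$variables, names(newdata))
    if (length(missing_col)) {
      stop("newdata lacks column(s): ", paste(missing_col, collapse = ", "))
    }
    stats::predict(object$model,
                   newdata[, object$variables, drop = FALSE],
                   type = "prob")[, object$pos_class]
  }
}

#' @export
print.suitability_raster <- function(x, ...) {
  v <- x$prob[!is.na(x$prob)]
  cat("Suitability raster:", length(x$lat), "x", length(x$lon),
      "cells; probability range", round(min(v), 3), "..", round(max(v), 3), "\n")
  invisible(x)
}

#' Write a suitability raster as CSV (lon, lat, prob)
#'
#' @param x a `suitability_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_suitability_csv <- function(x, path) {
  ok <- which(!is.na(x$prob), arr.ind = TRUE)
  utils::write.csv(data.frame(lon = x$lon[ok[, 2]], lat = x$lat[ok[, 1]],
                              prob = x$prob[ok]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
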