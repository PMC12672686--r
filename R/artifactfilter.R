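#' Machine-learning curation of detected rare events
#'
#' A histogram-binned gradient-boosted tree classifier separates biological
#' cells from technical artifacts (debris, saturated speckles).  The model is
#' selected by stratified k-fold cross-validation over a grid of
#' hyperparameters and morphometric feature subsets, then applied with a
#' prediction-confidence threshold (default 0.90): only events whose
#' predicted probability of being a cell reaches the threshold are kept.
#'
#' @name artifactfilter
NULL

#' Default hyperparameter / feature-subset grid
#'
#' @return list of grid points, each with `max_depth`, `eta`, `nrounds` and
#'   `features` (column subset).
#' @export
default_curation_grid <- function() {
  feats <- morphometric_feature_names()
  morpho <- c("nuclear_area", "nuclear_eccentricity", "cellular_area",
              "cellular_eccentricity", "cellular_perimeter", "solidity")
  subsets <- list(all = feats, morphometric = morpho,
                  morpho_dapi = c(morpho, "median_dapi", "mad_dapi"))
  grid <- list()
  for (nm in names(subsets)) {
    for (depth in c(3L, 6L)) {
      grid[[length(grid) + 1]] <- list(max_depth = depth, eta = 0.3,
                                       nrounds = 50L, features = subsets[[nm]],
                                       feature_set = nm)
    }
  }
  grid
}

# stratified fold assignment, deterministic given the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.fit_xgb <- function(X, y01, par, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = par$max_depth,
                  eta = par$eta, tree_method = "hist", nthread = 1,
                  seed = seed),
    data = dm, nrounds = par$nrounds, verbose = 0)
}

.xgb_predict <- function(booster, X) {
  stats::predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Train the curation model
#'
#' Stratified k-fold cross-validation over the grid; the (hyperparameters,
#' feature subset) pair with the highest mean CV accuracy is selected and
#' refit on all data.  The evaluation budget (grid points x folds) is capped
#' at `max_evaluations`.
#'
#' @param events CellEvent feature table.
#' @param label factor with levels `artifact`, `cell` (or coercible).
#' @param k folds (default 5).
#' @param grid list of grid points as in [default_curation_grid()].
#' @param seed integer seed; retraining with the same seed reproduces the CV
#'   accuracies and selection exactly.
#' @param confidence_threshold default probability cutoff stored with the
#'   model.
#' @param max_evaluations cap on grid x fold model fits.
#' @return object of class `raredrop_curation_model`.
#' @export
train_curation_model <- function(events, label, k = 5,
                                 grid = default_curation_grid(), seed = 1,
                                 confidence_threshold = 0.90,
                                 max_evaluations = 1000) {
  label <- factor(as.character(label), levels = c("artifact", "cell"))
  if (anyNA(label)) stop("labels must be 'artifact' or 'cell'")
  if (nlevels(droplevels(label)) < 2)
    stop("both labels (cell, artifact) must be present")
  if (k < 2) stop("k must be >= 2")
  if (k > min(table(label))) stop("k exceeds the smallest class count")
  if (!length(grid)) stop("empty hyperparameter grid")
  n_grid_max <- max(1, floor(max_evaluations / k))
  if (length(grid) > n_grid_max) grid <- grid[seq_len(n_grid_max)]

  set.seed(seed)
  fold <- stratified_folds(label, k)
  y01 <- as.integer(label == "cell")
  cv <- lapply(seq_along(grid), function(gi) {
    par <- grid[[gi]]
    feats <- intersect(par$features, names(events))
    X <- as.matrix(events[, feats, drop = FALSE])
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- .fit_xgb(X[tr, , drop = FALSE], y01[tr], par, seed)
      p <- .xgb_predict(m, X[!tr, , drop = FALSE])
      mean((p >= 0.5) == (y01[!tr] == 1))
    }, numeric(1))
    list(grid_index = gi, fold_accuracy = acc, mean_accuracy = mean(acc))
  })
  means <- vapply(cv, `[[`, numeric(1), "mean_accuracy")
  best_i <- which.max(means)   # first maximum: deterministic tie rule
  best <- grid[[best_i]]
  feats <- intersect(best$features, names(events))
  X <- as.matrix(events[, feats, drop = FALSE])
  final <- .fit_xgb(X, y01, best, seed)
  structure(list(
    booster = final, features = feats, hyperparameters = best,
    cv_summary = data.frame(
      grid_index = seq_along(grid),
      feature_set = vapply(grid, function(g) g$feature_set %||% "custom",
                           character(1)),
      max_depth = vapply(grid, `[[`, integer(1), "max_depth"),
      mean_cv_accuracy = means),
    fold_accuracy = cv[[best_i]]$fold_accuracy,
    confidence_threshold = confidence_threshold, k = k, seed = seed
  ), class = "raredrop_curation_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict cell confidence for events
#' @param model a `raredrop_curation_model`.
#' @param events CellEvent feature table.
#' @return numeric vector of P(cell) per event.
#' @export
curation_confidence <- function(model, events) {
  miss <- setdiff(model$features, names(events))
  if (length(miss))
    stop("events table is missing model features: ", paste(miss, collapse = ", "))
  .xgb_predict(model$booster,
               as.matrix(events[, model$features, drop = FALSE]))
}

#' Apply the prediction-confidence filter
#'
#' Keeps events with P(cell) >= `threshold`; kept and rejected sets partition
#' the input.
#'
#' @param model a `raredrop_curation_model`.
#' @param events CellEvent table.
#' @param threshold probability cutoff (default: the model's stored 0.90).
#' @return list with `kept`, `rejected` (row subsets of `events`) and
#'   `confidence` (per input event).
#' @export
apply_confidence_filter <- function(model, events,
                                    threshold = model$confidence_threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- curation_confidence(model, events)
  keep <- p >= threshold
  list(kept = events[keep, , drop = FALSE],
       rejected = events[!keep, , drop = FALSE],
       confidence = p)
}

#' @export
print.raredrop_curation_model <- function(x, ...) {
  cat("Curation model:", length(x$features), "features, max_depth",
      x$hyperparameters$max_depth, "| mean CV accuracy",
      sprintf("%.3f", mean(x$fold_accuracy)),
      "| confidence threshold", x$confidence_threshold, "\n")
  invisible(x)
}
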