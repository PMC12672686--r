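#' Patient-level disease-state prediction
#'
#' Binary prediction of disease grouping (precursor vs overt disease,
#' precursor vs newly diagnosed, MGUS vs SMM) from per-sample cells/mL
#' features: univariate single-feature threshold classifiers and multivariate
#' decision-tree / random-forest models, all evaluated by stratified
#' cross-validation (accuracies are always held-out, never resubstitution).
#'
#' @name predictmod
NULL

#' Built-in label definitions
#'
#' @param task one of `"precursor_vs_overt"` (`MGUS`,`SMM` vs `NDMM`,`RRMM`),
#'   `"precursor_vs_ndmm"`, `"mgus_vs_smm"`.
#' @param disease_state character vector of states per sample.
#' @return factor of labels with `NA` for samples outside the task.
#' @export
task_labels <- function(task = c("precursor_vs_overt", "precursor_vs_ndmm",
                                 "mgus_vs_smm"), disease_state) {
  task <- match.arg(task)
  lab <- switch(task,
    precursor_vs_overt = ifelse(disease_state %in% c("MGUS", "SMM"),
                                "precursor",
                         ifelse(disease_state %in% c("NDMM", "RRMM"),
                                "overt", NA)),
    precursor_vs_ndmm = ifelse(disease_state %in% c("MGUS", "SMM"),
                               "precursor",
                        ifelse(disease_state == "NDMM", "NDMM", NA)),
    mgus_vs_smm = ifelse(disease_state == "MGUS", "MGUS",
                  ifelse(disease_state == "SMM", "SMM", NA)))
  factor(lab)
}

# repeated stratified k-fold assignments; returns list of integer vectors
cv_folds <- function(y, k, repeats) {
  lapply(seq_len(repeats), function(r) stratified_folds(y, k))
}

# best single-feature threshold on training data: maximize accuracy over all
# midpoints and both directions; ties resolved toward the midpoint closest
# to the pooled median
best_stump <- function(x, y) {
  lv <- levels(y)
  ux <- sort(unique(x))
  cuts <- if (length(ux) > 1) (ux[-1] + ux[-length(ux)]) / 2 else ux
  cand <- expand.grid(cut = cuts, hi = lv, stringsAsFactors = FALSE)
  acc <- vapply(seq_len(nrow(cand)), function(i) {
    pred <- ifelse(x >= cand$cut[i], cand$hi[i], setdiff(lv, cand$hi[i]))
    mean(pred == as.character(y))
  }, numeric(1))
  best <- which(acc == max(acc))
  if (length(best) > 1) {
    med <- stats::median(x)
    best <- best[which.min(abs(cand$cut[best] - med))]
  }
  list(cut = cand$cut[best], hi = cand$hi[best], train_accuracy = max(acc))
}

#' Cross-validated accuracy of a single-feature threshold classifier
#'
#' Per fold the cut maximizing training accuracy is chosen (ties resolved
#' toward the pooled median) and evaluated on the held-out fold.
#'
#' @param x numeric feature per sample.
#' @param y binary factor labels.
#' @param k folds.
#' @param repeats repeated CV rounds.
#' @param seed integer seed.
#' @return list with `accuracy` (mean held-out), `threshold` and `direction`
#'   refit on all data, `fold_accuracy`.
#' @export
univariate_accuracy <- function(x, y, k = 5, repeats = 5, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("binary labels required")
  if (min(table(y)) < 3) stop("need at least 3 samples per class")
  if (length(unique(x)) == 1) {
    warning("constant feature; accuracy equals the majority-class rate")
    maj <- names(which.max(table(y)))
    return(list(accuracy = mean(y == maj), threshold = unique(x),
                direction = maj, fold_accuracy = NULL))
  }
  set.seed(seed)
  folds <- cv_folds(y, k, repeats)
  accs <- unlist(lapply(folds, function(fold) {
    vapply(seq_len(k), function(f) {
      tr <- fold != f
      st <- best_stump(x[tr], y[tr])
      pred <- ifelse(x[!tr] >= st$cut, st$hi, setdiff(levels(y), st$hi))
      mean(pred == as.character(y[!tr]))
    }, numeric(1))
  }))
  full <- best_stump(x, y)
  list(accuracy = mean(accs), threshold = full$cut, direction = full$hi,
       fold_accuracy = accs)
}

#' Cross-validated multivariate prediction
#'
#' Stratified repeated k-fold cross-validation of a decision tree or random
#' forest on the cells/mL feature matrix; impurity-based importances are
#' averaged over folds.
#'
#' @param features data.frame/matrix of per-sample features.
#' @param y binary factor labels.
#' @param model `"decision-tree"`, `"random-forest"` or `"univariate-stump"`
#'   (best single feature per fold).
#' @param k,repeats CV scheme.
#' @param seed integer seed.
#' @param ntree random-forest size.
#' @param folds optional explicit fold assignments (list of integer vectors in
#'   `1:k`, one per repeat); lets callers group duplicated or related samples
#'   into the same fold to guard against leakage.
#' @return `raredrop_prediction`: list with `accuracy`, `importance` (named,
#'   decreasing), `confusion` (2x2 summed over folds), `fold_accuracy`,
#'   `folds` (the fold assignments, for leakage audits), `model`.
#' @export
multivariate_accuracy <- function(features, y,
                                  model = c("random-forest", "decision-tree",
                                            "univariate-stump"),
                                  k = 5, repeats = 5, seed = 1, ntree = 500,
                                  folds = NULL) {
  model <- match.arg(model)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("all labels identical; nothing to predict")
  if (min(table(y)) < 3) stop("need at least 3 samples per class")
  X <- as.data.frame(features)
  names(X) <- make.names(names(X))
  set.seed(seed)
  if (is.null(folds)) {
    folds <- cv_folds(y, k, repeats)
  } else {
    stopifnot(is.list(folds),
              all(vapply(folds, length, integer(1)) == length(y)))
    repeats <- length(folds)
  }
  imp_sum <- stats::setNames(numeric(ncol(X)), names(X))
  conf <- matrix(0, 2, 2, dimnames = list(truth = levels(y),
                                          predicted = levels(y)))
  accs <- numeric(0)
  for (fold in folds) {
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
      # features constant on the training fold carry no information and make
      # the forest's split search degenerate; drop them, and with none left
      # predict the training majority class
      varying <- vapply(X[tr, , drop = FALSE],
                        function(col) length(unique(col)) > 1, logical(1))
      if (!any(varying)) {
        maj <- names(which.max(table(y[tr])))
        pred <- factor(rep(maj, sum(!tr)), levels = levels(y))
        accs <- c(accs, mean(pred == y[!tr]))
        conf <- conf + table(truth = y[!tr],
                             predicted = factor(pred, levels = levels(y)))
        next
      }
      Xv <- X[, varying, drop = FALSE]
      pred <- switch(model,
        "random-forest" = {
          fit <- randomForest::randomForest(Xv[tr, , drop = FALSE], y[tr],
                                            ntree = ntree)
          imp <- randomForest::importance(fit)[, 1]
          imp_sum[names(imp)] <- imp_sum[names(imp)] + pmax(imp, 0)
          stats::predict(fit, Xv[!tr, , drop = FALSE])
        },
        "decision-tree" = {
          d <- cbind(.y = y[tr], Xv[tr, , drop = FALSE])
          fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                              control = rpart::rpart.control(minsplit = 5,
                                                             cp = 0.01))
          vi <- fit$variable.importance
          if (!is.null(vi)) imp_sum[names(vi)] <- imp_sum[names(vi)] + vi
          stats::predict(fit, Xv[!tr, , drop = FALSE], type = "class")
        },
        "univariate-stump" = {
          per_feat <- lapply(Xv, function(col) best_stump(col[tr], y[tr]))
          ta <- vapply(per_feat, `[[`, numeric(1), "train_accuracy")
          j <- which.max(ta)
          imp_sum[names(Xv)[j]] <- imp_sum[names(Xv)[j]] + 1
          st <- per_feat[[j]]
          factor(ifelse(Xv[[j]][!tr] >= st$cut, st$hi,
                        setdiff(levels(y), st$hi)), levels = levels(y))
        })
      accs <- c(accs, mean(pred == y[!tr]))
      conf <- conf + table(truth = y[!tr],
                           predicted = factor(pred, levels = levels(y)))
    }
  }
  structure(list(
    accuracy = mean(accs), fold_accuracy = accs,
    importance = sort(imp_sum / (k * repeats), decreasing = TRUE),
    confusion = conf, folds = folds, model = model, seed = seed
  ), class = "raredrop_prediction")
}

#' Run a full prediction task on a cohort enumeration
#'
#' Univariate accuracy for every cells/mL feature plus the multivariate
#' models.
#'
#' @param enums stacked [enumerate_sample()] output with `disease_state`.
#' @param task see [task_labels()].
#' @param k,repeats,seed CV scheme.
#' @return list with `task`, `univariate` (data.frame feature/accuracy,
#'   sorted), `decision_tree`, `random_forest` (each a
#'   `raredrop_prediction`), `n`, `majority_rate`.
#' @export
predict_disease_state <- function(enums, task = "precursor_vs_overt",
                                  k = 5, repeats = 5, seed = 1) {
  wide <- enumeration_matrix(enums)
  y <- task_labels(task, wide$disease_state)
  keep <- !is.na(y)
  wide <- wide[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  feats <- wide[, setdiff(names(wide), c("sample_id", "disease_state")),
                drop = FALSE]
  uni <- lapply(names(feats), function(f)
    univariate_accuracy(feats[[f]], y, k = k, repeats = repeats, seed = seed))
  uni_df <- data.frame(
    feature = names(feats),
    accuracy = vapply(uni, `[[`, numeric(1), "accuracy"),
    threshold = vapply(uni, `[[`, numeric(1), "threshold"),
    stringsAsFactors = FALSE)
  uni_df <- uni_df[order(-uni_df$accuracy), ]
  list(task = task,
       univariate = uni_df,
       decision_tree = multivariate_accuracy(feats, y, "decision-tree",
                                             k = k, repeats = repeats,
                                             seed = seed),
       random_forest = multivariate_accuracy(feats, y, "random-forest",
                                             k = k, repeats = repeats,
                                             seed = seed),
       n = length(y),
       majority_rate = max(table(y)) / length(y))
}

#' @export
print.raredrop_prediction <- function(x, ...) {
  cat(sprintf("%s: CV accuracy %.3f over %d held-out folds; top feature: %s\n",
              x$model, x$accuracy, length(x$fold_accuracy),
              names(x$importance)[1]))
  invisible(x)
}
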