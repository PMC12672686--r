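#' Outlier-clustering rare-event detection
#'
#' Flags single cells or small clusters of cells that significantly deviate
#' from the median cell in a PCA-reduced morphometric space: features are
#' robustly standardized, projected onto the principal components retaining a
#' target fraction of variance, and each event's Euclidean distance to the
#' coordinate-wise median cell is computed.  Hierarchical clustering groups
#' deviant events; events are flagged rare when their own distance reaches
#' the distance-quantile threshold, or when they sit in a small cluster whose
#' centroid does.
#'
#' @name raredetect
NULL

#' Detection parameters
#'
#' @param variance_retained cumulative PC variance to keep (default 0.95).
#' @param linkage hierarchical-clustering linkage.
#' @param max_rare_cluster_size largest cluster still considered "rare"; a
#'   value below 1 is read as a fraction of the event count.  Default
#'   `max(10, 0.1%)`.
#' @param distance_quantile percentile of the median-cell distances defining
#'   significant deviation (default 99.5).
#' @param standardize robustly standardize features (median/MAD, with an SD
#'   fallback for zero-MAD features) before PCA.
#' @param cluster_candidate_quantile events above this distance percentile
#'   enter the hierarchical clustering when the event table is too large to
#'   cluster wholesale; below `cluster_all_max` events everything is
#'   clustered.
#' @param cluster_all_max see above.
#' @param cluster_cut_scale the dendrogram is cut at the largest height whose
#'   clusters all have internal max pairwise distance at most
#'   `cluster_cut_scale` x the detection threshold.  A scale above 1 lets the
#'   smooth tail of the common population cohere into large (hence unflagged)
#'   clusters while well-separated outliers remain in small ones.
#' @return object of class `raredrop_detection_params`.
#' @export
detection_params <- function(variance_retained = 0.95,
                             linkage = c("ward", "average", "complete"),
                             max_rare_cluster_size = NULL,
                             distance_quantile = 99.5,
                             standardize = TRUE,
                             cluster_candidate_quantile = 99,
                             cluster_all_max = 2000,
                             cluster_cut_scale = 2) {
  linkage <- match.arg(linkage)
  stopifnot(variance_retained > 0, variance_retained <= 1,
            distance_quantile > 0, distance_quantile < 100,
            is.null(max_rare_cluster_size) || max_rare_cluster_size > 0)
  structure(list(variance_retained = variance_retained, linkage = linkage,
                 max_rare_cluster_size = max_rare_cluster_size,
                 distance_quantile = distance_quantile,
                 standardize = standardize,
                 cluster_candidate_quantile = cluster_candidate_quantile,
                 cluster_all_max = cluster_all_max,
                 cluster_cut_scale = cluster_cut_scale),
            class = "raredrop_detection_params")
}

# robust per-feature standardization; constant features are dropped
robust_standardize <- function(X) {
  med <- apply(X, 2, stats::median)
  scale_ <- apply(X, 2, stats::mad)
  sdv <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- sdv[scale_ == 0]     # heavy point masses: fall back
  keep <- scale_ > 0
  if (!any(keep)) return(NULL)
  sweep(sweep(X[, keep, drop = FALSE], 2, med[keep]), 2, scale_[keep], "/")
}

# features matrix from an event table
detection_features <- function(events, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- intersect(morphometric_feature_names(), names(events))
  X <- as.matrix(events[, feature_cols, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values in event table")
  X
}

#' Distance of every event to the median cell in PC space
#'
#' Exposes the distance computation of [detect_rare_events()] on its own:
#' standardization (optional), PCA retaining the target variance, and
#' Euclidean distance to the coordinate-wise median cell.
#'
#' @param events CellEvent table.
#' @param params a [detection_params()].
#' @param feature_cols feature columns (default: the morphometric feature set
#'   present in the table).
#' @return list with `distance` (per event), `scores` (PC coordinates),
#'   `rotation`, `explained_variance`, `n_components`.
#' @export
distance_profile <- function(events, params = detection_params(),
                             feature_cols = NULL) {
  if (nrow(events) < 2) stop("need at least 2 events")
  X <- detection_features(events, feature_cols)
  if (params$standardize) {
    X <- robust_standardize(X)
    if (is.null(X)) {
      # fully degenerate input: every event identical -> no deviation
      return(list(distance = rep(0, nrow(events)), scores = NULL,
                  rotation = NULL, explained_variance = numeric(0),
                  n_components = 0L))
    }
  } else if (all(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate PCA: constant feature matrix and standardization is off")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(vr) >= params$variance_retained)[1]
  if (is.na(k)) k <- length(vr)
  S <- pc$x[, seq_len(k), drop = FALSE]
  med <- apply(S, 2, stats::median)
  d <- sqrt(rowSums(sweep(S, 2, med)^2))
  list(distance = d, scores = S, rotation = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = vr[seq_len(k)], n_components = k)
}

# cut a dendrogram at the largest height whose clusters all have internal
# max pairwise distance <= threshold (binary search over merge heights)
cut_by_internal_distance <- function(hc, D, threshold, n) {
  heights <- sort(unique(hc$height))
  ok_at <- function(h) {
    cl <- stats::cutree(hc, h = h)
    for (g in unique(cl)) {
      idx <- which(cl == g)
      if (length(idx) > 1 && max(D[idx, idx]) > threshold) return(FALSE)
    }
    TRUE
  }
  # ok_at is monotone (true for small heights); find the last true height
  lo <- 0L; hi <- length(heights)
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (ok_at(heights[mid])) lo <- mid else hi <- mid - 1L
  }
  if (lo == 0L) seq_len(n) else stats::cutree(hc, h = heights[lo])
}

#' Detect rare events
#'
#' @inheritParams distance_profile
#' @return object of class `raredrop_detection`: a list with `flag`
#'   (factor rare/common per event), `distance`, `cluster` (cluster id for
#'   clustered events, `NA` otherwise), `threshold`, `rotation`,
#'   `explained_variance`, `params`.
#' @export
detect_rare_events <- function(events, params = detection_params(),
                               feature_cols = NULL) {
  if (nrow(events) < 50) stop("need at least 50 events for rare-event detection")
  prof <- distance_profile(events, params, feature_cols)
  d <- prof$distance
  n <- length(d)
  threshold <- stats::quantile(d, params$distance_quantile / 100, names = FALSE)
  max_sz <- params$max_rare_cluster_size
  if (is.null(max_sz)) max_sz <- max(10, 0.001 * n)
  if (max_sz < 1) max_sz <- max_sz * n
  max_sz <- max(1, floor(max_sz))

  # With max_rare_cluster_size = 1 clustering is bypassed and flags reduce to
  # the pure distance-threshold rule (inclusive tie at a positive threshold;
  # a fully degenerate profile - all distances zero - flags nothing).
  # Otherwise the hierarchical clustering does the work the threshold alone
  # cannot: the smooth tail of the common population beyond the quantile
  # forms large mutually-close clusters and stays common, while genuine rare
  # events land in small clusters (or singletons) whose centroid
  # significantly deviates from the median cell.
  flag <- rep(FALSE, n)
  cluster <- rep(NA_integer_, n)
  if (max_sz <= 1 || is.null(prof$scores) || threshold == 0) {
    flag <- d >= threshold & d > 0
  } else {
    cand <- if (n <= params$cluster_all_max) {
      seq_len(n)
    } else {
      # candidate tail for clustering; never above the detection threshold,
      # so every event that could be flagged is available to the clustering
      pre <- stats::quantile(d, params$cluster_candidate_quantile / 100,
                             names = FALSE)
      which(d >= min(pre, threshold))
    }
    if (length(cand) == 1) {
      flag[cand] <- d[cand] >= threshold & d[cand] > 0
    } else if (length(cand) >= 2) {
      S <- prof$scores[cand, , drop = FALSE]
      D <- as.matrix(stats::dist(S))
      method <- switch(params$linkage, ward = "ward.D2",
                       average = "average", complete = "complete")
      hc <- stats::hclust(stats::as.dist(D), method = method)
      cl <- cut_by_internal_distance(hc, D,
                                     params$cluster_cut_scale * threshold,
                                     length(cand))
      # stable cluster ids: numbered by first occurrence in candidate order
      cl <- match(cl, unique(cl))
      cluster[cand] <- cl
      centre <- apply(prof$scores, 2, stats::median)
      for (g in unique(cl)) {
        idx <- cand[cl == g]
        if (length(idx) <= max_sz) {
          cen <- colMeans(prof$scores[idx, , drop = FALSE])
          cd <- sqrt(sum((cen - centre)^2))
          if (cd >= threshold && cd > 0) flag[idx] <- TRUE
        }
      }
    }
  }
  structure(list(
    flag = factor(ifelse(flag, "rare", "common"), levels = c("common", "rare")),
    distance = d, cluster = cluster, threshold = threshold,
    rotation = prof$rotation, explained_variance = prof$explained_variance,
    n_components = prof$n_components, params = params
  ), class = "raredrop_detection")
}

#' @export
print.raredrop_detection <- function(x, ...) {
  cat("Rare-event detection:", sum(x$flag == "rare"), "rare of",
      length(x$flag), "events;", x$n_components, "PCs;",
      sprintf("threshold %.3f (q%.1f)\n", x$threshold,
              x$params$distance_quantile))
  invisible(x)
}
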