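#' Enumeration and cohort statistics
#'
#' Converts per-class event counts into cells per mL of blood using the CBC
#' taken at processing and the number of cells plated on the analyzed slides:
#' \deqn{cells/mL = count \times (CBC_{nucleated} / n_{analyzed}) / V_{blood}}
#' and runs the cohort comparisons (two-sided Wilcoxon rank-sum between
#' disease states, no multiplicity correction), the clinical correlations
#' (Spearman for continuous/ordinal, standardized Wilcoxon for binary), and
#' the morphometric visualizations (UMAP embedding, density distributions).
#'
#' @name enumstats
NULL

#' Convert class counts of one sample to cells/mL
#'
#' @param events phenotyped event table (with a `class` column), or `NULL` if
#'   `counts` is given.
#' @param meta list with `n_analyzed_cells`, `cbc_total_nucleated`,
#'   `blood_volume_ml` (see [sample_metadata()]).
#' @param sample_id,disease_state identifiers carried into the output.
#' @param counts optional named counts (as from [count_classes()]) to use
#'   instead of tallying `events`.
#' @return data.frame with one row per class/aggregate: `sample_id`,
#'   `disease_state`, `event_type`, `count`, `cells_per_ml`.
#' @export
enumerate_sample <- function(events, meta, sample_id = NULL,
                             disease_state = NA_character_, counts = NULL) {
  if (is.null(meta$n_analyzed_cells) || meta$n_analyzed_cells <= 0)
    stop("zero or missing analyzed cell count")
  if (is.null(meta$cbc_total_nucleated) || meta$cbc_total_nucleated <= 0)
    stop("missing CBC nucleated cell count")
  if (is.null(meta$blood_volume_ml) || meta$blood_volume_ml <= 0)
    stop("missing blood volume")
  if (is.null(counts)) {
    if (is.null(sample_id))
      sample_id <- if (nrow(events)) events$sample_id[1] else "sample"
    counts <- count_classes(events$class)
  }
  # evaluated in the documented order -- count x (CBC / analyzed) / volume --
  # so the identity is bit-reproducible against independent arithmetic
  scaling <- meta$cbc_total_nucleated / meta$n_analyzed_cells
  data.frame(
    sample_id = sample_id %||% "sample",
    disease_state = disease_state,
    event_type = names(counts),
    count = as.integer(counts),
    cells_per_ml = as.numeric(counts) * scaling / meta$blood_volume_ml,
    stringsAsFactors = FALSE
  )
}

#' Wide cells/mL matrix from stacked enumerations
#'
#' @param enums row-bound output of [enumerate_sample()] over samples.
#' @return data.frame with one row per sample, columns `sample_id`,
#'   `disease_state` and one cells/mL column per event type.
#' @export
enumeration_matrix <- function(enums) {
  types <- unique(enums$event_type)
  ids <- unique(enums$sample_id)
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  out$disease_state <- enums$disease_state[match(ids, enums$sample_id)]
  for (t in types) {
    sub <- enums[enums$event_type == t, ]
    out[[t]] <- sub$cells_per_ml[match(ids, sub$sample_id)]
  }
  out
}

#' Two-sided Wilcoxon rank-sum comparisons between disease states
#'
#' For each state pair and each class/aggregate, a two-sided Wilcoxon
#' rank-sum test on cells/mL.  The exact null distribution is used for
#' combined group sizes up to `exact_max` without ties; otherwise the normal
#' approximation with continuity and tie correction.  Each comparison is
#' analyzed independently (no multiplicity correction, mirroring standard
#' practice for exploratory cohort screens); a Benjamini-Hochberg column is
#' appended for reference only.
#'
#' @param enums stacked [enumerate_sample()] output with `disease_state`.
#' @param state_pairs list of length-2 character vectors; default all 6 pairs
#'   of the states present.
#' @param exact_max largest combined n for the exact test.
#' @return data.frame of StatResult rows: group1, group2, event_type,
#'   p_value, mean1, mean2, statistic, significant, p_bh.
#' @export
pairwise_state_tests <- function(enums, state_pairs = NULL, exact_max = 50) {
  states <- unique(enums$disease_state)
  if (is.null(state_pairs)) {
    cmb <- utils::combn(states, 2, simplify = FALSE)
    state_pairs <- cmb
  }
  rows <- list()
  for (pair in state_pairs) {
    g1 <- enums[enums$disease_state == pair[1], ]
    g2 <- enums[enums$disease_state == pair[2], ]
    if (!nrow(g1) || !nrow(g2)) stop("empty group in comparison: ",
                                     paste(pair, collapse = " vs "))
    for (t in unique(enums$event_type)) {
      x <- g1$cells_per_ml[g1$event_type == t]
      y <- g2$cells_per_ml[g2$event_type == t]
      if (length(x) < 2 || length(y) < 2) next
      res <- rank_sum_test(x, y, exact_max = exact_max)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = pair[1], group2 = pair[2], event_type = t,
        p_value = res$p_value, mean1 = mean(x), mean2 = mean(y),
        statistic = res$statistic, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      event_type = character(0), p_value = numeric(0),
                      mean1 = numeric(0), mean2 = numeric(0),
                      statistic = numeric(0), significant = logical(0),
                      p_bh = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when the combined sample size is at most `exact_max` and there are
#' no ties; normal approximation with continuity and tie correction
#' otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-test size limit.
#' @return list with `statistic` (Mann-Whitney W of `x`), `p_value`, `exact`.
#' @export
rank_sum_test <- function(x, y, exact_max = 50) {
  # degenerate comparison: every observation identical carries no evidence
  # (the tie-corrected normal approximation would otherwise divide by zero)
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                exact = FALSE))
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Standardized Wilcoxon statistic for a binary clinical variable
#'
#' The tie-corrected z statistic comparing cell burden between the two
#' categories.  Sign convention: positive means higher burden in the
#' reference (first) category.
#'
#' @param values cells/mL per sample.
#' @param group two-level factor; first level = reference.
#' @return list with `z` and two-sided `p_value`.
#' @export
wilcoxon_z <- function(values, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2) stop("binary variable required")
  ref <- levels(group)[1]
  r <- rank(values)
  n1 <- sum(group == ref); n2 <- sum(group != ref); n <- n1 + n2
  W <- sum(r[group == ref]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(values)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(z = 0, p_value = 1))
  z <- (W - mu) / sqrt(sig2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Correlations between enumerations and clinical variables
#'
#' Spearman rank correlation (average-rank ties) for continuous and ordinal
#' variables; standardized Wilcoxon z for binary variables.  Results are
#' sorted by p-value.  Variables that are entirely missing or constant are
#' skipped with a log message.
#'
#' @param enums stacked [enumerate_sample()] output.
#' @param clinical data.frame with `sample_id` and clinical columns.
#' @param types named character vector typing each clinical column as
#'   `"continuous"`, `"ordinal"` or `"binary"`; untyped columns are inferred
#'   (two unique values = binary, otherwise continuous).
#' @return data.frame of StatResult rows: analyte, clinical_variable, method,
#'   correlation_value, p_value, significant.
#' @export
clinical_correlations <- function(enums, clinical, types = NULL) {
  vars <- setdiff(names(clinical), c("sample_id", "disease_state"))
  wide <- enumeration_matrix(enums)
  wide <- wide[match(clinical$sample_id, wide$sample_id), ]
  analytes <- setdiff(names(wide), c("sample_id", "disease_state"))
  rows <- list()
  skipped <- character(0)
  for (v in vars) {
    cv <- clinical[[v]]
    ok <- !is.na(cv)
    vtype <- if (!is.null(types) && v %in% names(types)) types[[v]] else {
      if (length(unique(cv[ok])) == 2) "binary" else "continuous"
    }
    if (!any(ok) || length(unique(cv[ok])) < 2) {
      skipped <- c(skipped, v)
      next
    }
    for (a in analytes) {
      x <- wide[[a]][ok]
      if (vtype == "binary") {
        res <- wilcoxon_z(x, factor(cv[ok]))
        rows[[length(rows) + 1]] <- data.frame(
          analyte = a, clinical_variable = v, method = "Wilcoxon",
          correlation_value = res$z, p_value = res$p_value,
          stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, as.numeric(cv[ok]), method = "spearman",
                          exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          analyte = a, clinical_variable = v, method = "Spearman",
          correlation_value = unname(ct$estimate), p_value = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(skipped))
    message("skipped constant/all-missing clinical variable(s): ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$significant <- out$p_value < 0.05
  out <- out[order(out$p_value), ]
  attr(out, "skipped") <- skipped
  out
}

#' Two-dimensional UMAP embedding of cell morphometrics
#'
#' Deterministic given the seed (single-threaded layout).  Returns the
#' embedding along with kernel-density summaries for the morphometric
#' parameter set (median channel intensities, nuclear/cellular area and
#' eccentricity).
#'
#' @param events CellEvent table (optionally with `class` / `disease_state`
#'   columns, carried into the embedding table for plotting).
#' @param seed integer seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return list with `embedding` (data.frame `umap1`, `umap2` plus carried
#'   columns) and `densities` (named list of `stats::density` objects).
#' @export
morphometric_umap <- function(events, seed = 1, n_neighbors = 15) {
  if (nrow(events) < 20) stop("need at least 20 events for an embedding")
  feats <- intersect(morphometric_feature_names(), names(events))
  X <- robust_standardize(as.matrix(events[, feats, drop = FALSE]))
  if (is.null(X)) stop("degenerate feature matrix")
  set.seed(seed)
  emb <- uwot::umap(X, n_neighbors = min(n_neighbors, nrow(X) - 1),
                    n_threads = 1, n_sgd_threads = 1, batch = FALSE)
  out <- data.frame(umap1 = emb[, 1], umap2 = emb[, 2])
  for (cc in intersect(c("class", "disease_state", "sample_id"), names(events)))
    out[[cc]] <- events[[cc]]
  dens_pars <- c("median_cd138", "median_bcma", "median_cd45", "nuclear_area",
                 "nuclear_eccentricity", "cellular_area",
                 "cellular_eccentricity")
  densities <- lapply(intersect(dens_pars, names(events)), function(p)
    stats::density(events[[p]]))
  names(densities) <- intersect(dens_pars, names(events))
  list(embedding = out, densities = densities)
}

#' Plot a morphometric UMAP colored by class, faceted by disease state
#' @param umap result of [morphometric_umap()].
#' @return a ggplot object.
#' @export
plot_umap <- function(umap) {
  df <- umap$embedding
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$umap1, .data$umap2))
  p <- if ("class" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class),
                            size = 0.6, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(size = 0.6, alpha = 0.7)
  }
  p <- p + ggplot2::theme_minimal()
  if ("disease_state" %in% names(df))
    p <- p + ggplot2::facet_wrap(~disease_state)
  p
}

#' Density plots for the morphometric parameter set
#' @param events CellEvent table.
#' @return a ggplot object (free-scale facets, one per parameter).
#' @export
plot_morphometric_densities <- function(events) {
  pars <- intersect(c("median_cd138", "median_bcma", "median_cd45",
                      "nuclear_area", "nuclear_eccentricity", "cellular_area",
                      "cellular_eccentricity"), names(events))
  long <- do.call(rbind, lapply(pars, function(p) data.frame(
    parameter = p, value = events[[p]],
    disease_state = if ("disease_state" %in% names(events))
      events$disease_state else "all")))
  ggplot2::ggplot(long, ggplot2::aes(.data$value, colour = .data$disease_state)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_minimal()
}
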