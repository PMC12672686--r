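#' Phenotype classes and marker calling
#'
#' Events are characterised by the immunofluorescence channels in which they
#' are positive and referred to by their positive markers only.  DAPI ("D")
#' gates events to nucleated cells; CD138, BCMA (with membrane vs perinuclear
#' localization) and CD45 define 12 marker-combination classes:
#' \{CD138 +/-\} x \{BCMA negative/Memb/Peri\} x \{CD45 +/-\}.
#'
#' @name phenotype
NULL

#' The three BCMA localization states
#' @export
bcma_states <- function() c("negative", "Memb", "Peri")

#' Canonical name for one marker combination
#'
#' @param cd138_pos logical, CD138 positivity.
#' @param bcma_state one of `"negative"`, `"Memb"`, `"Peri"` (recycled).
#' @param cd45_pos logical, CD45 positivity.
#' @return character vector of canonical class names, e.g.
#'   `"D | 138 | BCMA-Memb"`.  The all-negative combination is `"D"`
#'   (a DAPI-only nucleated event).
#' @export
phenotype_class_name <- function(cd138_pos, bcma_state, cd45_pos) {
  n <- max(length(cd138_pos), length(bcma_state), length(cd45_pos))
  cd138_pos <- rep_len(as.logical(cd138_pos), n)
  bcma_state <- rep_len(as.character(bcma_state), n)
  cd45_pos <- rep_len(as.logical(cd45_pos), n)
  if (!all(bcma_state %in% bcma_states()))
    stop("bcma_state must be one of: ", paste(bcma_states(), collapse = ", "))
  vapply(seq_len(n), function(i) {
    parts <- "D"
    if (cd138_pos[i]) parts <- c(parts, "138")
    if (bcma_state[i] != "negative")
      parts <- c(parts, paste0("BCMA-", bcma_state[i]))
    if (cd45_pos[i]) parts <- c(parts, "45")
    paste(parts, collapse = " | ")
  }, character(1))
}

#' All 12 phenotype class names
#'
#' @return character vector of the 12 canonical class names, in the fixed
#'   enumeration order CD138(-,+) x BCMA(negative,Memb,Peri) x CD45(-,+).
#' @export
phenotype_classes <- function() {
  grid <- expand.grid(cd45 = c(FALSE, TRUE),
                      bcma = bcma_states(),
                      cd138 = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  phenotype_class_name(grid$cd138, grid$bcma, grid$cd45)
}

#' Aggregate phenotype categories
#'
#' Derived categories used in cohort reporting: all cells, CD138-positive
#' cells, BCMA-positive cells and the two BCMA localization subsets.
#'
#' @return named list mapping aggregate names to their member classes.
#' @export
aggregate_categories <- function() {
  cls <- phenotype_classes()
  list(
    "Total Cells"           = cls,
    "Total 138+ Cells"      = cls[grepl("\\| 138", cls)],
    "Total BCMA+ Cells"     = cls[grepl("BCMA-", cls)],
    "Total BCMA-Memb Cells" = cls[grepl("BCMA-Memb", cls)],
    "Total BCMA-Peri Cells" = cls[grepl("BCMA-Peri", cls)]
  )
}

#' Estimate per-channel positivity cutoffs from the common population
#'
#' For each marker channel the negative subpopulation is identified by an
#' Otsu split of the intensity histogram (needed because the dominant
#' leukocyte background is itself CD45-positive, so a blanket
#' whole-population statistic cannot serve every channel), and the cutoff is
#' that subpopulation's median plus `k` robust standard deviations (scaled
#' MAD).  The DAPI gate is a fraction of the nucleated population's median
#' DAPI intensity, since common events are nucleated by construction.
#'
#' @param events CellEvent table with `median_*` intensity columns.
#' @param common logical mask of events to treat as the common population
#'   (default all).
#' @param k multiplier on the MAD (default 5).
#' @return named numeric cutoffs for `dapi`, `cd138`, `bcma`, `cd45`.
#' @export
estimate_positivity_thresholds <- function(events, common = NULL, k = 5) {
  if (is.null(common)) common <- rep(TRUE, nrow(events))
  chans <- c("cd138", "bcma", "cd45")
  negs <- lapply(chans, function(ch) {
    x <- events[[paste0("median_", ch)]][common]
    split <- intensity_otsu(x)
    neg <- x[x <= split]
    pos <- x[x > split]
    # a credible split must separate two modes; under heavy class imbalance
    # Otsu happily bisects the single dominant mode, which shows up as the
    # two halves sitting within a few robust SDs of each other
    credible <- length(neg) >= 10 && length(pos) >= 1 &&
      (stats::median(pos) - stats::median(neg)) >
        3 * (stats::mad(neg) + stats::mad(pos))
    if (credible) neg else NULL
  })
  names(negs) <- chans
  # pooled background fluorescence from channels with a clear negative mode
  # (the common leukocyte population is negative for the plasma-cell
  # markers); channels without one - typically the pan-leukocyte marker,
  # positive on nearly every common event - borrow it, since scanner
  # normalization puts all channels on a shared intensity scale
  pool <- unlist(negs[!vapply(negs, is.null, logical(1))])
  out <- vapply(chans, function(ch) {
    neg <- negs[[ch]]
    if (is.null(neg)) neg <- pool
    if (is.null(neg) || !length(neg))
      neg <- events[[paste0("median_", ch)]][common]
    stats::median(neg) + k * stats::mad(neg)
  }, numeric(1))
  c(dapi = 0.25 * stats::median(events$median_dapi[common]), out)
}

# Otsu split of an intensity vector on a 256-bin histogram over [0, 255]
intensity_otsu <- function(x) {
  img <- EBImage::Image(matrix(pmin(pmax(x, 0), 255) / 255, ncol = 1))
  255 * EBImage::otsu(img, range = c(0, 1), levels = 256)
}

#' Call per-channel marker positivity
#'
#' A marker is positive iff its median intensity is greater than or equal to
#' the channel cutoff (inclusive rule, so an event exactly at the cutoff is
#' positive).  BCMA is additionally considered positive when either
#' localization score reaches the cutoff, since a thin membrane ring can
#' leave the whole-cell median low.
#'
#' @param events CellEvent table.
#' @param thresholds named cutoffs as from [estimate_positivity_thresholds()].
#' @return data.frame with logical `dapi_pos`, `cd138_pos`, `cd45_pos` and
#'   `bcma_state` (`"negative"`, `"Memb"` or `"Peri"`).
#' @export
call_positivity <- function(events, thresholds) {
  need <- c("median_dapi", "median_cd138", "median_bcma", "median_cd45",
            "bcma_membrane_score", "bcma_perinuclear_score")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table is missing channel features: ",
         paste(miss, collapse = ", "))
  stopifnot(all(is.finite(thresholds)))
  bcma_pos <- events$median_bcma >= thresholds[["bcma"]] |
    events$bcma_membrane_score >= thresholds[["bcma"]] |
    events$bcma_perinuclear_score >= thresholds[["bcma"]]
  data.frame(
    dapi_pos  = events$median_dapi >= thresholds[["dapi"]],
    cd138_pos = events$median_cd138 >= thresholds[["cd138"]],
    bcma_state = call_bcma_localization(events, thresholds, bcma_pos),
    cd45_pos  = events$median_cd45 >= thresholds[["cd45"]],
    stringsAsFactors = FALSE
  )
}

#' Call BCMA subcellular localization
#'
#' For BCMA-positive events the membrane and perinuclear band scores are
#' compared: the state is `Memb` when the membrane score is at least
#' `contrast_ratio` times the perinuclear score, `Peri` in the reverse case,
#' and otherwise whichever score is larger wins (exact tie goes to `Memb`).
#' BCMA-negative events get state `"negative"`.
#'
#' @param events CellEvent table.
#' @param thresholds named cutoffs (used for the positivity gate when
#'   `bcma_pos` is not supplied).
#' @param bcma_pos optional logical vector of BCMA positivity.
#' @param contrast_ratio dominance ratio between the two band scores
#'   (default 1.2).
#' @return character vector of localization states.
#' @export
call_bcma_localization <- function(events, thresholds, bcma_pos = NULL,
                                   contrast_ratio = 1.2) {
  m <- events$bcma_membrane_score
  p <- events$bcma_perinuclear_score
  if (is.null(bcma_pos)) {
    bcma_pos <- events$median_bcma >= thresholds[["bcma"]] |
      m >= thresholds[["bcma"]] | p >= thresholds[["bcma"]]
  }
  state <- ifelse(m >= contrast_ratio * p, "Memb",
           ifelse(p >= contrast_ratio * m, "Peri",
           ifelse(m >= p, "Memb", "Peri")))
  state[!bcma_pos] <- "negative"
  state
}

#' Assign the phenotype class from marker calls
#'
#' Pure lookup on (CD138, BCMA state, CD45); bijective from the 12 call
#' combinations onto the 12 canonical names.  DAPI-negative events are not
#' cells and must be excluded before classification.
#'
#' @param calls data.frame as returned by [call_positivity()].
#' @return character vector of class names.
#' @export
assign_class <- function(calls) {
  if (any(!calls$dapi_pos))
    stop("assign_class received DAPI-negative events; ",
         "filter non-nucleated events before classification")
  phenotype_class_name(calls$cd138_pos, calls$bcma_state, calls$cd45_pos)
}

#' Phenotype a curated event table
#'
#' Calls positivity, localization and class for every event.  DAPI-negative
#' events are returned separately (they are not nucleated cells and do not
#' receive a class).
#'
#' @param events CellEvent table.
#' @param thresholds optional fixed cutoffs; estimated from the table when
#'   `NULL`.
#' @param contrast_ratio BCMA localization dominance ratio.
#' @return list with `events` (phenotyped table gaining `class`, `cd138_pos`,
#'   `bcma_state`, `cd45_pos` columns), `excluded` (DAPI-negative rows) and
#'   `thresholds` used.
#' @export
phenotype_events <- function(events, thresholds = NULL, contrast_ratio = 1.2) {
  if (is.null(thresholds)) thresholds <- estimate_positivity_thresholds(events)
  calls <- call_positivity(events, thresholds)
  calls$bcma_state <- call_bcma_localization(
    events, thresholds, bcma_pos = calls$bcma_state != "negative",
    contrast_ratio = contrast_ratio)
  keep <- calls$dapi_pos
  out <- events[keep, , drop = FALSE]
  out$cd138_pos <- calls$cd138_pos[keep]
  out$bcma_state <- calls$bcma_state[keep]
  out$cd45_pos <- calls$cd45_pos[keep]
  out$class <- assign_class(calls[keep, , drop = FALSE])
  list(events = out, excluded = events[!keep, , drop = FALSE],
       thresholds = thresholds)
}

#' Count events per class and aggregate category
#'
#' @param classes character vector of class names (one per event).
#' @return named integer vector over the 12 classes followed by the 5
#'   aggregates.  Each event is counted in exactly one class; aggregates are
#'   sums of member classes.
#' @export
count_classes <- function(classes) {
  cls <- phenotype_classes()
  bad <- setdiff(unique(classes), cls)
  if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  base <- table(factor(classes, levels = cls))
  aggs <- vapply(aggregate_categories(), function(m) sum(base[m]), numeric(1))
  counts <- c(as.integer(base), as.integer(aggs))
  names(counts) <- c(cls, names(aggs))
  counts
}
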