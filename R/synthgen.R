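#' Synthetic slide, event-table and cohort generation
#'
#' The generator emulates the data a slide-based non-enrichment liquid biopsy
#' produces: a dominant white-blood-cell background, rare planted
#' subpopulations drawn from the 12 phenotype classes (including membrane vs
#' perinuclear BCMA localization), technical artifacts/debris, per-channel
#' intensity noise, per-sample blood counts and plating metadata, and a
#' 4-group disease cohort (MGUS/SMM/NDMM/RRMM).  Every generated object
#' carries full ground truth so that detection, curation, phenotyping and
#' cohort statistics can be validated end to end.
#'
#' @name synthgen
NULL

# Truth-model intensity bands: negative channel levels live in [0, 30],
# positive levels in [70, 255]; 50 separates them exactly for ground truth.
.TRUTH_CUTOFF <- 50

#' Channel names of a four-channel immunofluorescence frame
#' @export
channel_names <- function() c("dapi", "cd138", "bcma", "cd45")

#' Morphometric/intensity feature columns of a CellEvent table
#'
#' The feature space used by rare-event detection and artifact curation.
#' @export
morphometric_feature_names <- function() {
  c("nuclear_area", "nuclear_eccentricity", "cellular_area",
    "cellular_eccentricity", "cellular_perimeter", "solidity",
    "median_dapi", "median_cd138", "median_bcma", "median_cd45",
    "mad_dapi", "mad_cd138", "mad_bcma", "mad_cd45",
    "bcma_membrane_score", "bcma_perinuclear_score")
}

#' Per-disease-state rare-class incidence presets (cells/mL)
#'
#' Directions of the state differences follow the cohort comparisons the
#' pipeline is designed to recover (CD138/BCMA-membrane plasma-cell burden
#' rising from MGUS through SMM to overt disease; perinuclear-BCMA and
#' CD45-coexpressing subsets dropping after treatment in RRMM).  The
#' magnitudes are simulation parameters of this package, in cells/mL.
#'
#' @return named list of named incidence vectors, one per disease state.
#' @export
incidence_presets <- function() {
  cls <- phenotype_classes()
  mk <- function(...) {
    v <- stats::setNames(rep(0, length(cls)), cls)
    inc <- c(...)
    v[names(inc)] <- inc
    v
  }
  list(
    MGUS = mk("D" = 0.6, "D | 45" = 0.8, "D | 138" = 0.19,
              "D | 138 | 45" = 0.4, "D | BCMA-Memb" = 0.5,
              "D | BCMA-Peri" = 0.8, "D | BCMA-Memb | 45" = 1.54,
              "D | BCMA-Peri | 45" = 1.8, "D | 138 | BCMA-Memb" = 1.0,
              "D | 138 | BCMA-Peri" = 0.4, "D | 138 | BCMA-Memb | 45" = 0.5,
              "D | 138 | BCMA-Peri | 45" = 0.45),
    SMM = mk("D" = 0.6, "D | 45" = 0.8, "D | 138" = 0.9,
             "D | 138 | 45" = 0.5, "D | BCMA-Memb" = 0.55,
             "D | BCMA-Peri" = 0.9, "D | BCMA-Memb | 45" = 1.83,
             "D | BCMA-Peri | 45" = 2.77, "D | 138 | BCMA-Memb" = 2.73,
             "D | 138 | BCMA-Peri" = 0.45, "D | 138 | BCMA-Memb | 45" = 0.6,
             "D | 138 | BCMA-Peri | 45" = 0.5),
    NDMM = mk("D" = 0.6, "D | 45" = 0.8, "D | 138" = 1.84,
              "D | 138 | 45" = 0.6, "D | BCMA-Memb" = 0.6,
              "D | BCMA-Peri" = 1.5, "D | BCMA-Memb | 45" = 3.02,
              "D | BCMA-Peri | 45" = 4.17, "D | 138 | BCMA-Memb" = 3.45,
              "D | 138 | BCMA-Peri" = 0.55, "D | 138 | BCMA-Memb | 45" = 0.8,
              "D | 138 | BCMA-Peri | 45" = 0.6),
    RRMM = mk("D" = 0.6, "D | 45" = 0.8, "D | 138" = 2.32,
              "D | 138 | 45" = 0.5, "D | BCMA-Memb" = 0.7,
              "D | BCMA-Peri" = 0.7, "D | BCMA-Memb | 45" = 1.85,
              "D | BCMA-Peri | 45" = 1.9, "D | 138 | BCMA-Memb" = 3.61,
              "D | 138 | BCMA-Peri" = 0.5, "D | 138 | BCMA-Memb | 45" = 0.7,
              "D | 138 | BCMA-Peri | 45" = 0.55)
  )
}

#' Specification of one synthetic blood sample
#'
#' @param sample_id sample identifier.
#' @param disease_state one of MGUS, SMM, NDMM, RRMM.
#' @param n_background_cells number of ordinary leukocyte events generated at
#'   desk scale (the full plated population is represented by the CBC and
#'   plating metadata, not generated event-by-event).
#' @param class_incidence named vector of expected cells/mL per phenotype
#'   class; defaults to the preset for `disease_state`.
#' @param artifact_rate fraction of events that are debris/artifacts.
#' @param cbc_nucleated_per_ml nucleated cells per mL of blood at processing.
#' @param blood_volume_ml drawn blood volume in mL.
#' @param n_slides slides plated per sample.
#' @param cells_per_slide nucleated cells plated per slide (approximately
#'   3 million on the assay this emulates).
#' @param cells_per_frame rendering density used by [generate_frame()].
#' @return object of class `raredrop_sample_spec`.
#' @export
sample_spec <- function(sample_id = "S1",
                        disease_state = c("MGUS", "SMM", "NDMM", "RRMM"),
                        n_background_cells = 2000,
                        class_incidence = NULL,
                        artifact_rate = 0.05,
                        cbc_nucleated_per_ml = 6e6,
                        blood_volume_ml = 8,
                        n_slides = 2,
                        cells_per_slide = 3e6,
                        cells_per_frame = 50) {
  disease_state <- match.arg(disease_state)
  if (is.null(class_incidence))
    class_incidence <- incidence_presets()[[disease_state]]
  stopifnot(
    n_background_cells >= 0, all(class_incidence >= 0),
    artifact_rate >= 0, artifact_rate < 1,
    cbc_nucleated_per_ml > 0, blood_volume_ml > 0,
    n_slides >= 1, cells_per_slide > 0, cells_per_frame >= 0
  )
  bad <- setdiff(names(class_incidence), phenotype_classes())
  if (length(bad)) stop("unknown incidence class(es): ",
                        paste(bad, collapse = ", "))
  structure(list(
    sample_id = sample_id, disease_state = disease_state,
    n_background_cells = as.integer(n_background_cells),
    class_incidence = class_incidence, artifact_rate = artifact_rate,
    cbc_nucleated_per_ml = cbc_nucleated_per_ml,
    blood_volume_ml = blood_volume_ml, n_slides = as.integer(n_slides),
    cells_per_slide = cells_per_slide,
    cells_per_frame = as.integer(cells_per_frame)
  ), class = "raredrop_sample_spec")
}

#' Plating/CBC metadata needed to convert counts to cells/mL
#' @param spec a [sample_spec()].
#' @return list with `n_analyzed_cells`, `cbc_total_nucleated`,
#'   `blood_volume_ml`.
#' @export
sample_metadata <- function(spec) {
  list(n_analyzed_cells = spec$n_slides * spec$cells_per_slide,
       cbc_total_nucleated = spec$cbc_nucleated_per_ml * spec$blood_volume_ml,
       blood_volume_ml = spec$blood_volume_ml)
}

# Effective analyzed blood volume in mL: the fraction of the draw whose cells
# end up on analyzed slides.  Expected planted count = incidence * this.
effective_volume_ml <- function(spec) {
  meta <- sample_metadata(spec)
  meta$blood_volume_ml * meta$n_analyzed_cells / meta$cbc_total_nucleated
}

# --- truth draws ------------------------------------------------------------

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.neg_level <- function(n) .clip(abs(stats::rnorm(n, 8, 4)), 0, 30)
.pos_level <- function(n, mean = 140, sd = 25) .clip(stats::rnorm(n, mean, sd), 70, 255)

# Draw truth rows for n events of one kind ("background", a class name, or
# "ARTIFACT").  Returns a data.frame of CellTruth fields.
draw_truth <- function(n, kind) {
  if (n == 0) return(NULL)
  if (kind == "BACKGROUND") {
    nuc_r <- .clip(stats::rnorm(n, 9, 1.2), 5, 14)
    ratio <- stats::runif(n, 1.15, 1.5)
    lv <- cbind(dapi = .clip(stats::rnorm(n, 180, 20), 70, 255),
                cd138 = .neg_level(n),
                bcma = .neg_level(n),
                cd45 = .pos_level(n, 120, 25))
    loc <- rep("none", n)
  } else if (kind == "ARTIFACT") {
    blob <- stats::runif(n) < 0.5
    nuc_r <- ifelse(blob, stats::runif(n, 2, 5), stats::runif(n, 1.5, 3))
    ratio <- stats::runif(n, 1.0, 1.1)
    hot <- sample.int(3, n, replace = TRUE)   # one saturated marker channel
    lv <- cbind(dapi = ifelse(blob, .clip(abs(stats::rnorm(n, 15, 8)), 0, 40),
                              .clip(stats::rnorm(n, 100, 60), 0, 255)),
                cd138 = ifelse(hot == 1, 250, .neg_level(n)),
                bcma = ifelse(hot == 2, 250, .neg_level(n)),
                cd45 = ifelse(hot == 3, 250, .neg_level(n)))
    loc <- rep("none", n)
  } else {
    flags <- parse_class_flags(kind)
    nuc_r <- .clip(stats::rnorm(n, 11, 1.5), 6, 16)
    ratio <- stats::runif(n, 1.3, 1.8)
    lv <- cbind(
      dapi = .clip(stats::rnorm(n, 180, 20), 70, 255),
      cd138 = if (flags$cd138) .pos_level(n) else .neg_level(n),
      bcma = if (flags$bcma != "negative") .pos_level(n, 130, 25) else .neg_level(n),
      cd45 = if (flags$cd45) .pos_level(n, 120, 25) else .neg_level(n))
    loc <- rep(switch(flags$bcma, negative = "none", Memb = "membrane",
                      Peri = "perinuclear"), n)
  }
  data.frame(
    true_class = kind,
    true_nuclear_radius = nuc_r,
    true_cell_radius = nuc_r * ratio,
    true_dapi = lv[, "dapi"], true_cd138 = lv[, "cd138"],
    true_bcma = lv[, "bcma"], true_cd45 = lv[, "cd45"],
    bcma_localization = loc,
    stringsAsFactors = FALSE
  )
}

#' Parse a canonical class name back into marker flags
#' @param class_name canonical class name.
#' @return list with `cd138` (logical), `bcma` (state), `cd45` (logical).
#' @export
parse_class_flags <- function(class_name) {
  parts <- strsplit(class_name, " | ", fixed = TRUE)[[1]]
  if (parts[1] != "D") stop("not a canonical class name: ", class_name)
  bcma <- "negative"
  if ("BCMA-Memb" %in% parts) bcma <- "Memb"
  if ("BCMA-Peri" %in% parts) bcma <- "Peri"
  list(cd138 = "138" %in% parts, bcma = bcma, cd45 = "45" %in% parts)
}

#' Recover the truth class from true channel levels
#'
#' Applies the phenotype truth table to the generator's noiseless channel
#' levels; used by the ground-truth-consistency checks.
#' @param truth CellTruth table.
#' @return character class names ("ARTIFACT" rows are passed through).
#' @export
truth_class_from_levels <- function(truth) {
  out <- character(nrow(truth))
  art <- truth$true_class == "ARTIFACT"
  out[art] <- "ARTIFACT"
  if (any(!art)) {
    t2 <- truth[!art, ]
    state <- ifelse(t2$true_bcma < .TRUTH_CUTOFF, "negative",
             ifelse(t2$bcma_localization == "membrane", "Memb", "Peri"))
    out[!art] <- phenotype_class_name(t2$true_cd138 >= .TRUTH_CUTOFF, state,
                                      t2$true_cd45 >= .TRUTH_CUTOFF)
  }
  out
}

# Measured CellEvent features from truth rows (the measurement noise model:
# additive Gaussian intensity noise, multiplicative area jitter).
measure_events <- function(truth, sd_intensity = 5) {
  n <- nrow(truth)
  nuc_r <- truth$true_nuclear_radius
  cel_r <- truth$true_cell_radius
  art <- truth$true_class == "ARTIFACT"
  nuc_ecc <- ifelse(art, stats::runif(n, 0.7, 0.95),
                    stats::rbeta(n, 2, 4) * 0.8)
  cel_ecc <- ifelse(art, stats::runif(n, 0.7, 0.95),
                    stats::rbeta(n, 2, 4) * 0.7)
  jig <- function(x) x * stats::runif(n, 0.95, 1.05)
  noisy <- function(x) .clip(x + stats::rnorm(n, 0, sd_intensity), 0, 255)
  # BCMA band scores follow the localization pattern: a membrane ring
  # concentrates signal at the cell edge, a perinuclear pattern just outside
  # the nucleus; unlocalized signal spreads evenly.
  memb_mult <- ifelse(truth$bcma_localization == "membrane",
                      stats::runif(n, 1.5, 2.2),
               ifelse(truth$bcma_localization == "perinuclear",
                      stats::runif(n, 0.25, 0.55), stats::runif(n, 0.6, 1.0)))
  peri_mult <- ifelse(truth$bcma_localization == "perinuclear",
                      stats::runif(n, 1.5, 2.2),
               ifelse(truth$bcma_localization == "membrane",
                      stats::runif(n, 0.25, 0.55), stats::runif(n, 0.6, 1.0)))
  nuclear_area <- jig(pi * nuc_r^2)
  cellular_area <- pmax(jig(pi * cel_r^2), nuclear_area)
  perim_mult <- ifelse(art, stats::runif(n, 1.3, 2.0), stats::runif(n, 1.0, 1.15))
  data.frame(
    nuclear_area = nuclear_area,
    nuclear_eccentricity = nuc_ecc,
    cellular_area = cellular_area,
    cellular_eccentricity = cel_ecc,
    cellular_perimeter = 2 * pi * cel_r * perim_mult,
    solidity = ifelse(art, stats::runif(n, 0.5, 0.9), stats::runif(n, 0.92, 0.99)),
    median_dapi = noisy(truth$true_dapi),
    median_cd138 = noisy(truth$true_cd138),
    median_bcma = noisy(truth$true_bcma),
    median_cd45 = noisy(truth$true_cd45),
    mad_dapi = .clip(truth$true_dapi * 0.1 + stats::rnorm(n, 0, 2), 0, 255),
    mad_cd138 = .clip(truth$true_cd138 * 0.1 + stats::rnorm(n, 0, 2), 0, 255),
    mad_bcma = .clip(truth$true_bcma * 0.1 + stats::rnorm(n, 0, 2), 0, 255),
    mad_cd45 = .clip(truth$true_cd45 * 0.1 + stats::rnorm(n, 0, 2), 0, 255),
    bcma_membrane_score = noisy(truth$true_bcma * memb_mult),
    bcma_perinuclear_score = noisy(truth$true_bcma * peri_mult),
    stringsAsFactors = FALSE
  )
}

#' Generate a per-sample cell-event table with ground truth
#'
#' Samples morphometric and intensity features directly from the same
#' generative model the frame renderer uses, so detection and statistics can
#' be exercised at scales where rendering every frame would be wasteful.
#' Event count = background + planted rare counts (Poisson around
#' incidence x effective analyzed volume) + artifacts (binomial).
#'
#' @param spec a [sample_spec()].
#' @param seed integer seed; fixed seed gives identical tables.
#' @return list with `events` (CellEvent table) and `truth` (CellTruth table),
#'   row-aligned via `cell_id`.
#' @export
generate_event_table <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "raredrop_sample_spec"))
  set.seed(seed)
  ev <- effective_volume_ml(spec)
  inc <- spec$class_incidence[spec$class_incidence > 0]
  rare_n <- if (length(inc)) stats::rpois(length(inc), inc * ev) else integer(0)
  names(rare_n) <- names(inc)
  n_bio <- spec$n_background_cells + sum(rare_n)
  n_art <- stats::rbinom(1, n_bio, spec$artifact_rate)
  pieces <- c(list(draw_truth(spec$n_background_cells, "BACKGROUND")),
              lapply(seq_along(rare_n),
                     function(i) draw_truth(rare_n[i], names(rare_n)[i])),
              list(draw_truth(n_art, "ARTIFACT")))
  truth <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(truth)) {
    truth <- draw_truth(0, "BACKGROUND")
  }
  n <- if (is.null(truth)) 0 else nrow(truth)
  if (n == 0) {
    empty <- measure_events(draw_truth(1, "BACKGROUND"))[0, ]
    events <- cbind(data.frame(cell_id = character(0), sample_id = character(0),
                               slide = integer(0), frame = integer(0),
                               x = numeric(0), y = numeric(0)), empty)
    truth0 <- data.frame(cell_id = character(0), true_class = character(0))
    return(list(events = events, truth = truth0))
  }
  ord <- sample.int(n)
  truth <- truth[ord, , drop = FALSE]
  feats <- measure_events(truth)
  ids <- sprintf("%s-%06d", spec$sample_id, seq_len(n))
  events <- cbind(
    data.frame(
      cell_id = ids, sample_id = spec$sample_id,
      slide = sample.int(spec$n_slides, n, replace = TRUE),
      frame = sample.int(2304, n, replace = TRUE),
      x = stats::runif(n, 0, 1024), y = stats::runif(n, 0, 1024),
      stringsAsFactors = FALSE),
    feats)
  truth <- cbind(data.frame(cell_id = ids, stringsAsFactors = FALSE), truth)
  rownames(events) <- rownames(truth) <- NULL
  list(events = events, truth = truth)
}

# --- frame rendering --------------------------------------------------------

#' Render one synthetic multichannel field of view
#'
#' Nuclei are filled ellipses in the DAPI channel; CD138/CD45 fill the cell
#' body per the event's class; BCMA is rendered either as a membrane ring (a
#' band within `ring_px` outside the cell boundary) or as a perinuclear
#' annulus (a band 1 to `annulus_px` px outside the nucleus).  Gaussian
#' background noise is always added; Poisson shot noise optionally.
#'
#' @param spec a [sample_spec()]; `spec$cells_per_frame` cells are rendered
#'   with class composition proportional to the spec's background/incidence
#'   structure, each being an artifact with probability `spec$artifact_rate`.
#' @param frame_index frame number within the slide.
#' @param seed integer seed; fixed seed gives identical pixels.
#' @param width,height frame dimensions in pixels.
#' @param background_mean,background_sd Gaussian background level and noise.
#' @param poisson_noise add Poisson shot noise.
#' @param ring_px,annulus_px localization band geometry in pixels.
#' @return list with `frame` (a `raredrop_frame`: `pixels` array
#'   height x width x 4, `channels`, metadata) and `truth` (CellTruth table
#'   with pixel centers).
#' @export
generate_frame <- function(spec, frame_index = 1, seed = 1,
                           width = 1024, height = 1024,
                           background_mean = 20, background_sd = 2,
                           poisson_noise = FALSE,
                           ring_px = 3, annulus_px = 4) {
  stopifnot(inherits(spec, "raredrop_sample_spec"))
  if (width <= 0 || height <= 0) stop("frame dimensions must be positive")
  set.seed(seed + frame_index)
  n <- spec$cells_per_frame

  # class composition: background vs planted classes, proportional to the
  # sample-level expected counts
  inc <- spec$class_incidence[spec$class_incidence > 0]
  w_rare <- inc * effective_volume_ml(spec)
  weights <- c(BACKGROUND = spec$n_background_cells, w_rare)
  truth <- NULL
  if (n > 0) {
    if (sum(weights) <= 0) stop("spec generates no cells but cells_per_frame > 0")
    kind <- sample(names(weights), n, replace = TRUE, prob = weights)
    kind[stats::runif(n) < spec$artifact_rate] <- "ARTIFACT"
    parts <- lapply(unique(kind), function(k) draw_truth(sum(kind == k), k))
    truth <- do.call(rbind, parts)
    # rendered geometry must leave room for a perinuclear annulus that is
    # distinct from the cell boundary: enforce a minimum cytoplasm thickness
    truth$true_cell_radius <- pmax(truth$true_cell_radius,
                                   truth$true_nuclear_radius + annulus_px + 2)
  }

  img <- array(0, dim = c(height, width, 4),
               dimnames = list(NULL, NULL, channel_names()))
  for (ch in 1:4) {
    img[, , ch] <- matrix(stats::rnorm(height * width, background_mean,
                                       if (background_sd > 0) background_sd else 0),
                          height, width)
  }

  if (!is.null(truth) && nrow(truth) > 0) {
    n <- nrow(truth)
    # place cells with a minimum center separation so objects do not touch
    margin <- truth$true_cell_radius + ring_px + 2
    cx <- cy <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:300) {
        px <- stats::runif(1, margin[i], width - margin[i])
        py <- stats::runif(1, margin[i], height - margin[i])
        if (i == 1 || all(sqrt((px - cx[seq_len(i - 1)])^2 +
                               (py - cy[seq_len(i - 1)])^2) >=
                          margin[i] + margin[seq_len(i - 1)])) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("overlapping-cell capacity exceeded: placed ", i - 1,
                    " of ", n, " cells in a ", width, "x", height, " frame")
      cx[i] <- px; cy[i] <- py
    }
    theta <- stats::runif(n, 0, pi)
    ecc_n <- stats::rbeta(n, 2, 4) * 0.8
    ecc_c <- stats::rbeta(n, 2, 4) * 0.7
    for (i in seq_len(n)) {
      img <- render_cell(img, truth[i, ], cx[i], cy[i], theta[i],
                         ecc_n[i], ecc_c[i], ring_px, annulus_px)
    }
    # 0-based pixel coordinates (x = column), matching feature extraction
    truth$true_x <- cx - 1
    truth$true_y <- cy - 1
    truth$cell_id <- sprintf("%s-f%04d-%04d", spec$sample_id, frame_index,
                             seq_len(n))
  }
  if (poisson_noise) {
    img[] <- stats::rpois(length(img), pmax(img, 0))
  }
  img <- .clip(img, 0, 255)
  frame <- structure(list(
    pixels = img, channels = channel_names(), sample_id = spec$sample_id,
    frame_index = frame_index, background_mean = background_mean
  ), class = "raredrop_frame")
  list(frame = frame, truth = truth)
}

# Paint one cell into the 4-channel image.  Ellipse membership is computed on
# a local bounding box via the normalized elliptical radius; the localization
# bands convert that radius to an approximate pixel offset from the boundary.
render_cell <- function(img, tr, cx, cy, theta, ecc_n, ecc_c,
                        ring_px, annulus_px) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r_n <- tr$true_nuclear_radius
  r_c <- tr$true_cell_radius
  # semi-axes preserving area pi*r^2 at eccentricity e
  ax <- function(r, e) {
    b <- r * (1 - e^2)^(1 / 4); a <- r^2 / b; c(a = a, b = b)
  }
  an <- ax(r_n, ecc_n); ac <- ax(r_c, ecc_c)
  ext <- ceiling(max(ac["a"], an["a"]) + max(ring_px, annulus_px) + 2)
  rows <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
  dy <- rows - cy
  dx <- cols - cx
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
  u <- function(a) {
    xr <- (DX * cos(theta) + DY * sin(theta)) / a["a"]
    yr <- (-DX * sin(theta) + DY * cos(theta)) / a["b"]
    sqrt(xr^2 + yr^2)
  }
  un <- u(an); uc <- u(ac)
  nuc <- un <= 1
  cell <- uc <= 1
  ring <- uc > 1 & (uc - 1) * min(ac) <= ring_px
  annulus <- un > 1 & (un - 1) * min(an) >= 1 & (un - 1) * min(an) <= annulus_px
  paint <- function(ch, mask, level) {
    sub <- img[rows, cols, ch]
    sub[mask] <- pmax(sub[mask], level)
    img[rows, cols, ch] <<- sub
    invisible(NULL)
  }
  is_art <- tr$true_class == "ARTIFACT"
  if (is_art || tr$true_dapi > 0) paint(1, nuc, tr$true_dapi)
  body <- if (is_art) nuc | cell else cell
  paint(2, body, tr$true_cd138)
  paint(4, body, tr$true_cd45)
  if (tr$bcma_localization == "membrane") {
    paint(3, ring, tr$true_bcma)
    paint(3, cell, tr$true_bcma * 0.2)
  } else if (tr$bcma_localization == "perinuclear") {
    paint(3, annulus, tr$true_bcma)
    paint(3, cell & !annulus, tr$true_bcma * 0.2)
  } else {
    paint(3, body, tr$true_bcma)
  }
  img
}

# --- cohort -----------------------------------------------------------------

#' Configuration for a synthetic disease cohort
#'
#' @param n_per_state named sample counts; `layout = "table"` switches to the
#'   alternative (11, 20, 19, 18) breakdown.
#' @param presets per-state incidence presets.
#' @param n_background_cells,artifact_rate passed to each [sample_spec()].
#' @param covariate_correlation knob in `[0, 1]` controlling how strongly the
#'   continuous clinical covariate tracks the planted CD138/BCMA-membrane
#'   plasma-cell count (0 = independent).
#' @param seed integer master seed.
#' @return object of class `raredrop_cohort_config`.
#' @export
cohort_config <- function(n_per_state = NULL,
                          presets = incidence_presets(),
                          n_background_cells = 2000,
                          artifact_rate = 0.05,
                          covariate_correlation = 0.6,
                          seed = 1,
                          layout = c("text", "table")) {
  layout <- match.arg(layout)
  if (is.null(n_per_state)) {
    n_per_state <- if (layout == "text") {
      c(MGUS = 11, SMM = 21, NDMM = 19, RRMM = 17)
    } else {
      c(MGUS = 11, SMM = 20, NDMM = 19, RRMM = 18)
    }
  }
  stopifnot(all(n_per_state >= 0),
            all(names(n_per_state) %in% c("MGUS", "SMM", "NDMM", "RRMM")),
            covariate_correlation >= 0, covariate_correlation <= 1)
  structure(list(n_per_state = n_per_state, presets = presets,
                 n_background_cells = n_background_cells,
                 artifact_rate = artifact_rate,
                 covariate_correlation = covariate_correlation,
                 seed = as.integer(seed)),
            class = "raredrop_cohort_config")
}

#' Generate a full synthetic cohort
#'
#' One sample spec per patient, per-sample event/truth tables, and a clinical
#' covariate table (age, an M-spike-like continuous marker, binary
#' cytogenetic flags) whose association with the planted plasma-cell burden
#' is controlled by `covariate_correlation`.
#'
#' @param config a [cohort_config()].
#' @return list with `specs`, `samples` (named list of
#'   `generate_event_table()` results) and `clinical` (data.frame).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "raredrop_cohort_config"))
  set.seed(config$seed)
  states <- rep(names(config$n_per_state), config$n_per_state)
  n <- length(states)
  ids <- sprintf("P%03d", seq_len(n))
  seeds <- sample.int(2^31 - 2, n)
  specs <- lapply(seq_len(n), function(i) {
    sample_spec(sample_id = ids[i], disease_state = states[i],
                n_background_cells = config$n_background_cells,
                class_incidence = config$presets[[states[i]]],
                artifact_rate = config$artifact_rate)
  })
  names(specs) <- ids
  samples <- lapply(seq_len(n), function(i)
    generate_event_table(specs[[i]], seed = seeds[i]))
  names(samples) <- ids

  # clinical covariates, drawn after the event tables so the planted burden
  # can be tied to the continuous marker through the correlation knob
  set.seed(config$seed + 1L)
  key <- "D | 138 | BCMA-Memb"
  burden <- vapply(samples, function(s) sum(s$truth$true_class == key),
                   numeric(1))
  z_burden <- if (n > 1 && stats::sd(burden) > 0) as.numeric(scale(burden))
              else rep(0, n)
  k <- config$covariate_correlation
  latent <- k * z_burden + sqrt(max(0, 1 - k^2)) * stats::rnorm(n)
  clinical <- data.frame(
    sample_id = ids, disease_state = states,
    age = round(.clip(stats::rnorm(n, 64, 10), 38, 88)),
    m_spike = round(pmax(0, 1.0 + 0.8 * latent + stats::rnorm(n, 0, 0.2)), 2),
    del13 = as.integer(stats::runif(n) < stats::plogis(-1 + 1.5 * k * z_burden)),
    gain1q = as.integer(stats::runif(n) < stats::plogis(-1 + 1.0 * k * z_burden)),
    stringsAsFactors = FALSE
  )
  list(specs = specs, samples = samples, clinical = clinical, seed = config$seed)
}

#' Generate a labeled curation training set
#'
#' A mixed set of biological cells (background leukocytes plus rare-class
#' cells) and technical artifacts with truth labels, sized like a scaled-down
#' manually curated training archive.
#'
#' @param n total events.
#' @param artifact_fraction fraction of artifact events.
#' @param seed integer seed.
#' @return list with `events` (CellEvent features) and `label`
#'   (factor `cell`/`artifact`).
#' @export
generate_curation_set <- function(n = 2000, artifact_fraction = 0.3, seed = 1) {
  set.seed(seed)
  n_art <- round(n * artifact_fraction)
  n_cell <- n - n_art
  n_rare <- round(n_cell * 0.2)
  rare_cls <- sample(phenotype_classes(), n_rare, replace = TRUE)
  parts <- c(list(draw_truth(n_cell - n_rare, "BACKGROUND")),
             lapply(unique(rare_cls),
                    function(k) draw_truth(sum(rare_cls == k), k)),
             list(draw_truth(n_art, "ARTIFACT")))
  truth <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  ord <- sample.int(nrow(truth))
  truth <- truth[ord, , drop = FALSE]
  events <- measure_events(truth)
  label <- factor(ifelse(truth$true_class == "ARTIFACT", "artifact", "cell"),
                  levels = c("artifact", "cell"))
  list(events = events, label = label)
}
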