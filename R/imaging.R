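#' Segmentation and morphometric feature extraction
#'
#' Nuclei are segmented on the DAPI channel (Otsu threshold, hole filling,
#' watershed split on the distance transform, size filter); cells by a seeded
#' propagation from the nuclei over the summed marker channels, capped at a
#' maximum expansion beyond the nucleus.  Features follow the morphometric
#' parameter set used downstream: nuclear/cellular area and eccentricity,
#' per-channel median intensities, and the two BCMA localization band scores.
#'
#' Pixel convention: 0-based, x = column, y = row.
#'
#' @name imaging
NULL

# frame pixels are stored row(y) x col(x); EBImage wants x,y -> transpose
.as_ebimage <- function(mat) EBImage::Image(t(mat) / 255)

.get_channel <- function(frame, ch) {
  stopifnot(inherits(frame, "raredrop_frame"))
  i <- match(ch, frame$channels)
  if (is.na(i)) stop("frame is missing channel: ", ch)
  frame$pixels[, , i]
}

#' Segment nuclei in the DAPI channel
#'
#' @param frame a `raredrop_frame`.
#' @param min_nuclear_area,max_nuclear_area size filter in px^2.
#' @return integer label matrix (row = y, col = x), 0 = background.
#' @export
segment_nuclei <- function(frame, min_nuclear_area = 20,
                           max_nuclear_area = 5000) {
  dapi <- .as_ebimage(.get_channel(frame, "dapi"))
  # Otsu always bisects the histogram, even of a frame that is pure
  # background noise; the background floor (median + 5 MAD, as in cell
  # segmentation) stops it from fabricating nuclei there
  floor_ <- stats::median(dapi) + 5 * stats::mad(dapi)
  thr <- max(EBImage::otsu(dapi, range = c(0, 1)), floor_)
  mask <- dapi > thr
  if (sum(mask) == 0) return(matrix(0L, nrow = dim(frame$pixels)[1],
                                    ncol = dim(frame$pixels)[2]))
  mask <- EBImage::fillHull(mask)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  areas <- table(as.integer(lab)[as.integer(lab) > 0])
  drop <- as.integer(names(areas)[areas < min_nuclear_area |
                                  areas > max_nuclear_area])
  m <- EBImage::imageData(lab)
  m[m %in% drop] <- 0L
  # relabel 1..k, transpose back to row/col
  out <- t(m)
  relabel_mask(out)
}

relabel_mask <- function(m) {
  ids <- sort(unique(as.integer(m[m > 0])))
  if (length(ids)) m[] <- match(as.integer(m), ids, nomatch = 0L)
  storage.mode(m) <- "integer"
  m
}

#' Segment cell bodies from nuclear seeds
#'
#' Seeded propagation (Voronoi watershed on image gradient) from the nuclei
#' over the sum of the marker channels, restricted to signal above background
#' and to at most `max_expansion` px beyond the nucleus; a minimum rim of
#' `min_rim` px around each nucleus is always included.  Bright objects with
#' no nucleus are returned separately as candidate artifacts.
#'
#' @param frame a `raredrop_frame`.
#' @param nuclear_mask label matrix from [segment_nuclei()].
#' @param max_expansion,min_rim expansion caps in px.
#' @return list with `cell_mask` (label matrix matched to nuclear labels) and
#'   `artifact_mask` (label matrix of anuclear bright objects).
#' @export
segment_cells <- function(frame, nuclear_mask, max_expansion = 24,
                          min_rim = 2) {
  if (!all(dim(nuclear_mask) == dim(frame$pixels)[1:2]))
    stop("nuclear mask shape does not match frame")
  sig_mat <- .get_channel(frame, "cd138") + .get_channel(frame, "bcma") +
    .get_channel(frame, "cd45")
  sig <- EBImage::Image(t(sig_mat) / max(sig_mat, 1))
  # foreground: union of per-channel background-statistics masks.  Stained
  # objects are sparse, so the per-channel median/MAD estimate the background
  # mode; median + 5 MAD separates any stained pixel from noise regardless of
  # how bright other objects in the frame are (a global or Otsu threshold
  # would truncate cells dim relative to the brightest ones).
  sigmask <- EBImage::Image(matrix(FALSE, ncol(sig_mat), nrow(sig_mat)))
  for (ch in c("cd138", "bcma", "cd45")) {
    cm_ <- .get_channel(frame, ch)
    thr <- stats::median(cm_) + 5 * stats::mad(cm_)
    sigmask <- sigmask | EBImage::Image(t(cm_)) > thr
  }
  seeds <- EBImage::Image(t(nuclear_mask))
  nucbin <- seeds > 0
  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  allowed <- EBImage::dilate(nucbin, brush(max_expansion))
  rim <- EBImage::dilate(nucbin, brush(min_rim))
  mask <- (sigmask | rim) & allowed
  cells <- EBImage::propagate(sig, seeds, mask = mask)
  cm <- t(EBImage::imageData(cells))
  storage.mode(cm) <- "integer"
  # every cell contains its nucleus even if signal-free beyond it
  cm[nuclear_mask > 0] <- nuclear_mask[nuclear_mask > 0]

  # anuclear bright objects: connected signal components with no nucleus
  anuc <- sigmask & !allowed
  alab <- EBImage::bwlabel(anuc)
  am <- relabel_mask(t(EBImage::imageData(alab)))
  list(cell_mask = cm, artifact_mask = am)
}

# eccentricity of the moment-equivalent ellipse from pixel coordinates
.moment_ecc <- function(ys, xs) {
  if (length(xs) < 2) return(0)
  mu <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# boundary pixel count: mask pixels with at least one 4-neighbour outside
.perimeter <- function(mask_idx, nr, nc) {
  m <- matrix(FALSE, nr + 2, nc + 2)
  yx <- arrayInd(mask_idx, c(nr, nc))
  m[cbind(yx[, 1] + 1, yx[, 2] + 1)] <- TRUE
  inner <- m[2:(nr + 1), 2:(nc + 1)]
  up <- m[1:nr, 2:(nc + 1)]; down <- m[3:(nr + 2), 2:(nc + 1)]
  left <- m[2:(nr + 1), 1:nc]; right <- m[2:(nr + 1), 3:(nc + 2)]
  sum(inner & !(up & down & left & right))
}

#' Extract CellEvent features from a segmented frame
#'
#' Per cell: areas and eccentricities (moment-equivalent ellipse), per-channel
#' medians and MADs over the cell mask, the membrane band score (median BCMA
#' over the cell mask minus its erosion by `band_width`) and the perinuclear
#' score (median BCMA over the nucleus dilated by `annulus_width`, minus the
#' nucleus).
#'
#' @param frame a `raredrop_frame`.
#' @param nuclear_mask,cell_mask label matrices from segmentation.
#' @param band_width,annulus_width localization band widths in px.
#' @return CellEvent data.frame (one row per cell label).
#' @export
extract_features <- function(frame, nuclear_mask, cell_mask,
                             band_width = 3, annulus_width = 4) {
  if (!all(dim(cell_mask) == dim(frame$pixels)[1:2]))
    stop("label mask shape does not match frame")
  labs <- sort(unique(cell_mask[cell_mask > 0]))
  if (!length(labs)) {
    return(data.frame(cell_id = character(0)))
  }
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  chans <- lapply(channel_names(), function(ch) .get_channel(frame, ch))
  names(chans) <- channel_names()

  brush <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")
  nuc_dil <- t(EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(nuclear_mask)), brush(annulus_width))))

  # per-label binary erosion on a padded bounding box (EBImage's erode
  # binarizes label images, so a single global erosion cannot be used)
  boundary_band <- function(ci, cyx) {
    r0 <- max(1, min(cyx[, 1]) - 1); r1 <- min(nr, max(cyx[, 1]) + 1)
    c0 <- max(1, min(cyx[, 2]) - 1); c1 <- min(nc, max(cyx[, 2]) + 1)
    sub <- matrix(0L, r1 - r0 + 1, c1 - c0 + 1)
    sub[cbind(cyx[, 1] - r0 + 1, cyx[, 2] - c0 + 1)] <- 1L
    ero <- t(EBImage::imageData(
      EBImage::erode(EBImage::Image(t(sub)), brush(band_width))))
    ci[ero[cbind(cyx[, 1] - r0 + 1, cyx[, 2] - c0 + 1)] == 0]
  }

  rows <- lapply(labs, function(l) {
    ci <- which(cell_mask == l)
    ni <- which(nuclear_mask == l)
    cyx <- arrayInd(ci, c(nr, nc))
    nyx <- if (length(ni)) arrayInd(ni, c(nr, nc)) else cyx[0, , drop = FALSE]
    ann_i <- which(nuc_dil == l & nuclear_mask != l)      # perinuclear ring
    # boundary band; the two compartment measures are kept disjoint (in thin
    # cytoplasm the boundary band would otherwise overlap the perinuclear
    # annulus and the overlapping pixels belong to the latter compartment)
    band_i <- setdiff(boundary_band(ci, cyx), ann_i)
    med <- function(ch, idx) if (length(idx)) stats::median(chans[[ch]][idx]) else 0
    madv <- function(ch, idx) if (length(idx) > 1) stats::mad(chans[[ch]][idx]) else 0
    data.frame(
      cell_id = sprintf("%s-f%04d-L%04d", frame$sample_id, frame$frame_index, l),
      sample_id = frame$sample_id, slide = 1L, frame = frame$frame_index,
      # 0-based centroid, x = column
      x = mean(cyx[, 2]) - 1, y = mean(cyx[, 1]) - 1,
      nuclear_area = length(ni),
      nuclear_eccentricity = .moment_ecc(nyx[, 1], nyx[, 2]),
      cellular_area = length(ci),
      cellular_eccentricity = .moment_ecc(cyx[, 1], cyx[, 2]),
      cellular_perimeter = .perimeter(ci, nr, nc),
      solidity = length(ci) /
        max(1, polygon_area(cyx[grDevices::chull(cyx[, 2], cyx[, 1]), ,
                                drop = FALSE])),
      # DAPI is a nuclear stain: its median is taken over the nucleus (falling
      # back to the full object for anuclear candidates)
      median_dapi = med("dapi", if (length(ni)) ni else ci),
      median_cd138 = med("cd138", ci),
      median_bcma = med("bcma", ci), median_cd45 = med("cd45", ci),
      mad_dapi = madv("dapi", ci), mad_cd138 = madv("cd138", ci),
      mad_bcma = madv("bcma", ci), mad_cd45 = madv("cd45", ci),
      bcma_membrane_score = med("bcma", band_i),
      bcma_perinuclear_score = med("bcma", ann_i),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$solidity <- pmin(out$solidity, 1)
  rownames(out) <- NULL
  out
}

# shoelace area of a polygon given vertex coordinates (rows: y, x)
polygon_area <- function(v) {
  if (nrow(v) < 3) return(1)
  x <- v[, 2]; y <- v[, 1]
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

#' Run segmentation and feature extraction on one frame
#'
#' @param frame a `raredrop_frame`.
#' @param ... passed to the segmentation steps.
#' @return list with `events` (CellEvent table), `nuclear_mask`, `cell_mask`,
#'   `artifact_mask`, and `artifact_events` (features of anuclear objects).
#' @export
process_frame <- function(frame, ...) {
  nm <- segment_nuclei(frame)
  seg <- segment_cells(frame, nm)
  ev <- extract_features(frame, nm, seg$cell_mask, ...)
  art <- if (max(seg$artifact_mask) > 0) {
    extract_features(frame, matrix(0L, nrow(nm), ncol(nm)),
                     seg$artifact_mask, ...)
  } else {
    ev[0, ]
  }
  list(events = ev, nuclear_mask = nm, cell_mask = seg$cell_mask,
       artifact_mask = seg$artifact_mask, artifact_events = art)
}

#' Write / read a frame as multi-page TIFF
#'
#' One 16-bit page per channel; channel names and intensity scale are stored
#' in a JSON sidecar (`<path>.meta.json`) since the TIFF writer exposes no
#' per-page description field.
#'
#' @param frame a `raredrop_frame`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  pages <- lapply(seq_along(frame$channels),
                  function(i) frame$pixels[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(channels = frame$channels, sample_id = frame$sample_id,
               frame_index = frame$frame_index, scale = 255)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, meta$channels))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * meta$scale
  structure(list(pixels = arr, channels = meta$channels,
                 sample_id = meta$sample_id, frame_index = meta$frame_index,
                 background_mean = NA), class = "raredrop_frame")
}
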