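spec_one_class <- function(class_name, n_frame = 8, artifact_rate = 0) {
  inc <- stats::setNames(rep(0, 12), phenotype_classes())
  inc[[class_name]] <- 50
  sample_spec(n_background_cells = 0, class_incidence = inc,
              artifact_rate = artifact_rate, cells_per_frame = n_frame)
}

test_that("an empty frame yields no events", {
  spec <- sample_spec(cells_per_frame = 0)
  fr <- generate_frame(spec, seed = 1, width = 128, height = 128)
  out <- process_frame(fr$frame)
  expect_equal(nrow(out$events), 0)
  expect_true(all(out$nuclear_mask == 0))
})

test_that("segmentation recovers count and centroids of rendered cells", {
  spec <- sample_spec(n_background_cells = 100, cells_per_frame = 15,
                      artifact_rate = 0)
  fr <- generate_frame(spec, seed = 4, width = 512, height = 512)
  out <- process_frame(fr$frame)
  expect_equal(nrow(out$events), 15)
  # match each truth center to the nearest segmented centroid
  d <- vapply(seq_len(15), function(i) min(sqrt(
    (out$events$x - fr$truth$true_x[i])^2 +
    (out$events$y - fr$truth$true_y[i])^2)), numeric(1))
  expect_lt(max(d), 2)
})

test_that("watershed separates two nearly touching nuclei", {
  px <- array(5, dim = c(128, 128, 4))
  px <- paint_disc(px, "dapi", 64, 50, 9, 200)
  px <- paint_disc(px, "dapi", 64, 71, 9, 200)  # 3 px gap between rims
  nm <- segment_nuclei(make_frame(px))
  expect_equal(max(nm), 2)
})

test_that("a signal-free cell still gets a minimal rim beyond its nucleus", {
  px <- array(0, dim = c(96, 96, 4))
  px <- paint_disc(px, "dapi", 48, 48, 10, 200)
  fr <- make_frame(px)
  nm <- segment_nuclei(fr)
  expect_equal(max(nm), 1)
  seg <- segment_cells(fr, nm)
  ev <- extract_features(fr, nm, seg$cell_mask)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$cellular_area, ev$nuclear_area)
  expect_lt(ev$cellular_area, 3 * ev$nuclear_area)
  expect_error(segment_cells(fr, nm[1:10, 1:10]), "shape")
  expect_error(extract_features(fr, nm, seg$cell_mask[1:10, 1:10]), "shape")
})

test_that("bright anuclear objects are routed to the artifact mask", {
  px <- array(0, dim = c(128, 128, 4))
  px <- paint_disc(px, "dapi", 40, 40, 9, 200)     # a real cell
  px <- paint_disc(px, "cd138", 40, 40, 11, 150)
  px <- paint_disc(px, "cd138", 100, 100, 6, 250)  # bright, no nucleus
  out <- process_frame(make_frame(px))
  expect_equal(nrow(out$events), 1)
  expect_equal(max(out$artifact_mask), 1)
  expect_equal(nrow(out$artifact_events), 1)
  expect_gt(out$artifact_events$median_cd138, 200)
})

test_that("median intensities over a uniform disc equal the painted value", {
  px <- array(0, dim = c(128, 128, 4))
  px <- paint_disc(px, "dapi", 64, 64, 9, 180)
  px <- paint_disc(px, "cd138", 64, 64, 14, 200)
  px <- paint_disc(px, "cd45", 64, 64, 14, 120)
  out <- process_frame(make_frame(px))
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$median_dapi, 180)
  expect_equal(out$events$median_cd138, 200)
  expect_equal(out$events$median_cd45, 120)
  expect_lt(out$events$median_bcma, 10)
  # a filled disc is solid and round
  expect_gt(out$events$solidity, 0.9)
  expect_lt(out$events$cellular_eccentricity, 0.35)
})

test_that("moment eccentricity matches closed forms for circle and ellipse", {
  yx <- expand.grid(y = -30:30, x = -30:30)
  circ <- yx[yx$y^2 + yx$x^2 <= 20^2, ]
  expect_lt(.moment_ecc(circ$y, circ$x), 0.05)
  ell <- yx[(yx$x / 24)^2 + (yx$y / 12)^2 <= 1, ]
  expect_equal(.moment_ecc(ell$y, ell$x), sqrt(3) / 2, tolerance = 0.05)
  # rotating the ellipse 90 degrees leaves eccentricity unchanged
  expect_equal(.moment_ecc(ell$x, ell$y), .moment_ecc(ell$y, ell$x),
               tolerance = 1e-12)
})

test_that("BCMA band scores recover the rendered localization", {
  for (cls in c("D | 138 | BCMA-Memb", "D | BCMA-Peri | 45")) {
    fr <- generate_frame(spec_one_class(cls), seed = 6,
                         width = 512, height = 512)
    out <- process_frame(fr$frame)
    expect_equal(nrow(out$events), 8)
    memb <- out$events$bcma_membrane_score > out$events$bcma_perinuclear_score
    if (grepl("Memb", cls)) expect_true(all(memb))
    else expect_true(all(!memb))
  }
})

test_that("extracted features track truth across a rendered frame", {
  spec <- sample_spec(n_background_cells = 60, cells_per_frame = 15,
                      artifact_rate = 0)
  evs <- list(); trs <- list()
  for (s in 1:3) {
    fr <- generate_frame(spec, seed = 10 + s, width = 512, height = 512)
    out <- process_frame(fr$frame)
    # align by nearest centroid
    ord <- vapply(seq_len(nrow(fr$truth)), function(i) which.min(
      (out$events$x - fr$truth$true_x[i])^2 +
      (out$events$y - fr$truth$true_y[i])^2), integer(1))
    evs[[s]] <- out$events[ord, ]
    trs[[s]] <- fr$truth
  }
  ev <- do.call(rbind, evs); tr <- do.call(rbind, trs)
  # rendered cells are eccentricity-jittered ellipses, so pi r^2 is only the
  # circle-equivalent area; correlation is attenuated accordingly
  expect_gt(stats::cor(ev$cellular_area, pi * tr$true_cell_radius^2), 0.85)
  expect_gt(stats::cor(ev$median_dapi, tr$true_dapi), 0.95)
  expect_gt(stats::cor(ev$median_cd45, tr$true_cd45), 0.95)
})

test_that("feature extraction is invariant to label permutation", {
  spec <- sample_spec(n_background_cells = 50, cells_per_frame = 6,
                      artifact_rate = 0)
  fr <- generate_frame(spec, seed = 21, width = 320, height = 320)
  nm <- segment_nuclei(fr$frame)
  seg <- segment_cells(fr$frame, nm)
  ev <- extract_features(fr$frame, nm, seg$cell_mask)
  # permute the labels 1..k
  k <- max(nm)
  perm <- rev(seq_len(k))
  nm2 <- nm; nm2[nm > 0] <- perm[nm[nm > 0]]
  cm2 <- seg$cell_mask; cm2[cm2 > 0] <- perm[cm2[cm2 > 0]]
  ev2 <- extract_features(fr$frame, nm2, cm2)
  feats <- morphometric_feature_names()
  a <- ev[order(ev$x), feats]; b <- ev2[order(ev2$x), feats]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("frames round-trip through 16-bit TIFF with small error", {
  skip_if_not_installed("tiff")
  spec <- sample_spec(n_background_cells = 40, cells_per_frame = 4,
                      artifact_rate = 0)
  fr <- generate_frame(spec, seed = 31, width = 128, height = 128)
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))), add = TRUE)
  write_frame_tiff(fr$frame, path)
  back <- read_frame_tiff(path)
  expect_identical(back$channels, channel_names())
  expect_equal(dim(back$pixels), dim(fr$frame$pixels))
  expect_lt(max(abs(back$pixels - fr$frame$pixels)), 0.01)
})
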