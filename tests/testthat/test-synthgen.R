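test_that("sample_spec validates inputs and resolves presets", {
  spec <- sample_spec(disease_state = "NDMM")
  expect_s3_class(spec, "raredrop_sample_spec")
  expect_equal(spec$class_incidence, incidence_presets()[["NDMM"]])
  expect_error(sample_spec(disease_state = "CLL"), "arg")
  expect_error(sample_spec(class_incidence = c(foo = 1)), "unknown incidence")
  expect_error(sample_spec(artifact_rate = 1.2))
})

test_that("the default plating makes the effective analyzed volume 1 mL", {
  spec <- sample_spec()
  meta <- sample_metadata(spec)
  expect_equal(meta$n_analyzed_cells, 6e6)
  expect_equal(meta$cbc_total_nucleated, 4.8e7)
  expect_equal(effective_volume_ml(spec), 1)
})

test_that("incidence presets cover all states and the headline gradient", {
  pre <- incidence_presets()
  expect_setequal(names(pre), c("MGUS", "SMM", "NDMM", "RRMM"))
  for (p in pre) expect_setequal(names(p), phenotype_classes())
  key <- "D | 138 | BCMA-Memb"
  expect_lt(pre$MGUS[[key]], pre$SMM[[key]])
  expect_lt(pre$SMM[[key]], pre$NDMM[[key]])
})

test_that("generate_event_table is deterministic per seed", {
  spec <- sample_spec(n_background_cells = 200)
  a <- generate_event_table(spec, seed = 4)
  b <- generate_event_table(spec, seed = 4)
  c <- generate_event_table(spec, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$events, c$events))
  expect_identical(a$events$cell_id, a$truth$cell_id)  # row-aligned
})

test_that("an all-zero spec yields a typed empty table", {
  spec <- sample_spec(n_background_cells = 0,
                      class_incidence = stats::setNames(
                        rep(0, 12), phenotype_classes()),
                      artifact_rate = 0)
  out <- generate_event_table(spec, seed = 1)
  expect_equal(nrow(out$events), 0)
  expect_true(all(morphometric_feature_names() %in% names(out$events)))
})

test_that("truth channel levels honor the 50-intensity truth cutoff", {
  set.seed(8)
  tr <- rbind(draw_truth(200, "BACKGROUND"), draw_truth(50, "D | 138 | BCMA-Memb"),
              draw_truth(50, "D | BCMA-Peri | 45"))
  # negatives clip to [0, 30], positives to [70, 255]: nothing near the cutoff
  marker <- c(tr$true_cd138, tr$true_bcma, tr$true_cd45)
  expect_true(all(marker <= 30 | marker >= 70))
  expect_identical(truth_class_from_levels(tr),
                   c(rep("D | 45", 200), rep("D | 138 | BCMA-Memb", 50),
                     rep("D | BCMA-Peri | 45", 50)))
})

test_that("planted rare counts follow the Poisson law over many seeds", {
  # cheap spec: one planted class at incidence 3/mL, no background/artifacts
  inc <- stats::setNames(rep(0, 12), phenotype_classes())
  inc[["D | 138"]] <- 3
  spec <- sample_spec(n_background_cells = 0, class_incidence = inc,
                      artifact_rate = 0)
  n_seeds <- 300
  counts <- vapply(seq_len(n_seeds), function(s) {
    tb <- generate_event_table(spec, seed = s)
    sum(tb$truth$true_class == "D | 138")
  }, numeric(1))
  # chi-square goodness of fit against Poisson(3), tail pooled
  breaks <- 0:7
  obs <- vapply(breaks, function(k)
    if (k < 7) sum(counts == k) else sum(counts >= 7), numeric(1))
  p <- stats::dpois(0:6, 3)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
  expect_equal(mean(counts), 3, tolerance = 0.15)
})

test_that("artifact counts follow the binomial law over many seeds", {
  spec <- sample_spec(n_background_cells = 100, artifact_rate = 0.2,
                      class_incidence = stats::setNames(
                        rep(0, 12), phenotype_classes()))
  n_art <- vapply(1:200, function(s)
    sum(generate_event_table(spec, seed = s)$truth$true_class == "ARTIFACT"),
    numeric(1))
  expect_equal(mean(n_art) / 100, 0.2, tolerance = 0.03)
  expect_equal(stats::var(n_art), 100 * 0.2 * 0.8, tolerance = 0.35 * 16)
})

test_that("measured features stay near the truth model", {
  set.seed(21)
  tr <- draw_truth(400, "D | 138 | BCMA-Memb")
  ev <- measure_events(tr)
  # intensity noise is additive gaussian sd 5: medians track truth closely
  expect_gt(stats::cor(ev$median_cd138, tr$true_cd138), 0.9)
  # membrane-localized cells have membrane score > perinuclear score
  expect_gte(mean(ev$bcma_membrane_score > ev$bcma_perinuclear_score), 0.98)
  # areas track pi r^2 within the 5% jitter
  expect_equal(ev$nuclear_area / (pi * tr$true_nuclear_radius^2),
               rep(1, 400), tolerance = 0.06)
  expect_true(all(ev$cellular_area >= ev$nuclear_area))
})

test_that("NDMM plants more target cells than MGUS on average", {
  key <- "D | 138 | BCMA-Memb"
  planted <- function(state, seeds) vapply(seeds, function(s) {
    spec <- sample_spec(disease_state = state, n_background_cells = 0,
                        artifact_rate = 0)
    sum(generate_event_table(spec, seed = s)$truth$true_class == key)
  }, numeric(1))
  seeds <- 1:60
  expect_gt(mean(planted("NDMM", seeds)), mean(planted("MGUS", seeds)))
})

test_that("the default cohort layout matches the 68-patient composition", {
  cc <- cohort_config()
  expect_equal(sum(cc$n_per_state), 68)
  expect_equal(cc$n_per_state[["MGUS"]], 11)
})

test_that("generate_cohort produces aligned specs, samples and clinical rows", {
  cc <- cohort_config(n_per_state = c(MGUS = 2, NDMM = 2),
                      n_background_cells = 50, seed = 2)
  coh <- generate_cohort(cc)
  expect_length(coh$samples, 4)
  expect_identical(names(coh$samples), names(coh$specs))
  expect_identical(coh$clinical$sample_id, names(coh$samples))
  expect_identical(coh$clinical$disease_state, c("MGUS", "MGUS", "NDMM", "NDMM"))
  expect_true(all(coh$clinical$age >= 38 & coh$clinical$age <= 88))
  expect_true(all(coh$clinical$del13 %in% 0:1))
  # determinism
  coh2 <- generate_cohort(cc)
  expect_identical(coh$samples, coh2$samples)
  expect_identical(coh$clinical, coh2$clinical)
  # a single-sample cohort must not crash the covariate coupling
  one <- generate_cohort(cohort_config(n_per_state = c(MGUS = 1),
                                       n_background_cells = 20, seed = 3))
  expect_equal(nrow(one$clinical), 1)
})

test_that("covariate_correlation = 0 decouples clinical markers from burden", {
  key <- "D | 138 | BCMA-Memb"
  rhos <- vapply(1:25, function(s) {
    cc <- cohort_config(n_per_state = c(MGUS = 6, NDMM = 6),
                        n_background_cells = 10,
                        covariate_correlation = 0, seed = s)
    coh <- generate_cohort(cc)
    burden <- vapply(coh$samples,
                     function(x) sum(x$truth$true_class == key), numeric(1))
    if (stats::sd(burden) == 0) return(NA_real_)
    stats::cor(burden, coh$clinical$m_spike)
  }, numeric(1))
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.2)
})

test_that("generate_curation_set is labeled, shuffled and deterministic", {
  cur <- generate_curation_set(n = 300, artifact_fraction = 0.3, seed = 6)
  expect_equal(nrow(cur$events), 300)
  expect_equal(sum(cur$label == "artifact"), 90)
  expect_identical(cur, generate_curation_set(300, 0.3, seed = 6))
  # labels are interleaved, not blocked
  expect_gt(length(rle(as.character(cur$label))$lengths), 20)
})

test_that("generate_frame is deterministic and matches the truth table", {
  spec <- sample_spec(n_background_cells = 50, cells_per_frame = 6,
                      artifact_rate = 0)
  f1 <- generate_frame(spec, seed = 2, width = 256, height = 256)
  f2 <- generate_frame(spec, seed = 2, width = 256, height = 256)
  expect_identical(f1$frame$pixels, f2$frame$pixels)
  expect_identical(f1$truth, f2$truth)
  expect_equal(nrow(f1$truth), 6)
  expect_equal(dim(f1$frame$pixels), c(256, 256, 4))
  expect_true(all(f1$frame$pixels >= 0 & f1$frame$pixels <= 255))
  # placement keeps every cell fully inside the frame
  r <- f1$truth$true_cell_radius
  expect_true(all(f1$truth$true_x - r >= 0 & f1$truth$true_x + r <= 255))
  expect_true(all(f1$truth$true_y - r >= 0 & f1$truth$true_y + r <= 255))
})

test_that("overcrowded frames fail loudly instead of overlapping", {
  spec <- sample_spec(n_background_cells = 50, cells_per_frame = 40)
  expect_error(generate_frame(spec, seed = 1, width = 96, height = 96),
               "capacity exceeded")
})
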