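test_that("the worked enumeration example holds: 10 events -> 10 cells/mL", {
  spec <- sample_spec()  # defaults: 8 mL draw, CBC 6e6/mL, 2 x 3e6 analyzed
  meta <- sample_metadata(spec)
  counts <- count_classes(rep("D | 138 | BCMA-Memb", 10))
  enum <- enumerate_sample(NULL, meta, sample_id = "S1", counts = counts)
  expect_equal(enum$cells_per_ml[enum$event_type == "D | 138 | BCMA-Memb"], 10)
  expect_equal(enum$cells_per_ml[enum$event_type == "Total Cells"], 10)
})

test_that("the enumeration identity holds exactly on random integer fixtures", {
  set.seed(5)
  for (i in 1:200) {
    count <- sample.int(500, 1)
    cbc <- sample.int(1e7, 1)
    analyzed <- sample.int(1e7, 1)
    vol <- sample.int(20, 1)
    meta <- list(n_analyzed_cells = analyzed, cbc_total_nucleated = cbc,
                 blood_volume_ml = vol)
    counts <- count_classes(rep("D", count))
    enum <- enumerate_sample(NULL, meta, sample_id = "S", counts = counts)
    got <- enum$cells_per_ml[enum$event_type == "D"]
    expect_identical(got, count * (cbc / analyzed) / vol)
  }
})

test_that("cells/mL scales inversely with analyzed cells and volume", {
  counts <- count_classes(rep("D", 12))
  m1 <- list(n_analyzed_cells = 6e6, cbc_total_nucleated = 4.8e7,
             blood_volume_ml = 8)
  m2 <- m1; m2$n_analyzed_cells <- 3e6
  e1 <- enumerate_sample(NULL, m1, "S", counts = counts)
  e2 <- enumerate_sample(NULL, m2, "S", counts = counts)
  expect_equal(e2$cells_per_ml, 2 * e1$cells_per_ml)
  expect_error(enumerate_sample(NULL, list(n_analyzed_cells = 0,
                                           cbc_total_nucleated = 1,
                                           blood_volume_ml = 1), "S",
                                counts = counts), "analyzed")
})

test_that("zero events enumerate to all-zero cells/mL", {
  meta <- sample_metadata(sample_spec())
  enum <- enumerate_sample(NULL, meta, "S", counts = count_classes(character(0)))
  expect_equal(nrow(enum), 17)  # 12 classes + 5 aggregates
  expect_true(all(enum$cells_per_ml == 0))
})

test_that("enumeration_matrix is one row per sample, one column per type", {
  meta <- sample_metadata(sample_spec())
  e <- rbind(
    enumerate_sample(NULL, meta, "A", "MGUS", count_classes(rep("D", 3))),
    enumerate_sample(NULL, meta, "B", "NDMM", count_classes(rep("D | 45", 2))))
  wide <- enumeration_matrix(e)
  expect_equal(nrow(wide), 2)
  expect_equal(ncol(wide), 2 + 17)
  expect_equal(wide$`D`[wide$sample_id == "A"], 3)
  expect_equal(wide$`D`[wide$sample_id == "B"], 0)
})

test_that("rank_sum_test matches the enumeration oracle on tie-free fixtures", {
  set.seed(31)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    repeat {
      x <- round(stats::rnorm(n1), 6); y <- round(stats::rnorm(n2), 6)
      if (anyDuplicated(c(x, y)) == 0) break
    }
    res <- rank_sum_test(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 and a symmetric-case example works", {
  expect_equal(rank_sum_test(c(1, 3, 5), c(2, 4, 6))$p_value,
               oracle_wilcoxon_p(c(1, 3, 5), c(2, 4, 6)))
  # fully separated small groups: p = 2 / C(6,3) = 0.1
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # ties force the approximate path
  expect_false(rank_sum_test(c(1, 1, 2), c(3, 4, 5))$exact)
})

test_that("wilcoxon_z sign convention and degenerate input", {
  g <- factor(rep(c("hi", "lo"), each = 5), levels = c("hi", "lo"))
  v <- c(10:14, 1:5)
  res <- wilcoxon_z(v, g)
  expect_gt(res$z, 0)  # higher burden in the reference level
  expect_lt(res$p_value, 0.05)
  const <- wilcoxon_z(rep(1, 10), g)
  expect_equal(const$z, 0)
  expect_equal(const$p_value, 1)
  expect_error(wilcoxon_z(1:3, factor(c("a", "b", "c"))), "binary")
})

test_that("pairwise_state_tests ranks a strong group difference first", {
  meta <- sample_metadata(sample_spec())
  mk <- function(id, state, n) enumerate_sample(
    NULL, meta, id, state, count_classes(rep("D | 138", n)))
  e <- rbind(mk("A1", "MGUS", 1), mk("A2", "MGUS", 2), mk("A3", "MGUS", 3),
             mk("A4", "MGUS", 4),
             mk("B1", "NDMM", 20), mk("B2", "NDMM", 21), mk("B3", "NDMM", 22),
             mk("B4", "NDMM", 23))
  tests <- pairwise_state_tests(e)
  expect_true(all(diff(tests$p_value) >= 0))      # sorted by p
  expect_true(all(tests$p_bh >= tests$p_value))   # BH never smaller
  top <- tests[1, ]
  expect_lt(top$p_value, 0.05)
  expect_true(top$significant)
  # with under-2-sample groups everywhere the result is a typed empty frame
  empty <- pairwise_state_tests(e[e$sample_id %in% c("A1", "B1"), ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("p_value", "p_bh") %in% names(empty)))
  expect_error(pairwise_state_tests(e, state_pairs = list(c("MGUS", "RRMM"))),
               "empty group")
})

test_that("Spearman correlations match the rank-then-Pearson oracle", {
  set.seed(17)
  meta <- sample_metadata(sample_spec())
  n <- 12
  counts <- sample.int(30, n, replace = TRUE)
  e <- do.call(rbind, lapply(seq_len(n), function(i) enumerate_sample(
    NULL, meta, sprintf("S%02d", i), "MGUS",
    count_classes(rep("D | 138", counts[i])))))
  clin <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     marker = counts + stats::rnorm(n, 0, 4),
                     flat = rep(1, n))
  expect_message(cors <- clinical_correlations(e, clin), "flat")
  expect_identical(attr(cors, "skipped"), "flat")
  row <- cors[cors$analyte == "D | 138" & cors$clinical_variable == "marker", ]
  expect_identical(row$method, "Spearman")
  expect_equal(row$correlation_value,
               oracle_spearman(counts, clin$marker), tolerance = 1e-12)
  # a strictly monotone pair has rho exactly 1
  expect_equal(oracle_spearman(1:8, exp(1:8)), 1)
})

test_that("binary clinical variables route through the Wilcoxon z", {
  meta <- sample_metadata(sample_spec())
  n <- 10
  counts <- c(1:5, 21:25)
  e <- do.call(rbind, lapply(seq_len(n), function(i) enumerate_sample(
    NULL, meta, sprintf("S%02d", i), "MGUS",
    count_classes(rep("D", counts[i])))))
  clin <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     flag = rep(c(0, 1), each = 5))
  cors <- clinical_correlations(e, clin)
  row <- cors[cors$analyte == "D", ]
  expect_identical(row$method, "Wilcoxon")
  expect_lt(row$correlation_value, 0)  # reference level "0" has lower burden
  expect_lt(row$p_value, 0.05)
})

test_that("morphometric UMAP is deterministic and separates distinct populations", {
  skip_if_not_installed("uwot")
  skip_if_not_installed("cluster")
  set.seed(3)
  tr <- rbind(draw_truth(150, "BACKGROUND"), draw_truth(50, "D | 138 | BCMA-Memb"))
  ev <- measure_events(tr)
  u1 <- morphometric_umap(ev, seed = 9)
  u2 <- morphometric_umap(ev, seed = 9)
  expect_equal(u1$embedding, u2$embedding)
  lab <- as.integer(tr$true_class != "BACKGROUND") + 1L
  sil <- cluster::silhouette(lab, stats::dist(as.matrix(
    u1$embedding[, c("umap1", "umap2")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(morphometric_umap(ev[1:10, ]), "at least 20")
})
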