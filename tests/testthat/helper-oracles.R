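# Independent oracles and small construction helpers shared by the tests.
# Oracles are deliberately written from first principles (no reuse of package
# internals) so that agreement is evidence of correctness, not of shared bugs.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n1+n2, n1) assignments of the pooled ranks to group 1.  Requires
# tie-free data.  Two-sided rule: double the tail containing the observed
# Mann-Whitney U (inclusive), capped at 1.
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(anyDuplicated(c(x, y)) == 0)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tail_p <- if (u_obs > mu) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(1, 2 * tail_p)
}

# Spearman rho computed by the rank-then-Pearson definition with
# average ranks for ties.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Displace selected rows of an event table so each becomes an outlier at
# least `k` robust SDs (MAD, SD fallback) away from the population median in
# every morphometric feature.  Caller controls RNG state.
plant_outliers <- function(events, idx, k = 8) {
  for (f in intersect(raredrop::morphometric_feature_names(), names(events))) {
    s <- stats::mad(events[[f]])
    if (s == 0) s <- stats::sd(events[[f]])
    if (s == 0) next
    sign_ <- sample(c(-1, 1), length(idx), replace = TRUE)
    events[[f]][idx] <- stats::median(events[[f]]) + sign_ * k * s
  }
  events
}

# Minimal single-channel-stack frame object compatible with the imaging
# functions: a height x width x 4 array with the package's channel order.
make_frame <- function(px, sample_id = "T1", frame_index = 1L) {
  structure(list(pixels = px, channels = raredrop::channel_names(),
                 sample_id = sample_id, frame_index = frame_index),
            class = "raredrop_frame")
}

# Blank frame of constant background, optionally with Gaussian noise.
blank_frame <- function(h = 128, w = 128, level = 20, sd = 0, seed = 1) {
  set.seed(seed)
  px <- array(level, dim = c(h, w, 4))
  if (sd > 0) px <- px + array(stats::rnorm(h * w * 4, 0, sd), dim = dim(px))
  px[px < 0] <- 0; px[px > 255] <- 255
  make_frame(px)
}

# Paint a filled disc into one channel of a frame's pixel array.
paint_disc <- function(px, channel, cy, cx, r, value) {
  ch <- match(channel, raredrop::channel_names())
  ys <- seq_len(dim(px)[1]); xs <- seq_len(dim(px)[2])
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  pxc <- px[, , ch]
  pxc[d2 <= r^2] <- value
  px[, , ch] <- pxc
  px
}

# Gaussian pseudo-event table with the morphometric feature columns; used
# for detection null-calibration checks where no structure should exist.
gaussian_events <- function(n, p = 5, seed = 1) {
  set.seed(seed)
  feats <- raredrop::morphometric_feature_names()[seq_len(p)]
  as.data.frame(stats::setNames(
    lapply(feats, function(f) stats::rnorm(n)), feats))
}
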