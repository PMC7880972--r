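make_t1 <- function(values, spacing = c(1, 1, 1)) {
  volume_grid(values, spacing = spacing)
}

test_that("histogram features: constant region and direct-formula oracle", {
  d <- c(10, 10, 10)
  t1 <- make_t1(array(1234, d))
  mask <- make_t1(array(1, d))
  h <- histogram_features(t1, mask)
  expect_equal(h$volume, 1.000)  # 1000 voxels at 1 mm^3
  expect_equal(h$mean, 1234); expect_equal(h$median, 1234)
  expect_equal(h$p5, 1234); expect_equal(h$p95, 1234)
  expect_equal(h$sd, 0)

  vals <- c(600, 800, 1000, 1200, 1400)
  t1b <- make_t1(array(vals, c(5, 1, 1)))
  maskb <- make_t1(array(1, c(5, 1, 1)))
  hb <- histogram_features(t1b, maskb)
  expect_equal(hb$mean, 1000)
  expect_equal(hb$median, 1000)
  expect_equal(hb$sd, sd(vals))
  sorted <- sort(vals)  # sort-and-interpolate oracle (type 7)
  p5_o <- sorted[1] + (sorted[2] - sorted[1]) * (0.05 * 4 - 0)
  p95_o <- sorted[4] + (sorted[5] - sorted[4]) * (0.95 * 4 - 3)
  expect_equal(hb$p5, p5_o)
  expect_equal(hb$p95, p95_o)
})

test_that("histogram features: exclusions, empty and single-voxel masks", {
  d <- c(3, 3, 1)
  vals <- array(1000, d); vals[1, 1, 1] <- T1_INVALID
  t1 <- make_t1(vals)
  attr(t1, "invalid_value") <- T1_INVALID
  mask <- make_t1(array(1, d))
  h <- histogram_features(t1, mask)
  expect_equal(attr(h, "n_voxels"), 8)  # invalid voxel excluded
  expect_error(histogram_features(make_t1(array(1, d)),
                                  make_t1(array(0, d))), "empty")
  m1 <- array(0, d); m1[2, 2, 1] <- 1
  h1 <- histogram_features(make_t1(array(900, d)), make_t1(m1))
  expect_equal(h1$sd, 0)
  expect_true(is.na(h1$skewness) && is.na(h1$kurtosis))
})

test_that("quantize: thresholds, constants, histogram-count oracle", {
  d <- c(10, 10, 1)
  v <- array(seq(500, 1500, length.out = prod(d)), d)
  mask <- make_t1(array(1, d))
  q <- quantize(make_t1(v), mask, n_levels = 2)
  expect_setequal(unique(as.vector(q$labels)), c(0L, 1L))
  expect_true(all(q$labels[v < 1000] == 0))
  expect_true(all(q$labels[v > 1000] == 1))
  expect_equal(q$labels[v == 1500], 1L)  # max into top bin

  qc <- quantize(make_t1(array(777, d)), mask, n_levels = 8)
  expect_true(all(qc$labels == 0L))

  set.seed(3)
  vr <- array(rnorm(prod(d), 1000, 200), d)
  q32 <- quantize(make_t1(vr), mask, n_levels = 32)
  counts <- tabulate(as.vector(q32$labels) + 1L, 32)
  # counting oracle with identical edges (right-closed except top)
  edges <- q32$bin_edges
  oracle <- vapply(seq_len(32), function(b) {
    if (b < 32) sum(vr >= edges[b] & vr < edges[b + 1])
    else sum(vr >= edges[b] & vr <= edges[b + 1])
  }, numeric(1))
  expect_equal(counts, as.integer(oracle))
})

test_that("GLCM: hand example, constants, brute-force oracle", {
  labs <- array(c(0L, 0L, 1L, 1L), c(2, 2, 1))  # columns 0 | 1
  q <- make_quantized(labs, 2)
  g <- glcm(q, offsets = matrix(c(0L, 1L, 0L), 1), symmetric = TRUE)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  tx <- texture_features(g)
  expect_equal(tx$entropy, 1.0)
  expect_equal(tx$contrast, 1.0)
  expect_equal(tx$diff_entropy, 0.0)
  expect_equal(tx$diff_variance, 0.0)

  qc <- make_quantized(array(0L, c(3, 3, 3)), 4)
  gc <- glcm(qc)
  expect_equal(gc$p[1, 1], 1)
  expect_equal(gc$p_diff[1], 1)
  tc <- texture_features(gc)
  expect_equal(unlist(tc), c(entropy = 0, contrast = 0,
                             diff_entropy = 0, diff_variance = 0))

  set.seed(11)
  offs <- unit_offsets_3d()
  for (trial in 1:20) {
    lab <- random_labels(c(8, 8, 8), n_levels = 4)
    g1 <- glcm(make_quantized(lab, 4), offsets = offs, symmetric = TRUE)
    expect_equal(g1$p, oracle_glcm(lab, 4, offs, TRUE))
    tx1 <- texture_features(g1)
    ora <- oracle_texture(g1$p)
    for (nm in names(ora)) expect_equal(tx1[[nm]], ora[[nm]],
                                        tolerance = 1e-12)
  }
})

test_that("GLCM error paths and invariants", {
  # scattered single voxels: no valid pairs
  lab <- array(-1L, c(5, 5, 1)); lab[1, 1, 1] <- 0L; lab[5, 5, 1] <- 1L
  expect_error(glcm(make_quantized(lab, 2),
                    offsets = matrix(c(1L, 0L, 0L), 1)), "no valid")
  expect_error(glcm(make_quantized(array(0L, c(2, 2, 1)), 2),
                    offsets = matrix(0L, 1, 3)), "nonzero")

  set.seed(5)
  ng <- 6
  for (trial in 1:10) {
    lab <- random_labels(c(6, 6, 4), ng)
    g <- glcm(make_quantized(lab, ng))
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_equal(g$p, t(g$p))  # symmetric
    tx <- texture_features(g)
    # entropy bounds
    expect_gte(tx$entropy, 0); expect_lte(tx$entropy, 2 * log2(ng) + 1e-12)
    expect_gte(tx$diff_entropy, 0)
    expect_lte(tx$diff_entropy, log2(ng) + 1e-12)
    # contrast = sum k^2 p_diff(k) (algebraic identity, both routes)
    expect_equal(tx$contrast,
                 sum((seq_along(g$p_diff) - 1)^2 * g$p_diff),
                 tolerance = 1e-12)
    # reflection invariance i -> ng-1-i
    labr <- lab
    labr[lab >= 0] <- ng - 1L - lab[lab >= 0]
    txr <- texture_features(glcm(make_quantized(labr, ng)))
    expect_equal(tx$contrast, txr$contrast, tolerance = 1e-12)
    expect_equal(tx$diff_variance, txr$diff_variance, tolerance = 1e-12)
  }
})

test_that("uniform GLCM over 16 cells has entropy 4 bits", {
  ng <- 4
  g <- structure(list(p = matrix(1 / 16, ng, ng),
                      p_diff = NULL, mu_diff = NULL), class = "glcm_matrix")
  k <- abs(row(g$p) - col(g$p))
  g$p_diff <- as.numeric(rowsum(as.vector(g$p), as.vector(k)))
  g$mu_diff <- sum(seq(0, ng - 1) * g$p_diff)
  tx <- texture_features(g)
  expect_equal(tx$entropy, 4.0)
  expect_equal(tx$contrast, oracle_texture(g$p)$contrast)
})

test_that("extract_all: constant phantom, determinism, config recorded", {
  d <- c(8, 8, 8)
  t1 <- make_t1(array(1000, d), spacing = c(2, 2, 2))
  mask <- make_t1(array(1, d), spacing = c(2, 2, 2))
  fv <- extract_all(t1, mask)
  expect_named(fv, feature_names(), ignore.order = TRUE)
  expect_equal(fv$sd, 0)
  expect_equal(fv$entropy, 0); expect_equal(fv$contrast, 0)
  expect_equal(fv$diff_entropy, 0); expect_equal(fv$diff_variance, 0)
  expect_equal(fv$volume, prod(d) * 8 / 1000)
  expect_s3_class(attr(fv, "config"), "feature_config")

  ph <- phantom_spec(grid_shape = c(16, 16, 16), voxel_spacing = c(4, 4, 4),
                     rng_seed = 99L)
  b1 <- generate_phantom(ph); b2 <- generate_phantom(ph)
  f1 <- extract_all(b1$truth_t1, b1$truth_mask)
  f2 <- extract_all(b2$truth_t1, b2$truth_mask)
  expect_identical(f1, f2)  # bit-identical under a fixed seed
})

test_that("monotone heterogeneity: entropy does not fall as T1 SD rises", {
  # note: per-volume min-max binning is scale-invariant, so the SD effect
  # is probed with a fixed ms range (the regime where more dispersed T1
  # spreads over more gray levels)
  cfg <- feature_config(range_rule = "fixed", range = c(200, 2500))
  mean_ent <- function(sdv) {
    e <- vapply(1:20, function(s) {
      ph <- phantom_spec(grid_shape = c(16, 16, 16),
                         voxel_spacing = c(4, 4, 4),
                         t1_liver_sd = sdv, noise_sd = 0, rng_seed = s)
      b <- generate_phantom(ph)
      extract_all(b$truth_t1, b$truth_mask, cfg)$entropy
    }, numeric(1))
    mean(e)
  }
  e_low <- mean_ent(150)
  e_high <- mean_ent(450)
  expect_gte(e_high, e_low)
})
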