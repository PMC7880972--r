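#' Feature-extraction configuration
#'
#' Conventions for the GLCM stage. The vendor conventions behind the
#' clinical prototype are unpublished, so these are explicit, configurable
#' choices recorded alongside every extracted vector: 32 equal-width gray
#' levels over the masked min-max range, the 13 unique unit-displacement 3D
#' directions pooled into one symmetric matrix (orientation invariance, one
#' value per liver), base-2 logarithms (entropies in bits), and excess
#' kurtosis.
#'
#' @param n_levels number of gray levels (>= 2).
#' @param range_rule "minmax" (per-volume) or "fixed".
#' @param range numeric length-2 (ms), required when `range_rule = "fixed"`.
#' @param offsets integer matrix of displacement vectors (rows), default the
#'   13 unique unit offsets.
#' @param symmetric pool each displacement with its negation.
#' @return a `feature_config` list.
#' @export
feature_config <- function(n_levels = 32L, range_rule = c("minmax", "fixed"),
                           range = NULL, offsets = unit_offsets_3d(),
                           symmetric = TRUE) {
  range_rule <- match.arg(range_rule)
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (range_rule == "fixed" &&
      (is.null(range) || length(range) != 2 || diff(range) <= 0))
    stop("range_rule='fixed' requires an increasing length-2 range")
  structure(list(n_levels = as.integer(n_levels), range_rule = range_rule,
                 range = range, offsets = offsets, symmetric = symmetric,
                 log_base = 2, kurtosis = "excess",
                 diff_variance = "variance of the difference distribution"),
            class = "feature_config")
}

#' The 13 unique 3D unit-displacement directions
#'
#' All 26 neighbours of a voxel come in antipodal pairs; this returns one
#' representative per pair (lexicographically positive), the standard offset
#' set for an orientation-pooled 3D GLCM.
#' @return 13 x 3 integer matrix.
#' @export
unit_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

masked_values <- function(t1_map, mask) {
  inv <- attr(t1_map, "invalid_value")
  v <- t1_map$values[mask$values > 0.5]
  if (!is.null(inv)) v <- v[v != inv]
  v[is.finite(v)]
}

#' Histogram features of the masked T1 distribution
#'
#' The eight first-order features of the whole-liver workflow: volume (cm^3,
#' voxel count x voxel volume), mean, SD, median, 5th and 95th percentile
#' (linear interpolation, R quantile type 7), skewness (standardized third
#' central moment) and excess kurtosis (fourth standardized moment minus 3;
#' normal = 0). Voxels flagged invalid by the T1 fit are excluded before
#' anything is computed.
#'
#' @param t1_map [volume_grid()] in ms.
#' @param mask binary [volume_grid()].
#' @return named list with fields `volume, mean, sd, median, p5, p95,
#'   skewness, kurtosis` and attribute `n_voxels`. A single-voxel mask gives
#'   `sd = 0` and `NA` skewness/kurtosis (flagged via attribute
#'   `moments_undefined`).
#' @export
histogram_features <- function(t1_map, mask) {
  stop_if_incongruent(t1_map, mask, "t1 map and mask")
  v <- masked_values(t1_map, mask)
  if (!length(v)) stop("mask is empty (or contains only invalid voxels)")
  voxvol_cm3 <- prod(t1_map$spacing) / 1000
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  out <- list(
    volume = n * voxvol_cm3,
    mean = mu,
    sd = stats::sd(v),
    median = stats::median(v),
    p5 = unname(stats::quantile(v, 0.05, type = 7)),
    p95 = unname(stats::quantile(v, 0.95, type = 7)))
  if (n == 1) out$sd <- 0
  if (m2 > 0) {
    out$skewness <- mean((v - mu)^3) / m2^1.5
    out$kurtosis <- mean((v - mu)^4) / m2^2 - 3
  } else {
    out$skewness <- NA_real_
    out$kurtosis <- NA_real_
    attr(out, "moments_undefined") <- TRUE
  }
  attr(out, "n_voxels") <- n
  out
}

#' Quantize masked T1 values to gray levels
#'
#' Equal-width bins over the masked min-max range (default) or a fixed ms
#' range; the maximum value lands in the top bin. Outside the mask the label
#' is the sentinel -1. A constant masked image maps entirely to level 0.
#'
#' @param t1_map [volume_grid()].
#' @param mask binary [volume_grid()].
#' @param n_levels number of gray levels.
#' @param range_rule,range see [feature_config()].
#' @return a `quantized_volume`: `labels` (integer array, -1 outside mask),
#'   `n_levels`, `bin_edges` (length `n_levels + 1`).
#' @export
quantize <- function(t1_map, mask, n_levels = 32L,
                     range_rule = c("minmax", "fixed"), range = NULL) {
  range_rule <- match.arg(range_rule)
  stop_if_incongruent(t1_map, mask, "t1 map and mask")
  inv <- attr(t1_map, "invalid_value")
  inmask <- mask$values > 0.5
  if (!is.null(inv)) inmask <- inmask & (t1_map$values != inv)
  if (!any(inmask)) stop("mask is empty")
  v <- t1_map$values[inmask]
  rng <- if (range_rule == "fixed") {
    if (is.null(range)) stop("fixed range rule requires `range`")
    as.numeric(range)
  } else range(v)
  labels <- array(-1L, dim(t1_map$values))
  if (rng[2] > rng[1]) {
    edges <- seq(rng[1], rng[2], length.out = n_levels + 1)
    lv <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels)
    lv <- pmin(pmax(lv, 0), n_levels - 1)  # top edge into top bin
  } else {
    edges <- rng[1] + seq(0, 1, length.out = n_levels + 1)
    lv <- rep(0L, length(v))
  }
  labels[inmask] <- as.integer(lv)
  structure(list(labels = labels, n_levels = as.integer(n_levels),
                 bin_edges = edges, spacing = t1_map$spacing),
            class = "quantized_volume")
}

#' Masked 3D gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs over the given displacement vectors,
#' pooled into one matrix; only pairs with both voxels inside the mask
#' contribute. With `symmetric = TRUE` each displacement also counts in its
#' negated direction, making `p` symmetric. From the normalized `p` the
#' gray-level difference distribution `p_diff(k) = sum_{|i-j|=k} p(i,j)` and
#' its mean `mu_diff` are derived.
#'
#' @param q a `quantized_volume` from [quantize()].
#' @param offsets integer matrix of displacements (rows).
#' @param symmetric logical.
#' @return a `glcm_matrix`: `p` (N_g x N_g), `p_diff` (length N_g),
#'   `mu_diff`, `offsets`, `symmetric`, `n_pairs`.
#' @export
glcm <- function(q, offsets = unit_offsets_3d(), symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_volume"))
  offsets <- matrix(as.integer(offsets), ncol = 3)
  if (any(rowSums(abs(offsets)) == 0)) stop("offsets must be nonzero")
  ng <- q$n_levels
  d <- dim(q$labels)
  counts <- matrix(0, ng, ng)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    # source index range such that source + offset stays in the grid
    sx <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    sy <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    sz <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    if (!length(sx) || !length(sy) || !length(sz)) next
    A <- q$labels[sx, sy, sz, drop = FALSE]
    B <- q$labels[sx + o[1], sy + o[2], sz + o[3], drop = FALSE]
    ok <- A >= 0L & B >= 0L
    if (!any(ok)) next
    tc <- tabulate(A[ok] * ng + B[ok] + 1L, nbins = ng * ng)
    counts <- counts + matrix(tc, ng, ng, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0)
    stop("no valid voxel pairs: mask voxels are isolated for every offset")
  p <- counts / n_pairs
  k <- abs(row(p) - col(p))
  p_diff <- as.numeric(rowsum(as.vector(p), as.vector(k)))
  structure(list(p = p, p_diff = p_diff,
                 mu_diff = sum(seq(0, ng - 1) * p_diff),
                 offsets = offsets, symmetric = symmetric,
                 n_pairs = n_pairs),
            class = "glcm_matrix")
}

#' Haralick-style texture features of a GLCM
#'
#' The four second-order features of the whole-liver workflow, with base-2
#' logarithms and the convention 0 log 0 = 0:
#' \describe{
#'   \item{entropy}{\eqn{-\sum_{ij} p(i,j)\log_2 p(i,j)} — randomness of the
#'     gray levels.}
#'   \item{contrast}{\eqn{\sum_{ij} (i-j)^2 p(i,j)} — amount of gray-level
#'     variation.}
#'   \item{diff_entropy}{\eqn{-\sum_k p_{x-y}(k)\log_2 p_{x-y}(k)}.}
#'   \item{diff_variance}{\eqn{\sum_k (k-\mu_{x-y})^2 p_{x-y}(k)} — variance
#'     of the gray-level difference distribution.}
#' }
#'
#' @param g a `glcm_matrix` from [glcm()].
#' @return named list `entropy, contrast, diff_entropy, diff_variance`.
#' @export
texture_features <- function(g) {
  stopifnot(inherits(g, "glcm_matrix"))
  xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)
  k <- seq_along(g$p_diff) - 1
  list(
    entropy = -sum(xlog2x(g$p)),
    contrast = sum((row(g$p) - col(g$p))^2 * g$p),
    diff_entropy = -sum(xlog2x(g$p_diff)),
    diff_variance = sum((k - g$mu_diff)^2 * g$p_diff))
}

#' Names of the 12 whole-liver features
#' @return character vector in canonical order.
#' @export
feature_names <- function() {
  c("volume", "mean", "sd", "median", "p5", "p95", "skewness", "kurtosis",
    "entropy", "contrast", "diff_entropy", "diff_variance")
}

#' Extract the full 12-feature vector from a masked T1 map
#'
#' One-call composition of [histogram_features()], [quantize()], [glcm()]
#' and [texture_features()]; the configuration used is recorded on the
#' result (`config` attribute) so every vector is traceable to its
#' conventions.
#'
#' @param t1_map [volume_grid()].
#' @param mask binary [volume_grid()].
#' @param config a [feature_config()].
#' @return named list of the 12 features (see [feature_names()]).
#' @export
extract_all <- function(t1_map, mask, config = feature_config()) {
  h <- histogram_features(t1_map, mask)
  q <- quantize(t1_map, mask, n_levels = config$n_levels,
                range_rule = config$range_rule, range = config$range)
  g <- glcm(q, offsets = config$offsets, symmetric = config$symmetric)
  tx <- texture_features(g)
  out <- c(h[c("volume", "mean", "sd", "median", "p5", "p95",
               "skewness", "kurtosis")], tx)
  attr(out, "config") <- config
  attr(out, "n_voxels") <- attr(h, "n_voxels")
  out
}
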