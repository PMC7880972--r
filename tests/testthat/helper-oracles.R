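# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by the dumbest correct route (dense algebra, brute-force
# enumeration, textbook formulas) so it shares no code with the package
# path it checks.

# brute-force triple-loop GLCM: counts over explicit voxel pairs
oracle_glcm <- function(labels, n_levels, offsets, symmetric = TRUE) {
  d <- dim(labels)
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      i2 <- i + o[1]; j2 <- j + o[2]; k2 <- k + o[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] ||
          k2 < 1 || k2 > d[3]) next
      a <- labels[i, j, k]; b <- labels[i2, j2, k2]
      if (a < 0 || b < 0) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# textbook sums over a GLCM probability matrix
oracle_texture <- function(p) {
  ng <- nrow(p)
  ent <- 0; con <- 0
  pd <- numeric(ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    con <- con + (i - j)^2 * p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
  }
  de <- -sum(ifelse(pd > 0, pd * log2(pd), 0))
  mu <- sum((0:(ng - 1)) * pd)
  dv <- sum(((0:(ng - 1)) - mu)^2 * pd)
  list(entropy = ent, contrast = con, diff_entropy = de, diff_variance = dv)
}

# dense random-walker solve: full graph Laplacian, base-R linear algebra
oracle_random_walker <- function(values, seed_idx, seed_fg, beta,
                                 eps = 1e-10) {
  d <- dim(values)
  n <- prod(d)
  g <- as.vector(values)
  rng <- range(g)
  if (rng[2] > rng[1]) g <- (g - rng[1]) / (rng[2] - rng[1]) else g <- g * 0
  W <- matrix(0, n, n)
  lin <- function(i, j, k) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lin(i, j, k)
    for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      i2 <- i + o[1]; j2 <- j + o[2]; k2 <- k + o[3]
      if (i2 > d[1] || j2 > d[2] || k2 > d[3]) next
      b <- lin(i2, j2, k2)
      w <- exp(-beta * (g[a] - g[b])^2) + eps
      W[a, b] <- w; W[b, a] <- w
    }
  }
  L <- diag(rowSums(W)) - W
  x <- numeric(n)
  x[seed_idx] <- as.numeric(seed_fg)
  free <- setdiff(seq_len(n), seed_idx)
  x[free] <- solve(L[free, free], -L[free, seed_idx] %*% x[seed_idx])
  x
}

# per-voxel nonlinear least-squares SPGR fit (the iterative route the
# two-point linearization replaces)
oracle_nls_t1 <- function(s1, s2, flips_deg, b1, tr) {
  a <- b1 * flips_deg * pi / 180
  obj <- function(par) {
    t1 <- par[1]; m0 <- par[2]
    e1 <- exp(-tr / t1)
    pred <- m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
    sum((pred - c(s1, s2))^2)
  }
  stats::optim(c(800, max(s1, s2) * 20), obj,
               method = "L-BFGS-B", lower = c(10, 1e-6),
               control = list(factr = 1e4))$par[1]
}

# DeLong paired z from an independently coded structural-components route
oracle_delong_z <- function(sa, sb, labels) {
  x1 <- sa[labels == 1]; y1 <- sa[labels == 0]
  x2 <- sb[labels == 1]; y2 <- sb[labels == 0]
  m <- length(x1); n <- length(y1)
  psi <- function(x, y) ifelse(x > y, 1, ifelse(x == y, 0.5, 0))
  a1 <- 0; a2 <- 0
  V10 <- matrix(0, m, 2); V01 <- matrix(0, n, 2)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    p1 <- psi(x1[i], y1[j]); p2 <- psi(x2[i], y2[j])
    a1 <- a1 + p1; a2 <- a2 + p2
    V10[i, 1] <- V10[i, 1] + p1 / n; V10[i, 2] <- V10[i, 2] + p2 / n
    V01[j, 1] <- V01[j, 1] + p1 / m; V01[j, 2] <- V01[j, 2] + p2 / m
  }
  a1 <- a1 / (m * n); a2 <- a2 / (m * n)
  S <- cov(V10) / m + cov(V01) / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v <= 0) return(0)
  (a1 - a2) / sqrt(v)
}

# ICC(3,1) from ANOVA mean squares computed with aov()
oracle_icc31 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse)
}

# tiny constant-image quantized volume for GLCM edge cases
make_quantized <- function(labels, n_levels) {
  structure(list(labels = labels, n_levels = as.integer(n_levels),
                 bin_edges = seq(0, 1, length.out = n_levels + 1),
                 spacing = c(1, 1, 1)),
            class = "quantized_volume")
}

# random masked label volume for property tests
random_labels <- function(d, n_levels, p_mask = 0.8) {
  lab <- array(sample(0:(n_levels - 1), prod(d), replace = TRUE), d)
  lab[stats::runif(prod(d)) > p_mask] <- -1L
  storage.mode(lab) <- "integer"
  lab
}
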