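#' Labeled seed voxels for random-walker segmentation
#'
#' Foreground seeds mark liver parenchyma; background seeds mark everything
#' outside the volume of interest (outside the liver and inside vessels).
#' Coordinates are stored 1-based (R convention); the CSV interchange format
#' is 0-based (see [read_seeds()]).
#'
#' @param coords integer matrix, one row per seed, columns x,y,z (1-based).
#' @param labels character vector, "foreground" or "background" per row.
#' @return a `seed_set` object.
#' @export
seed_set <- function(coords, labels) {
  coords <- matrix(as.integer(coords), ncol = 3)
  labels <- as.character(labels)
  if (nrow(coords) != length(labels))
    stop("one label per seed coordinate required")
  if (!all(labels %in% c("foreground", "background")))
    stop("labels must be 'foreground' or 'background'")
  if (!any(labels == "foreground") || !any(labels == "background"))
    stop("at least one seed of each label is required")
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  both <- intersect(key[labels == "foreground"], key[labels == "background"])
  if (length(both))
    stop("seed voxel(s) carry both labels: ", paste(both, collapse = "; "))
  structure(list(coords = coords, labels = labels), class = "seed_set")
}

#' Read / write seeds as CSV with 0-based voxel indices
#'
#' Columns `x,y,z,label`; indices are 0-based in the file, converted to
#' 1-based in memory.
#' @param path CSV path.
#' @param seeds a [seed_set()].
#' @return `read_seeds` returns a [seed_set()]; `write_seeds` the path.
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  seed_set(as.matrix(df[, c("x", "y", "z")]) + 1L, df$label)
}

#' @rdname read_seeds
#' @export
write_seeds <- function(seeds, path) {
  df <- data.frame(x = seeds$coords[, 1] - 1L, y = seeds$coords[, 2] - 1L,
                   z = seeds$coords[, 3] - 1L, label = seeds$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_seeds_in_grid <- function(seeds, d) {
  ok <- seeds$coords[, 1] >= 1 & seeds$coords[, 1] <= d[1] &
        seeds$coords[, 2] >= 1 & seeds$coords[, 2] <= d[2] &
        seeds$coords[, 3] >= 1 & seeds$coords[, 3] <= d[3]
  if (!all(ok)) stop(sum(!ok), " seed(s) fall outside the image grid")
  invisible(TRUE)
}

# 6-connected edge list of a d[1] x d[2] x d[3] lattice, as linear indices.
lattice_edges <- function(d) {
  n <- prod(d)
  idx <- array(seq_len(n), d)
  e <- vector("list", 3)
  if (d[1] > 1)
    e[[1]] <- cbind(as.vector(idx[-d[1], , , drop = FALSE]),
                    as.vector(idx[-1, , , drop = FALSE]))
  if (d[2] > 1)
    e[[2]] <- cbind(as.vector(idx[, -d[2], , drop = FALSE]),
                    as.vector(idx[, -1, , drop = FALSE]))
  if (d[3] > 1)
    e[[3]] <- cbind(as.vector(idx[, , -d[3], drop = FALSE]),
                    as.vector(idx[, , -1, drop = FALSE]))
  do.call(rbind, e[!vapply(e, is.null, logical(1))])
}

# Jacobi-preconditioned conjugate gradients for sparse SPD systems.
cg_solve <- function(A, b, tol = 1e-5, maxit = 10000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' Seeded random-walker segmentation
#'
#' Solves the combinatorial Dirichlet problem on the 6-connected voxel graph:
#' intensities are min-max normalized to \[0,1\], edges between neighbouring
#' voxels i,j get Gaussian weights \eqn{w_{ij} = \exp(-\beta (g_i-g_j)^2) +
#' \epsilon}, and the probability that a random walk started at each
#' unseeded voxel first reaches a foreground seed is the harmonic function
#' solving \eqn{L_U x_U = W_{US}\, m_S} with boundary values 1 at foreground
#' and 0 at background seeds. Small systems are solved directly (sparse
#' Cholesky); large ones with Jacobi-preconditioned conjugate gradients to
#' relative residual `solver_tol`.
#'
#' @param image [volume_grid()]; finite everywhere. Segmentation is run on
#'   the higher-flip SPGR magnitude image in the liver workflow.
#' @param seeds [seed_set()].
#' @param beta edge-weight sharpness on normalized intensities (default 130,
#'   standard random-walker practice).
#' @param solver_tol relative residual tolerance of the linear solve.
#' @param direct_max use the direct sparse solver when the number of
#'   unseeded voxels is at most this.
#' @return a `segmentation_result` with elements `probability`
#'   ([volume_grid()], foreground probability), `mask` (binary
#'   [volume_grid()], probability >= 0.5, ties to foreground), `beta`,
#'   `solver_tol`, `seeds`.
#' @export
random_walker_segment <- function(image, seeds, beta = 130,
                                  solver_tol = 1e-5, direct_max = 8000L) {
  stopifnot(is_volume_grid(image), inherits(seeds, "seed_set"))
  v <- image$values
  if (any(!is.finite(v))) stop("image must be finite everywhere")
  d <- dim(v)
  check_seeds_in_grid(seeds, d)
  n <- prod(d)
  rng <- range(v)
  g <- if (rng[2] > rng[1]) (as.vector(v) - rng[1]) / (rng[2] - rng[1])
       else numeric(n)
  eps <- 1e-10
  edges <- lattice_edges(d)
  w <- exp(-beta * (g[edges[, 1]] - g[edges[, 2]])^2) + eps
  sidx <- seeds$coords[, 1] +
    (seeds$coords[, 2] - 1L) * d[1] +
    (seeds$coords[, 3] - 1L) * d[1] * d[2]
  m <- as.numeric(seeds$labels == "foreground")
  # collapse duplicate seed rows (same voxel, same label)
  dup <- duplicated(sidx)
  sidx_u <- sidx[!dup]; m_u <- m[!dup]
  prob <- numeric(n)
  prob[sidx_u] <- m_u
  free <- setdiff(seq_len(n), sidx_u)
  if (length(free)) {
    # map to compact indices: positive for free nodes, negative for seeds
    code <- integer(n)
    code[free] <- seq_along(free)
    code[sidx_u] <- -seq_along(sidx_u)
    c1 <- code[edges[, 1]]; c2 <- code[edges[, 2]]
    ff <- c1 > 0 & c2 > 0
    fs <- c1 > 0 & c2 < 0
    sf <- c1 < 0 & c2 > 0
    # degree of each free node = sum of weights over ALL incident edges
    tab <- function(i, wt) {
      out <- numeric(length(free))
      if (length(i)) {
        s <- rowsum(wt, i)
        out[as.integer(rownames(s))] <- s[, 1]
      }
      out
    }
    deg <- tab(c(c1[c1 > 0], c2[c2 > 0]), c(w[c1 > 0], w[c2 > 0]))
    # symmetric class routes solve() to CHOLMOD (sparse Cholesky)
    Luu <- Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = c(c1[ff], c2[ff], seq_along(free)),
      j = c(c2[ff], c1[ff], seq_along(free)),
      x = c(-w[ff], -w[ff], deg),
      dims = c(length(free), length(free))))
    # rhs = W_US m_S: weight into foreground seeds only
    ri <- c(c1[fs], c2[sf])
    rs <- c(-c2[fs], -c1[sf])
    rw <- c(w[fs], w[sf]) * m_u[rs]
    b <- numeric(length(free))
    if (length(ri)) {
      s <- rowsum(rw, ri)
      b[as.integer(rownames(s))] <- s[, 1]
    }
    xu <- if (length(free) <= direct_max)
      as.numeric(Matrix::solve(Luu, b))
    else cg_solve(Luu, b, tol = solver_tol)
    prob[free] <- pmin(pmax(xu, 0), 1)  # clip solver round-off
  }
  p <- volume_grid(array(prob, d), image$spacing, image$origin)
  mask <- volume_grid(array(as.numeric(prob >= 0.5), d),
                      image$spacing, image$origin)
  structure(list(probability = p, mask = mask, beta = beta,
                 solver_tol = solver_tol, seeds = seeds,
                 edits = list()),
            class = "segmentation_result")
}

#' Manually refine a segmentation mask
#'
#' Applies voxel-level corrections to the mask after visual review, as in
#' the clinical workflow where initial random-walker output is adjusted
#' slice by slice. The probability map is left untouched and every edit is
#' logged on the result.
#'
#' @param result a `segmentation_result`.
#' @param add,remove integer matrices of 1-based voxel coordinates (columns
#'   x,y,z) to force into / out of the mask. The two sets must not overlap.
#' @return the updated `segmentation_result`; if the mask becomes empty an
#'   `empty_mask` attribute flags it and a warning is raised.
#' @export
refine_mask <- function(result, add = NULL, remove = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  d <- dim(result$mask$values)
  norm <- function(m) {
    if (is.null(m) || !length(m)) return(NULL)
    m <- matrix(as.integer(m), ncol = 3)
    if (any(m < 1) || any(m[, 1] > d[1]) || any(m[, 2] > d[2]) ||
        any(m[, 3] > d[3]))
      stop("edit coordinates fall outside the grid")
    m
  }
  add <- norm(add); remove <- norm(remove)
  if (!is.null(add) && !is.null(remove)) {
    ka <- paste(add[, 1], add[, 2], add[, 3])
    kr <- paste(remove[, 1], remove[, 2], remove[, 3])
    if (length(intersect(ka, kr)))
      stop("add and remove sets overlap")
  }
  mv <- result$mask$values
  if (!is.null(add)) mv[add] <- 1
  if (!is.null(remove)) mv[remove] <- 0
  result$mask$values <- mv
  result$edits <- c(result$edits,
                    list(list(n_add = if (is.null(add)) 0L else nrow(add),
                              n_remove = if (is.null(remove)) 0L
                                         else nrow(remove))))
  if (sum(mv) == 0) {
    attr(result, "empty_mask") <- TRUE
    warning("refined mask is empty")
  }
  result
}

#' Propagate a mask onto another volume's grid
#'
#' Re-associates a binary mask with the geometry of a target volume (the T1
#' map, acquired in the same scan as the segmented image). For congruent
#' grids this is a metadata operation; otherwise the mask is resampled with
#' nearest-neighbour interpolation. Physically disjoint volumes are an
#' error.
#'
#' @param mask binary [volume_grid()].
#' @param target [volume_grid()] providing the output geometry.
#' @return binary [volume_grid()] on the target grid.
#' @export
propagate_mask <- function(mask, target) {
  stopifnot(is_volume_grid(mask), is_volume_grid(target))
  em <- physical_extent(mask); et <- physical_extent(target)
  if (any(em[2, ] < et[1, ]) || any(et[2, ] < em[1, ]))
    stop("mask and target volumes occupy disjoint physical extents")
  if (grids_congruent(mask, target))
    return(volume_grid(mask$values, target$spacing, target$origin))
  out <- resample_to(mask, target, method = "nearest")
  out$values[] <- as.numeric(out$values >= 0.5)
  out
}

#' Dice overlap of two binary masks
#' @param a,b binary [volume_grid()] or arrays.
#' @return Dice coefficient in \[0,1\].
#' @export
dice <- function(a, b) {
  av <- if (is_volume_grid(a)) a$values else a
  bv <- if (is_volume_grid(b)) b$values else b
  2 * sum(av > 0.5 & bv > 0.5) / (sum(av > 0.5) + sum(bv > 0.5))
}
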