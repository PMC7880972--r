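#' 3D scalar volumes with voxel geometry
#'
#' A `volume_grid` is the carrier type for every image in the pipeline:
#' SPGR magnitude images, B1 maps, T1 maps and binary masks. It wraps a
#' numeric 3D array together with the voxel spacing (mm per axis) and the
#' physical position of the first voxel centre (mm), i.e. an axis-aligned
#' affine from 0-based voxel indices to scanner millimetres.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, mm per axis; all > 0.
#' @param origin numeric length-3, physical mm of voxel (0,0,0). Default 0.
#' @return A `volume_grid` object.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Test whether two volumes share shape and geometry
#'
#' @param a,b `volume_grid` objects.
#' @param tol relative tolerance on spacing/origin.
#' @return logical.
#' @export
grids_congruent <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(1, abs(a$spacing))) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin), abs(b$origin)))
}

stop_if_incongruent <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have mismatched grid shapes: %s vs %s", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  invisible(TRUE)
}

# physical coordinates (mm) of voxel centres along one axis, 1-based index
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

# physical extent [min, max] of the voxel-centre lattice per axis
physical_extent <- function(vol) {
  d <- dim(vol$values)
  rbind(vol$origin, vol$origin + (d - 1) * vol$spacing)
}

#' Resample a volume onto the lattice of a target volume
#'
#' Maps each target voxel centre into the source volume through the
#' axis-aligned affines and interpolates. Used for B1 maps acquired at a
#' coarser matrix than the T1 map (trilinear) and for mask propagation
#' across grids (nearest neighbour).
#'
#' @param vol source `volume_grid`.
#' @param target `volume_grid` defining the output lattice.
#' @param method "trilinear" or "nearest".
#' @return `volume_grid` on the target lattice.
#' @export
resample_to <- function(vol, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  sd <- dim(vol$values); td <- dim(target$values)
  # continuous source index (1-based) of each target voxel centre, per axis
  idx <- lapply(1:3, function(a) {
    (axis_coords(target, a) - vol$origin[a]) / vol$spacing[a] + 1
  })
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  out <- array(0, td)
  if (method == "nearest") {
    ii <- clamp(round(idx[[1]]), 1, sd[1])
    jj <- clamp(round(idx[[2]]), 1, sd[2])
    kk <- clamp(round(idx[[3]]), 1, sd[3])
    out[] <- vol$values[cbind(rep(ii, times = td[2] * td[3]),
                              rep(rep(jj, each = td[1]), times = td[3]),
                              rep(kk, each = td[1] * td[2]))]
  } else {
    x <- clamp(idx[[1]], 1, sd[1]); y <- clamp(idx[[2]], 1, sd[2])
    z <- clamp(idx[[3]], 1, sd[3])
    x0 <- pmin(floor(x), sd[1] - 1L); y0 <- pmin(floor(y), sd[2] - 1L)
    z0 <- pmin(floor(z), sd[3] - 1L)
    if (sd[1] == 1L) x0 <- rep(1, length(x))
    if (sd[2] == 1L) y0 <- rep(1, length(y))
    if (sd[3] == 1L) z0 <- rep(1, length(z))
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    X0 <- rep(x0, times = td[2] * td[3]); FX <- rep(fx, times = td[2] * td[3])
    Y0 <- rep(rep(y0, each = td[1]), times = td[3])
    FY <- rep(rep(fy, each = td[1]), times = td[3])
    Z0 <- rep(z0, each = td[1] * td[2]); FZ <- rep(fz, each = td[1] * td[2])
    v <- vol$values
    at <- function(dx, dy, dz) {
      v[cbind(pmin(X0 + dx, sd[1]), pmin(Y0 + dy, sd[2]), pmin(Z0 + dz, sd[3]))]
    }
    out[] <-
      at(0,0,0) * (1-FX)*(1-FY)*(1-FZ) + at(1,0,0) * FX*(1-FY)*(1-FZ) +
      at(0,1,0) * (1-FX)*FY*(1-FZ)     + at(1,1,0) * FX*FY*(1-FZ) +
      at(0,0,1) * (1-FX)*(1-FY)*FZ     + at(1,0,1) * FX*(1-FY)*FZ +
      at(0,1,1) * (1-FX)*FY*FZ         + at(1,1,1) * FX*FY*FZ
  }
  volume_grid(out, target$spacing, target$origin)
}
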