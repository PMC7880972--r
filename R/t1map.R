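#' Acquisition parameters for the two-flip SPGR protocol
#'
#' @param tr repetition time, ms.
#' @param flip_angles nominal flip angles in degrees; exactly two, both in
#'   (0, 90). Defaults to the 3/15 degree pair used for liver T1 mapping
#'   with a 1000 ms target T1.
#' @param te echo time, ms (metadata only; the SPGR T1 fit ignores TE).
#' @return an `acq_params` object.
#' @export
acq_params <- function(tr = 4.61, flip_angles = c(3, 15), te = 2.26) {
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) stop("tr must be > 0")
  if (length(flip_angles) != 2)
    stop("exactly two flip angles are required")
  if (any(flip_angles <= 0) || any(flip_angles >= 90))
    stop("flip angles must lie in (0, 90) degrees")
  structure(list(tr = tr, flip_angles = sort(as.numeric(flip_angles)),
                 te = te), class = "acq_params")
}

#' Sentinel marking voxels where the T1 fit is non-physical
#'
#' Voxels with a non-physical linearized slope (E1 outside (0,1)), zero
#' signal, or a degenerate system are assigned this value and must be
#' excluded from any masked statistic ([histogram_features()] does so).
#' @export
T1_INVALID <- -1

#' Steady-state spoiled gradient-echo signal
#'
#' \deqn{S = M_0 \sin(b_1\alpha)\,\frac{1 - E_1}{1 - E_1\cos(b_1\alpha)},
#'   \quad E_1 = e^{-TR/T_1}}
#'
#' The effective flip angle is the nominal angle scaled by the transmit
#' efficiency `b1`. All arguments recycle, so whole volumes can be
#' forward-simulated in one call.
#'
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param m0 equilibrium signal (proton density x gain).
#' @param flip_nominal nominal flip angle, degrees.
#' @param b1 transmit efficiency (fraction of nominal flip), default 1.
#' @param tr repetition time, ms.
#' @return noiseless signal, same shape as the broadcast inputs.
#' @export
spgr_signal <- function(t1, m0, flip_nominal, b1 = 1, tr = 4.61) {
  if (any(t1 <= 0, na.rm = TRUE)) stop("t1 must be positive")
  if (tr <= 0) stop("tr must be positive")
  a <- b1 * flip_nominal * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' B1-corrected two-point VFA T1 fit
#'
#' Per-voxel DESPOT1-style linearization of the SPGR equation: with
#' \eqn{y_i = S_i/\sin(\alpha_i^{eff})} and \eqn{x_i = S_i/\tan(\alpha_i^{eff})}
#' the signal model is the line \eqn{y = E_1 x + M_0(1-E_1)}, so with exactly
#' two flip angles the slope is \eqn{E_1 = (y_2-y_1)/(x_2-x_1)} and
#' \eqn{T_1 = -TR/\ln E_1}. With two points the linear solution is exact
#' (no iterative fit needed). The effective flip angle at each voxel is the
#' nominal angle scaled by the B1 map, which is trilinearly resampled onto
#' the signal grid when acquired at a different matrix.
#'
#' Voxels where the slope is non-physical (\eqn{E_1 \le 0} or \eqn{\ge 1}),
#' both signals vanish, or the system is degenerate are set to [T1_INVALID]
#' rather than raising: downstream masked statistics must (and do) exclude
#' them.
#'
#' @param spgr_low,spgr_high [volume_grid()] magnitude images at the lower
#'   and higher flip angle.
#' @param b1_map [volume_grid()] of transmit efficiency in (0, 2]; may be on
#'   a coarser grid. Pass `NULL` to assume a perfect transmit field (B1 = 1).
#' @param acq [acq_params()].
#' @return [volume_grid()] T1 map in ms, with attribute `invalid_value`.
#' @export
fit_t1_vfa <- function(spgr_low, spgr_high, b1_map = NULL,
                       acq = acq_params()) {
  stop_if_incongruent(spgr_low, spgr_high, "SPGR images")
  if (is.null(b1_map)) {
    b1 <- array(1, dim(spgr_low$values))
  } else {
    if (!identical(dim(b1_map$values), dim(spgr_low$values)))
      b1_map <- resample_to(b1_map, spgr_low, method = "trilinear")
    b1 <- b1_map$values
    nbad <- sum(b1 <= 0)
    if (nbad > 0)
      stop(sprintf("b1 map contains %d voxel(s) <= 0", nbad))
  }
  a1 <- b1 * acq$flip_angles[1] * pi / 180
  a2 <- b1 * acq$flip_angles[2] * pi / 180
  s1 <- spgr_low$values
  s2 <- spgr_high$values
  y1 <- s1 / sin(a1); x1 <- s1 / tan(a1)
  y2 <- s2 / sin(a2); x2 <- s2 / tan(a2)
  dx <- x2 - x1
  e1 <- ifelse(abs(dx) > 0, (y2 - y1) / dx, NA_real_)
  t1 <- array(T1_INVALID, dim(s1))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  t1[ok] <- -acq$tr / log(e1[ok])
  out <- volume_grid(t1, spgr_low$spacing, spgr_low$origin)
  attr(out, "invalid_value") <- T1_INVALID
  attr(out, "n_invalid") <- sum(!ok)
  out
}
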