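#' Rigid-body motion trace
#'
#' Wraps a timepoints x 6 matrix of rigid-body realignment parameters
#' (columns 1-3: translations in mm; columns 4-6: rotations) and records
#' the rotation unit, which downstream computations require.
#'
#' @param params numeric matrix with 6 columns.
#' @param rotation_unit `"radians"` or `"degrees"`.
#' @return a `motion_trace` object.
#' @export
motion_trace <- function(params, rotation_unit = c("radians", "degrees")) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion trace must have 6 columns")
  rotation_unit <- match.arg(rotation_unit)
  structure(params, rotation_unit = rotation_unit, class = "motion_trace")
}

rotations_in_radians <- function(trace) {
  unit <- attr(trace, "rotation_unit")
  if (is.null(unit)) stop("motion trace has no recorded rotation unit")
  rot <- unclass(trace)[, 4:6, drop = FALSE]
  if (unit == "degrees") rot * pi / 180 else rot
}

#' Framewise displacement from a motion trace
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations plus `head_radius` times the sum of absolute backward
#' differences of the three rotations (converted to radians, i.e. arc
#' length on a sphere of that radius). The first timepoint has FD 0.
#'
#' @param trace a [motion_trace()].
#' @param head_radius assumed head radius in mm (default 50).
#' @return numeric vector of per-timepoint FD values in mm.
#' @export
framewise_displacement <- function(trace, head_radius = 50) {
  if (head_radius <= 0) stop("head_radius must be positive")
  trans <- unclass(trace)[, 1:3, drop = FALSE]
  rot <- rotations_in_radians(trace)
  d_trans <- abs(diff(trans))
  d_rot <- abs(diff(rot))
  c(0, rowSums(d_trans) + head_radius * rowSums(d_rot))
}

#' Motion quality control
#'
#' A scan fails QC if its mean framewise displacement exceeds
#' `mean_fd_max`, if any translation exceeds `trans_max` in absolute value
#' in any of x, y, z, or if any rotation exceeds `rot_max` degrees in
#' absolute value. Defaults reproduce the conventional thresholds of 1 mm
#' mean FD, 2 mm maximal translation and 1 degree maximal rotation.
#'
#' @param trace a [motion_trace()].
#' @param mean_fd_max mean-FD threshold in mm.
#' @param trans_max maximal-translation threshold in mm.
#' @param rot_max maximal-rotation threshold in degrees.
#' @param head_radius head radius (mm) used for the FD computation.
#' @return a `qc_result` list: `mean_fd`, `max_translation`,
#'   `max_rotation` (degrees), `passed`, `reasons`.
#' @export
motion_qc <- function(trace, mean_fd_max = 1.0, trans_max = 2.0,
                      rot_max = 1.0, head_radius = 50) {
  if (mean_fd_max <= 0 || trans_max <= 0 || rot_max <= 0)
    stop("QC thresholds must be positive")
  fd <- framewise_displacement(trace, head_radius)
  max_trans <- max(abs(unclass(trace)[, 1:3]))
  max_rot_deg <- max(abs(rotations_in_radians(trace))) * 180 / pi
  reasons <- character(0)
  if (mean(fd) > mean_fd_max) reasons <- c(reasons, "mean-FD")
  if (max_trans > trans_max) reasons <- c(reasons, "max-translation")
  if (max_rot_deg > rot_max) reasons <- c(reasons, "max-rotation")
  structure(list(mean_fd = mean(fd), max_translation = max_trans,
                 max_rotation = max_rot_deg,
                 passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_result")
}

#' Regress nuisance time series out of a 4D volume
#'
#' Each voxel's time series is replaced by the residuals of an ordinary
#' least-squares fit on an intercept plus the given regressors (e.g. the
#' six motion parameters, white-matter and CSF signals). With no
#' regressors, the output is the per-voxel demeaned series.
#'
#' @param volume 4D array (x, y, z, time).
#' @param regressors timepoints x R matrix, or `NULL` for intercept only.
#' @return residual 4D array of the same shape.
#' @export
regress_nuisance <- function(volume, regressors = NULL) {
  dm <- dim(volume)
  if (length(dm) != 4L) stop("volume must be 4D")
  nt <- dm[4]
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != nt)
      stop("regressor rows must equal the number of timepoints")
    if (ncol(regressors) >= nt)
      stop("more regressors than timepoints")
  }
  series <- matrix(volume, prod(dm[1:3]), nt)   # voxels x time
  resid <- t(ols_residuals(t(series), regressors))
  array(resid, dim = dm)
}

# reflect-boundary 1D convolution along the first axis of a matrix
conv_reflect <- function(mat, kernel) {
  n <- nrow(mat)
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(n) + off
    idx[idx < 1L] <- 1L - idx[idx < 1L]          # mirror with edge repeat
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]
    out <- out + kernel[j] * mat[idx, , drop = FALSE]
  }
  out
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis, expressed in voxel units via `voxel_size`. Boundaries are handled
#' by reflection, so constant images are preserved exactly and the mean
#' intensity is conserved. `fwhm = 0` is the identity. 4D inputs are
#' smoothed volume-by-volume over the first three axes.
#'
#' @param volume 3D or 4D numeric array.
#' @param fwhm full width at half maximum, in mm.
#' @param voxel_size voxel edge length in mm (scalar or length-3).
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, fwhm, voxel_size = 1) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(volume)
  dm <- dim(volume)
  if (!length(dm) %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  voxel_size <- rep_len(voxel_size, 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size

  smooth3d <- function(vol) {
    for (ax in 1:3) {
      if (sigma[ax] <= 0) next
      r <- max(1L, ceiling(4 * sigma[ax]))
      k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
      k <- k / sum(k)
      perm <- c(ax, setdiff(1:3, ax))
      v <- aperm(vol, perm)
      dv <- dim(v)
      v <- array(conv_reflect(matrix(v, dv[1]), k), dim = dv)
      vol <- aperm(v, order(perm))
    }
    vol
  }
  if (length(dm) == 3L) return(smooth3d(volume))
  for (t in seq_len(dm[4])) volume[, , , t] <- smooth3d(volume[, , , t])
  volume
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' The sum of discrete-Fourier amplitude values (moduli, not powers) over
#' the low-frequency band divided by the sum over the full detectable
#' band. The DC bin is excluded from both sums, so the statistic does not
#' depend on the series mean; the full band is capped at the Nyquist
#' frequency when `full_band_max` exceeds it. The result lies in
#' `[0, 1]` and is invariant to positive rescaling of the series.
#'
#' @param series numeric time series (at least 32 points).
#' @param tr repetition time in seconds.
#' @param low_band numerator band in Hz, closed interval (default
#'   `c(0.01, 0.08)`).
#' @param full_band_max upper edge of the denominator band in Hz
#'   (default 0.25, the Nyquist frequency at TR = 2 s).
#' @return fALFF scalar in `[0, 1]`; an all-zero series returns 0 with a
#'   warning.
#' @examples
#' tt <- seq(0, by = 2, length.out = 200)
#' compute_falff(sin(2 * pi * 0.05 * tt), tr = 2)
#' @export
compute_falff <- function(series, tr, low_band = c(0.01, 0.08),
                          full_band_max = 0.25) {
  nt <- length(series)
  if (nt < 32L) stop("series must have at least 32 timepoints")
  if (tr <= 0) stop("tr must be positive")
  amp <- Mod(stats::fft(series))
  k <- 0:(floor(nt / 2))
  freq <- k / (nt * tr)
  amp <- amp[k + 1L]
  cap <- min(full_band_max, 1 / (2 * tr))
  den_bins <- freq > 0 & freq <= cap
  num_bins <- den_bins & freq >= low_band[1] & freq <= low_band[2]
  den <- sum(amp[den_bins])
  if (den == 0) {
    warning("spectrum is identically zero; fALFF defined as 0")
    return(0)
  }
  sum(amp[num_bins]) / den
}

#' Voxelwise fALFF map
#'
#' Applies [compute_falff()] to every in-mask voxel of a 4D volume;
#' out-of-mask voxels are set to `NA`.
#'
#' @param volume 4D array (x, y, z, time).
#' @param tr repetition time in seconds.
#' @param mask 3D logical array on the volume's grid; must select at least
#'   one voxel.
#' @param low_band,full_band_max passed to [compute_falff()].
#' @return 3D array of fALFF values with `NA` outside the mask.
#' @export
falff_map <- function(volume, tr, mask, low_band = c(0.01, 0.08),
                      full_band_max = 0.25) {
  dm <- dim(volume)
  if (length(dm) != 4L) stop("volume must be 4D")
  if (!identical(dim(mask), dm[1:3])) stop("mask grid does not match volume")
  idx <- which(as.vector(mask))
  if (length(idx) == 0L) stop("mask selects no voxels")
  series <- matrix(volume, prod(dm[1:3]), dm[4])
  out <- array(NA_real_, dim = dm[1:3])
  out[idx] <- apply(series[idx, , drop = FALSE], 1, compute_falff,
                    tr = tr, low_band = low_band,
                    full_band_max = full_band_max)
  out
}
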