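#' Drop initial volumes from a 4D series
#'
#' Removes the first `n_drop` time points (magnetization-stabilisation
#' volumes); the default leaves 230 analysed volumes from a 240-volume run.
#'
#' @param bold a `volume4d`.
#' @param n_drop number of leading volumes to remove; must be smaller than
#'   the volume count.
#' @return A `volume4d` with the remaining volumes; affine and TR unchanged.
#' @export
drop_initial_volumes <- function(bold, n_drop = 10L) {
  stopifnot(inherits(bold, "volume4d"))
  n_drop <- as.integer(n_drop)
  if (n_drop < 0) stop("`n_drop` must be non-negative")
  nt <- n_volumes(bold)
  if (n_drop >= nt) {
    stop(sprintf("cannot drop %d volumes from a %d-volume series", n_drop, nt))
  }
  if (n_drop == 0L) return(bold)
  volume4d(bold$data[, , , (n_drop + 1):nt, drop = FALSE],
           affine = bold$affine, tr_s = bold$tr_s)
}

# Time x voxel matrix view of a 4D array (columns are voxels of `mask`,
# in which(mask) order).
ts_matrix <- function(data4d, mask = NULL) {
  d <- dim(data4d)
  m <- matrix(data4d, prod(d[1:3]), d[4])
  if (is.null(mask)) t(m) else t(m[which(mask), , drop = FALSE])
}

#' Remove the per-voxel linear trend
#'
#' Least-squares line removed from each time series with the temporal mean
#' re-added, so the signal scale (and the spectral DC reference) is
#' preserved. Accepts a `volume4d`, a time-by-voxel matrix, or a vector.
#'
#' @param x input series (`volume4d`, T x V matrix, or length-T vector).
#' @return Object of the same shape, detrended.
#' @export
detrend_linear <- function(x) {
  if (inherits(x, "volume4d")) {
    d <- dim(x$data)
    nt <- d[4]
    if (nt < 3L) stop("need at least 3 time points to remove a linear trend")
    m <- matrix(x$data, prod(d[1:3]), nt)   # voxels x time, no transposes
    tc <- seq_len(nt) - (nt + 1) / 2
    beta <- as.numeric(m %*% tc) / sum(tc^2)
    out <- x
    out$data <- array(m - tcrossprod(beta, tc), d)
    return(out)
  }
  vec <- is.null(dim(x))
  y <- if (vec) matrix(x, ncol = 1) else x
  nt <- nrow(y)
  if (nt < 3L) stop("need at least 3 time points to remove a linear trend")
  tc <- seq_len(nt) - (nt + 1) / 2
  beta <- crossprod(tc, y) / sum(tc^2)
  y <- y - outer(tc, as.numeric(beta))
  if (vec) as.numeric(y) else y
}

#' Expand 6 rigid-body parameters to the Friston-24 motion model
#'
#' Columns are, per parameter: value, one-volume lag, squared value, squared
#' lag. Lagged rows at t = 1 are filled with 0.
#'
#' @param motion6 matrix/data.frame with >= 2 rows and exactly 6 columns.
#' @return numeric matrix with 24 named columns.
#' @export
build_friston24 <- function(motion6) {
  m <- as.matrix(motion6)
  if (ncol(m) != 6L) stop("`motion6` must have exactly 6 columns")
  if (nrow(m) < 2L) stop("`motion6` must have at least 2 rows")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  base <- if (!is.null(colnames(motion6))) colnames(motion6) else paste0("m", 1:6)
  colnames(out) <- c(base, paste0(base, "_lag"),
                     paste0(base, "_sq"), paste0(base, "_lag_sq"))
  out
}

#' Framewise displacement of a motion trace
#'
#' Sum of absolute backward differences of the six rigid-body parameters,
#' rotations converted to arc length on a 50 mm sphere (Power-style). The
#' first volume has FD 0 by convention.
#'
#' @param motion6 matrix with 6 columns: 3 translations (mm), 3 rotations.
#' @param rot_unit `"degrees"` (default, the simulator's convention) or
#'   `"radians"` (SPM's).
#' @param radius_mm sphere radius used for the rotation conversion.
#' @return numeric vector of per-volume FD values (mm).
#' @export
framewise_displacement <- function(motion6, rot_unit = c("degrees", "radians"),
                                   radius_mm = 50) {
  rot_unit <- match.arg(rot_unit)
  m <- as.matrix(motion6)
  if (ncol(m) != 6L) stop("`motion6` must have exactly 6 columns")
  rot_scale <- if (rot_unit == "degrees") pi / 180 * radius_mm else radius_mm
  m[, 4:6] <- m[, 4:6] * rot_scale
  dd <- abs(diff(m))
  c(0, rowSums(dd))
}

#' Flag motion-spike volumes by framewise displacement
#'
#' @param motion6 6-column motion table.
#' @param fd_threshold_mm positive FD cut-off in mm; volumes with
#'   FD strictly above it are flagged. The default 0.5 mm is a common
#'   scrubbing cut-off and is exposed as configuration.
#' @param ... passed to [framewise_displacement()].
#' @return list with `indices` (flagged volume indices), `fd` (per-volume FD),
#'   `threshold`.
#' @export
detect_spikes <- function(motion6, fd_threshold_mm = 0.5, ...) {
  if (!(fd_threshold_mm > 0)) stop("`fd_threshold_mm` must be positive")
  fd <- framewise_displacement(motion6, ...)
  list(indices = which(fd > fd_threshold_mm), fd = fd,
       threshold = fd_threshold_mm)
}

#' Assemble a nuisance design (Friston-24 + CSF + spike regressors)
#'
#' Spike volumes are encoded as one-hot columns, so censored volumes are
#' absorbed by the regression rather than deleted.
#'
#' @param motion6 6-column motion table (rows = analysed volumes).
#' @param csf_series optional per-volume mean CSF signal.
#' @param spike_indices integer volume indices to encode as one-hot columns.
#' @return Object of class `nuisance_design`: `columns` (matrix),
#'   `column_names`, `n_spikes`.
#' @export
build_nuisance_design <- function(motion6, csf_series = NULL,
                                  spike_indices = integer(0)) {
  fr24 <- build_friston24(motion6)
  nt <- nrow(fr24)
  cols <- fr24
  if (!is.null(csf_series)) {
    if (length(csf_series) != nt) stop("`csf_series` length must match rows")
    cols <- cbind(cols, csf = csf_series)
  }
  spike_indices <- as.integer(spike_indices)
  if (length(spike_indices)) {
    if (any(spike_indices < 1 | spike_indices > nt)) {
      stop("spike indices out of range")
    }
    sp <- matrix(0, nt, length(spike_indices))
    sp[cbind(spike_indices, seq_along(spike_indices))] <- 1
    colnames(sp) <- sprintf("spike_%03d", spike_indices)
    cols <- cbind(cols, sp)
  }
  structure(list(columns = cols, column_names = colnames(cols),
                 n_spikes = length(spike_indices)),
            class = "nuisance_design")
}

#' Regress nuisance signals out of a 4D series
#'
#' Per masked voxel, the residual of an ordinary least-squares fit on
#' `[intercept | design]` with the temporal mean restored; voxels outside the
#' mask are untouched.
#'
#' @param bold a `volume4d`.
#' @param design a `nuisance_design` (or plain regressor matrix).
#' @param mask logical 3D array of voxels to clean; default all voxels.
#' @return A cleaned `volume4d`.
#' @export
nuisance_regress <- function(bold, design, mask = NULL) {
  stopifnot(inherits(bold, "volume4d"))
  cols <- if (inherits(design, "nuisance_design")) design$columns else as.matrix(design)
  nt <- n_volumes(bold)
  if (nrow(cols) != nt) stop("design rows must equal the volume count")
  X <- cbind(intercept = 1, cols)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("nuisance design is rank deficient after adding an intercept; ",
         "remove collinear columns")
  }
  d <- dim(bold$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  Y <- ts_matrix(bold$data, mask)
  res <- qr.resid(qx, Y)
  res <- sweep(res, 2, colMeans(Y), "+")
  out <- bold
  m <- matrix(out$data, prod(d[1:3]), d[4])
  m[which(mask), ] <- t(res)
  out$data <- array(m, d)
  out
}

#' Mean signal within a region of interest
#'
#' @param bold a `volume4d`.
#' @param roi_mask non-empty logical 3D array.
#' @return per-volume numeric vector of spatial means.
#' @export
mean_roi_signal <- function(bold, roi_mask) {
  stopifnot(inherits(bold, "volume4d"))
  if (!any(roi_mask)) stop("ROI mask is empty")
  rowMeans(ts_matrix(bold$data, roi_mask))
}

# --- masked Gaussian smoothing ---------------------------------------------

# Normalized truncated Gaussian kernel (odd length, radius 4 sigma).
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  L <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(-L:L)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Separable convolution along the first three axes of a 3D or 4D array;
# the time axis (if any) is carried through.
sep_smooth3d <- function(a, kernels) {
  d <- dim(a)
  for (ax in 1:3) {
    if (length(kernels[[ax]]) > 1L) {
      a <- array(conv_axis_cpp(a, d, kernels[[ax]], ax - 1L), d)
    }
  }
  a
}

#' Gaussian smoothing restricted to a mask
#'
#' Applies `smooth(data * mask) / smooth(mask)` inside the mask and zero
#' outside, so no signal leaks across the mask boundary and constants are
#' preserved. The FWHM is converted to per-axis voxel sigmas via the affine's
#' voxel sizes. `fwhm_mm = 0` is the identity (masked).
#'
#' @param vol 3D array, or `volume4d` (smoothed volume by volume).
#' @param mask non-empty logical 3D array.
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @param affine grid-to-world transform supplying voxel sizes; defaults to
#'   the `volume4d`'s own affine, or 3 mm isotropic for bare arrays.
#' @return Smoothed object of the same class as `vol`.
#' @export
smooth_within_mask <- function(vol, mask, fwhm_mm, affine = NULL) {
  if (fwhm_mm < 0) stop("`fwhm_mm` must be non-negative")
  if (!any(mask)) stop("mask is empty")
  is_vol <- inherits(vol, "volume4d")
  if (is_vol) {
    affine <- affine %||% vol$affine
    a <- vol$data
  } else {
    a <- vol
  }
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  d <- dim(a)
  nt <- if (length(d) == 4L) d[4] else 1L
  a <- a * as.vector(mask)            # mask recycles over the time axis
  if (fwhm_mm > 0) {
    vsz <- voxel_sizes(affine)
    sig <- fwhm_mm / (sqrt(8 * log(2)) * vsz)
    kernels <- lapply(sig, gaussian_kernel_1d)
    num <- sep_smooth3d(a, kernels)
    den <- as.vector(sep_smooth3d(mask + 0, kernels))
    scale <- numeric(length(mask))
    inside <- which(mask)
    scale[inside] <- 1 / den[inside]
    a <- num * scale                  # zero outside, renormalised inside
  }
  if (is_vol) {
    out <- vol
    out$data <- a
    out
  } else {
    a
  }
}
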