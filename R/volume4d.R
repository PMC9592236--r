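#' 4D BOLD volume container
#'
#' Bundles a time-resolved 3D grid of signal values with its grid-to-world
#' affine (mm) and repetition time. Voxel indices are mapped to world
#' coordinates using a 0-based voxel convention:
#' `world = affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param data numeric 4D array (x, y, z, time) of finite values.
#' @param affine invertible 4x4 grid-to-world transform in mm.
#' @param tr_s repetition time in seconds, must be positive.
#'
#' @return An object of class `volume4d` with elements `data`, `affine`,
#'   `tr_s`.
#' @export
volume4d <- function(data, affine = diag(4), tr_s = 2) {
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (x, y, z, time)")
  }
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("`affine` must be an invertible 4x4 matrix")
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    stop("`tr_s` must be a positive scalar")
  }
  structure(list(data = data, affine = affine, tr_s = tr_s),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Number of time points in a 4D volume
#' @param bold a `volume4d`.
#' @return integer volume count.
#' @export
n_volumes <- function(bold) {
  stopifnot(inherits(bold, "volume4d"))
  dim(bold$data)[4]
}

# Per-axis voxel edge lengths (mm) implied by an affine.
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Voxel (1-based) to world mm coordinates.
voxel_to_world <- function(affine, ijk) {
  as.numeric(affine %*% c(ijk - 1, 1))[1:3]
}
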