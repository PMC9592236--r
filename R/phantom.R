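#' Generate a concentric-shell tissue phantom
#'
#' Builds the anatomical scaffold on which synthetic BOLD data are simulated:
#' GM/WM/CSF probability maps, a subcortical exclusion block, and a label
#' volume that tiles the white matter into named tract-like regions. The
#' geometry is deliberately concentric (CSF core, WM interior, GM shell, CSF
#' rim) rather than brain-shaped, so compartment membership is exactly known
#' and the downstream pipeline, which is geometry-agnostic, can be validated
#' against ground truth. Voxels outside the head are carried on the CSF
#' channel so the three probabilities sum to one everywhere.
#'
#' @param grid_shape integer vector of voxel counts per axis (recycled to
#'   length 3); every dimension must be at least 16 so all compartments fit.
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param seed integer seed; output is deterministic given the seed.
#'
#' @return An object of class `phantom_anatomy` with fields `grid_shape`,
#'   `voxel_size_mm`, `affine`, `prob_gm`, `prob_wm`, `prob_csf`,
#'   `subcortical_mask` (logical array), `atlas_labels` (integer array,
#'   0 = off atlas), `atlas_names` (data.frame with `label`, `name`), and
#'   `seed`.
#' @export
#' @examples
#' anat <- make_phantom_anatomy(c(24, 24, 24), voxel_size_mm = 3, seed = 1)
#' range(anat$prob_gm + anat$prob_wm + anat$prob_csf)  # 1 everywhere
make_phantom_anatomy <- function(grid_shape = c(32L, 32L, 32L),
                                 voxel_size_mm = 3,
                                 seed = 1L) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3L))
  if (any(grid_shape < 16L)) {
    stop("each grid dimension must be >= 16 to host all phantom compartments")
  }
  if (voxel_size_mm <= 0) stop("`voxel_size_mm` must be positive")
  set.seed(as.integer(seed))

  d <- grid_shape
  cx <- (d + 1) / 2
  tmp <- array(0, d)
  ii <- slice.index(tmp, 1); jj <- slice.index(tmp, 2); kk <- slice.index(tmp, 3)
  r <- sqrt((ii - cx[1])^2 + (jj - cx[2])^2 + (kk - cx[3])^2)
  r_head <- 0.92 * (min(d) / 2 - 1)   # head radius, voxel units
  u <- r / r_head

  # Gaussian-falloff occupancy score for a radial interval; sigma in
  # normalized-radius units keeps edges a fraction of a voxel wide.
  shell <- function(lo, hi, sigma = 0.05) {
    dd <- pmax(pmax(lo - u, 0), pmax(u - hi, 0))
    s <- exp(-dd^2 / (2 * sigma^2))
    s[s < 1e-6] <- 0
    s
  }
  s_csf <- pmax(shell(0, 0.25), shell(0.88, 1.05))
  s_csf[u > 1.05] <- 1                 # exterior rides the CSF channel
  s_wm <- shell(0.25, 0.70)
  s_gm <- shell(0.70, 0.88)

  # Mild seeded lognormal texture so segmentations are not piecewise constant.
  texture <- function(s) s * array(exp(rnorm(prod(d), 0, 0.05)), d)
  s_gm <- texture(s_gm); s_wm <- texture(s_wm); s_csf <- texture(s_csf)

  tot <- s_gm + s_wm + s_csf
  tot[tot == 0] <- 1                   # cannot happen inside head; safety
  prob_gm <- s_gm / tot; prob_wm <- s_wm / tot; prob_csf <- s_csf / tot

  labels <- assign_tissue_maxprob(prob_gm, prob_wm, prob_csf)

  # Subcortical stand-in: a small block in the +x WM interior.
  side <- max(2L, round(min(d) / 8))
  ctr <- round(cx + c(0.45 * r_head, 0, 0))
  half <- side %/% 2
  sub <- array(FALSE, d)
  xr <- pmax(1, ctr[1] - half):pmin(d[1], ctr[1] + half - 1 + side %% 2)
  yr <- pmax(1, ctr[2] - half):pmin(d[2], ctr[2] + half - 1 + side %% 2)
  zr <- pmax(1, ctr[3] - half):pmin(d[3], ctr[3] + half - 1 + side %% 2)
  sub[xr, yr, zr] <- TRUE
  sub <- sub & (prob_wm + prob_gm > 0)

  # Atlas: octant tiling of the WM compartment, named after major tracts.
  oct <- 1L + (ii > cx[1]) + 2L * (jj > cx[2]) + 4L * (kk > cx[3])
  atlas <- array(0L, d)
  wm_vox <- labels == TISSUE_WM
  atlas[wm_vox] <- oct[wm_vox]
  atlas_names <- data.frame(
    label = 1:8,
    name = c("Cingulum_R", "Cingulum_L",
             "Superior_longitudinal_fasciculus_R",
             "Superior_corona_radiata_L",
             "Cerebral_peduncle_R", "Middle_cerebellar_peduncle",
             "Genu_of_corpus_callosum", "Splenium_of_corpus_callosum"),
    stringsAsFactors = FALSE
  )

  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -voxel_size_mm * (cx - 1)

  structure(list(grid_shape = d,
                 voxel_size_mm = voxel_size_mm,
                 affine = affine,
                 prob_gm = prob_gm, prob_wm = prob_wm, prob_csf = prob_csf,
                 subcortical_mask = sub,
                 atlas_labels = atlas,
                 atlas_names = atlas_names,
                 r_head = r_head,
                 seed = as.integer(seed)),
            class = "phantom_anatomy")
}

#' @export
print.phantom_anatomy <- function(x, ...) {
  cat(sprintf("<phantom_anatomy> %s grid, %g mm voxels, %d WM / %d GM / %d CSF voxels\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              sum(x$atlas_labels > 0),
              sum(assign_tissue_maxprob(x$prob_gm, x$prob_wm, x$prob_csf) == TISSUE_GM),
              sum(assign_tissue_maxprob(x$prob_gm, x$prob_wm, x$prob_csf) == TISSUE_CSF)))
  invisible(x)
}
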