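#' Assign tissue labels by maximum probability
#'
#' Each voxel is labelled by the largest of its GM/WM/CSF probabilities.
#' Ties are broken by the fixed priority WM > GM > CSF (favouring the tissue
#' under study); voxels where all three probabilities are zero are labelled
#' background (0).
#'
#' @param prob_gm,prob_wm,prob_csf probability arrays in `[0, 1]`, identical
#'   shapes.
#' @return Integer array of labels: 0 background, 1 GM, 2 WM, 3 CSF.
#' @export
assign_tissue_maxprob <- function(prob_gm, prob_wm, prob_csf) {
  if (!identical(dim(prob_gm), dim(prob_wm)) ||
      !identical(dim(prob_gm), dim(prob_csf))) {
    stop("probability volumes must have identical shapes")
  }
  for (p in list(prob_gm, prob_wm, prob_csf)) {
    if (min(p) < -1e-9 || max(p) > 1 + 1e-9) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  lab <- array(TISSUE_BACKGROUND, dim(prob_gm))
  nz <- prob_gm > 0 | prob_wm > 0 | prob_csf > 0
  is_wm <- prob_wm >= prob_gm & prob_wm >= prob_csf
  is_gm <- !is_wm & prob_gm >= prob_csf
  lab[nz & is_wm] <- TISSUE_WM
  lab[nz & is_gm] <- TISSUE_GM
  lab[nz & !is_wm & !is_gm] <- TISSUE_CSF
  lab
}

#' Group-level white-matter mask from individual masks
#'
#' A voxel enters the group mask when it is labelled WM in strictly more than
#' `threshold` of the subjects (the ">60%" convention is a strict
#' inequality). The per-voxel overlap fraction is retained for audit.
#'
#' @param individual_wm_masks list (>= 2) of logical arrays with identical
#'   shapes.
#' @param threshold overlap fraction in `[0, 1)`; default 0.6.
#' @return Object of class `group_mask`: `mask` (logical array),
#'   `overlap_fraction`, `threshold`, `n_subjects`.
#' @export
group_wm_mask <- function(individual_wm_masks, threshold = 0.6) {
  if (!is.list(individual_wm_masks) || length(individual_wm_masks) < 2L) {
    stop("need at least 2 individual masks")
  }
  d <- dim(individual_wm_masks[[1]])
  for (m in individual_wm_masks) {
    if (!identical(dim(m), d)) stop("individual masks must share one shape")
  }
  if (!(threshold >= 0 && threshold < 1)) stop("`threshold` must be in [0, 1)")
  n <- length(individual_wm_masks)
  overlap <- Reduce(`+`, lapply(individual_wm_masks, function(m) m + 0)) / n
  structure(list(mask = overlap > threshold,
                 overlap_fraction = overlap,
                 threshold = threshold,
                 n_subjects = n),
            class = "group_mask")
}

#' Remove subcortical voxels from a group mask
#'
#' @param mask a `group_mask`.
#' @param subcortical_mask logical array, same shape.
#' @return The `group_mask` with `mask AND NOT subcortical`; warns when the
#'   result is empty.
#' @export
remove_subcortical <- function(mask, subcortical_mask) {
  stopifnot(inherits(mask, "group_mask"))
  if (!identical(dim(mask$mask), dim(subcortical_mask))) {
    stop("subcortical mask shape does not match the group mask")
  }
  out <- mask
  out$mask <- mask$mask & !subcortical_mask
  out$subcortical_removed <- TRUE
  if (!any(out$mask)) {
    warning("group WM mask is empty after subcortical removal")
  }
  out
}

#' @export
print.group_mask <- function(x, ...) {
  cat(sprintf("<group_mask> %d voxels (> %g overlap of %d subjects%s)\n",
              sum(x$mask), x$threshold, x$n_subjects,
              if (isTRUE(x$subcortical_removed)) ", subcortical removed" else ""))
  invisible(x)
}
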