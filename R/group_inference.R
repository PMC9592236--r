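# Coerce a list of metric_map / arrays to a voxel x subject matrix over mask.
map_matrix <- function(maps, mask) {
  vals <- lapply(maps, function(m) {
    a <- if (inherits(m, "metric_map")) m$values else m
    a[which(mask)]
  })
  do.call(cbind, vals)
}

#' Voxel-wise two-sample t-test
#'
#' Pooled-variance two-sample t per voxel with sign convention
#' `group A - group B` (patients minus controls, so amplitude deficits give
#' negative t). Voxels with zero pooled variance get t = 0 and are counted in
#' the `n_zero_variance` field.
#'
#' @param maps_a,maps_b lists (>= 2 each) of `metric_map`s or 3D arrays.
#' @param mask logical 3D array; the analysis (search) region.
#' @return Object of class `stat_map`: `t` (3D array, 0 outside mask), `df`,
#'   `n_a`, `n_b`, `mask`, `n_zero_variance`.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, mask) {
  if (length(maps_a) < 2L || length(maps_b) < 2L) {
    stop("need at least 2 maps per group")
  }
  A <- map_matrix(maps_a, mask)
  B <- map_matrix(maps_b, mask)
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tv <- ifelse(se > 0, (ma - mb) / se, 0)
  n_zero <- sum(se == 0)
  tmap <- array(0, dim(mask))
  tmap[which(mask)] <- tv
  structure(list(t = tmap, df = na + nb - 2L, n_a = na, n_b = nb,
                 mask = mask, n_zero_variance = n_zero),
            class = "stat_map")
}

#' Group-mean residual maps
#'
#' Each subject's map minus its group mean map: the residual fields whose
#' spatial autocorrelation drives the random-field correction.
#'
#' @inheritParams voxelwise_ttest
#' @return list of 3D arrays (length `n_a + n_b`).
#' @export
group_residuals <- function(maps_a, maps_b, mask) {
  A <- map_matrix(maps_a, mask)
  B <- map_matrix(maps_b, mask)
  ra <- A - rowMeans(A)
  rb <- B - rowMeans(B)
  res <- cbind(ra, rb)
  lapply(seq_len(ncol(res)), function(j) {
    a <- array(0, dim(mask)); a[which(mask)] <- res[, j]; a
  })
}

#' Estimate spatial smoothness from residual maps
#'
#' Residuals are standardised per voxel (unit variance across maps); the
#' variance `v_i` of their first differences along each axis, restricted to
#' in-mask neighbour pairs, gives the lag-1 field correlation
#' `rho_i = 1 - v_i/2`. Inverting the Gaussian autocorrelation model of a
#' white-noise field convolved with a Gaussian kernel yields
#' `FWHM_i = sqrt(-2*log(2) / log(rho_i))` in voxel units. Sub-voxel
#' smoothness is not identifiable from lattice differences, so estimates are
#' floored at one voxel. The resel count is the mask volume in voxel units
#' divided by the product of the per-axis FWHMs in voxel units.
#'
#' @param residual_maps list (>= 3) of 3D arrays, e.g. from
#'   [group_residuals()].
#' @param mask logical 3D array.
#' @param voxel_size_mm per-axis voxel sizes (recycled to length 3).
#' @return Object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`
#'   (per-axis), `resel_count`, `search_voxels`.
#' @export
estimate_smoothness <- function(residual_maps, mask, voxel_size_mm = 3) {
  if (length(residual_maps) < 3L) stop("need at least 3 residual maps")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  idx <- which(mask)
  R <- do.call(cbind, lapply(residual_maps, function(a) a[idx]))
  sdv <- sqrt(rowMeans(R^2))          # residuals are mean-zero across maps
  ok <- sdv > 0
  R <- R / ifelse(sdv > 0, sdv, 1)

  d <- dim(mask)
  std_arrays <- lapply(seq_len(ncol(R)), function(j) {
    a <- array(NA_real_, d)
    a[idx[ok]] <- R[ok, j]
    a
  })
  v <- numeric(3)
  for (ax in 1:3) {
    sel_lo <- lapply(d, seq_len); sel_hi <- sel_lo
    sel_lo[[ax]] <- 1:(d[ax] - 1); sel_hi[[ax]] <- 2:d[ax]
    diffs <- unlist(lapply(std_arrays, function(a) {
      dd <- do.call(`[`, c(list(a), sel_hi)) - do.call(`[`, c(list(a), sel_lo))
      dd[!is.na(dd)]
    }))
    if (!length(diffs)) stop("mask has no neighbour pairs along axis ", ax)
    v[ax] <- mean(diffs^2)
  }
  rho <- 1 - v / 2
  if (any(rho >= 1 - 1e-8)) {
    stop("degenerate residual variance: fields are (near) perfectly correlated")
  }
  fwhm_vox <- ifelse(rho <= 0.25, 1, sqrt(-2 * log(2) / log(pmax(rho, 1e-12))))
  fwhm_vox <- pmax(fwhm_vox, 1)
  structure(list(fwhm_mm = fwhm_vox * voxel_size_mm,
                 fwhm_vox = fwhm_vox,
                 resel_count = length(idx) / prod(fwhm_vox),
                 search_voxels = length(idx)),
            class = "smoothness_estimate")
}

# --- connected components ---------------------------------------------------

neighbour_offsets <- function(connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  g[ord <= lim, , drop = FALSE]
}

#' Label connected supra-threshold components
#'
#' @param binary logical 3D array.
#' @param connectivity neighbourhood: 6 (faces), 18 (faces + edges, default),
#'   or 26 (faces + edges + corners).
#' @return list with `labels` (integer array, 0 = background), `sizes`
#'   (voxel counts per component, component i has label i).
#' @export
extract_clusters <- function(binary, connectivity = 18L) {
  d <- dim(binary)
  labels <- array(0L, d)
  idx <- which(binary)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0)))
  offs <- neighbour_offsets(connectivity)
  coords <- arrayInd(idx, d)
  n_sup <- length(idx)
  queue <- matrix(0L, n_sup, 3)
  cl <- 0L
  sizes <- integer(0)
  for (s in seq_len(n_sup)) {
    if (labels[idx[s]] != 0L) next
    cl <- cl + 1L
    labels[idx[s]] <- cl
    queue[1, ] <- coords[s, ]
    head_i <- 1L; tail_i <- 1L
    size <- 1L
    while (head_i <= tail_i) {
      p <- queue[head_i, ]; head_i <- head_i + 1L
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (q[1] < 1L || q[1] > d[1] || q[2] < 1L || q[2] > d[2] ||
            q[3] < 1L || q[3] > d[3]) next
        if (binary[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- cl
          tail_i <- tail_i + 1L
          queue[tail_i, ] <- q
          size <- size + 1L
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

# --- Gaussian random field cluster-level correction -------------------------

# Expected number of clusters above threshold u in a 3D Gaussian field.
grf_expected_clusters <- function(u, resels) {
  resels * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
}

# Corrected p for a cluster of extent k voxels (3D field).
grf_cluster_pvalue <- function(k, u, resels, search_voxels) {
  Em <- max(grf_expected_clusters(u, resels), .Machine$double.eps)
  En <- search_voxels * pnorm(u, lower.tail = FALSE)
  if (!(En > 0)) stop("expected supra-threshold volume is zero")
  beta <- (gamma(5 / 2) * Em / En)^(2 / 3)
  p_ext <- exp(-beta * k^(2 / 3))
  1 - exp(-Em * p_ext)
}

# t values to z values preserving tail probability, stable for large |t|.
t_to_z <- function(tv, df) {
  sign(tv) * qnorm(pt(abs(tv), df, lower.tail = FALSE), lower.tail = FALSE)
}

#' GRF cluster-level correction of a t map
#'
#' Converts the t map to z, thresholds each sign at the one-tailed z
#' quantile for `voxel_p / 2` (two-sided default; `tails = "one"` uses
#' `voxel_p` per sign), extracts connected supra-threshold clusters, and
#' assigns each a corrected p-value from 3D Gaussian-field theory: the
#' expected cluster count at threshold u (Euler-characteristic density times
#' resel count), the expected supra-threshold volume, and the
#' `exp(-beta * k^(2/3))` cluster-extent tail. Clusters with corrected
#' p below `cluster_p` are kept, per sign.
#'
#' @param stat a `stat_map`.
#' @param smooth a `smoothness_estimate`.
#' @param voxel_p voxel-level (cluster-forming) p threshold in (0, 1).
#' @param cluster_p cluster-level corrected alpha in (0, 1).
#' @param tails `"two"` (threshold each sign at `voxel_p/2`) or `"one"`.
#' @param connectivity cluster connectivity (default 18).
#' @param atlas_labels,atlas_names,affine forwarded to [report_clusters()].
#' @return A cluster table (see [report_clusters()]) with attributes
#'   `label_volume` (signed cluster ids), `threshold_z`, and
#'   `all_clusters` (every supra-threshold cluster with its corrected p).
#' @export
grf_cluster_correction <- function(stat, smooth, voxel_p = 0.05,
                                   cluster_p = 0.05, tails = c("two", "one"),
                                   connectivity = 18L,
                                   atlas_labels = NULL, atlas_names = NULL,
                                   affine = NULL) {
  tails <- match.arg(tails)
  stopifnot(inherits(stat, "stat_map"), inherits(smooth, "smoothness_estimate"))
  if (!(voxel_p > 0 && voxel_p < 1) || !(cluster_p > 0 && cluster_p < 1)) {
    stop("`voxel_p` and `cluster_p` must lie in (0, 1)")
  }
  if (!(smooth$resel_count > 0)) stop("resel count must be positive")
  u <- qnorm(1 - if (tails == "two") voxel_p / 2 else voxel_p)
  z <- array(0, dim(stat$t))
  z[stat$mask] <- t_to_z(stat$t[stat$mask], stat$df)

  all_rows <- list()
  label_volume <- array(0L, dim(stat$t))
  next_id <- 0L
  for (sgn in c(1, -1)) {
    supra <- (sgn * z > u) & stat$mask
    cls <- extract_clusters(supra, connectivity)
    if (!length(cls$sizes)) next
    for (ci in seq_along(cls$sizes)) {
      k <- cls$sizes[ci]
      p_corr <- grf_cluster_pvalue(k, u, smooth$resel_count,
                                   smooth$search_voxels)
      next_id <- next_id + 1L
      vox <- which(cls$labels == ci)
      all_rows[[next_id]] <- list(id = next_id, sign = sgn, extent = k,
                                  p = p_corr, vox = vox)
    }
  }
  keep <- Filter(function(r) r$p < cluster_p, all_rows)
  for (i in seq_along(keep)) {
    keep[[i]]$id <- i
    label_volume[keep[[i]]$vox] <- i
  }
  tab <- report_clusters(keep, stat, atlas_labels = atlas_labels,
                         atlas_names = atlas_names, affine = affine)
  attr(tab, "label_volume") <- label_volume
  attr(tab, "threshold_z") <- u
  attr(tab, "all_clusters") <- data.frame(
    extent = vapply(all_rows, `[[`, 1, "extent"),
    sign = vapply(all_rows, `[[`, 1, "sign"),
    corrected_p = vapply(all_rows, `[[`, 1, "p")
  )
  tab
}

#' Cluster table with peaks, world coordinates, and atlas labels
#'
#' The peak is the voxel attaining the extremum of the cluster's sign; its
#' world coordinates come from the affine; the atlas label is the atlas
#' value at the peak. Clusters whose peak carries no atlas label are
#' retained, labelled `"unlabeled"`, and flagged `off_atlas`.
#'
#' @param clusters list of cluster records (`id`, `sign`, `extent`, `p`,
#'   `vox` linear indices), e.g. assembled by [grf_cluster_correction()].
#' @param stat the `stat_map` the clusters were extracted from.
#' @param atlas_labels optional integer label array on the same grid.
#' @param atlas_names optional data.frame with `label`, `name`.
#' @param affine optional 4x4 grid-to-world transform.
#' @return data.frame with one row per cluster: `cluster_id`, `sign`,
#'   `extent_voxels`, `peak_i/j/k`, `peak_x/y/z_mm`, `peak_t`,
#'   `corrected_p`, `atlas_label`, `off_atlas`.
#' @export
report_clusters <- function(clusters, stat, atlas_labels = NULL,
                            atlas_names = NULL, affine = NULL) {
  d <- dim(stat$t)
  if (!is.null(atlas_labels) && !identical(dim(atlas_labels), d)) {
    stop("atlas grid does not match the statistic grid")
  }
  rows <- lapply(clusters, function(cl) {
    tv <- stat$t[cl$vox]
    pk <- cl$vox[which.max(cl$sign * tv)]
    ijk <- as.integer(arrayInd(pk, d))
    world <- if (!is.null(affine)) voxel_to_world(affine, ijk) else rep(NA_real_, 3)
    lab <- "unlabeled"; off <- TRUE
    if (!is.null(atlas_labels)) {
      code <- atlas_labels[pk]
      if (code > 0) {
        off <- FALSE
        lab <- as.character(code)
        if (!is.null(atlas_names)) {
          hit <- match(code, atlas_names$label)
          if (!is.na(hit)) lab <- atlas_names$name[hit]
        }
      }
    }
    data.frame(cluster_id = cl$id, sign = cl$sign,
               extent_voxels = cl$extent,
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
               peak_x_mm = world[1], peak_y_mm = world[2], peak_z_mm = world[3],
               peak_t = stat$t[pk], corrected_p = cl$p,
               atlas_label = lab, off_atlas = off,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = integer(0), sign = numeric(0),
                      extent_voxels = integer(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0),
                      peak_t = numeric(0), corrected_p = numeric(0),
                      atlas_label = character(0), off_atlas = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Permutation oracle for cluster-level inference
#'
#' Group labels are permuted; the null distribution of the maximum
#' supra-threshold cluster extent (over both signs) gives each observed
#' cluster a corrected p as the proportion of permutations with a maximum
#' extent at least as large, using the `(b + 1) / (m + 1)` convention for
#' sampled permutations. When fewer distinct group assignments exist than
#' `n_perm`, all assignments are enumerated (with a warning) and the exact
#' proportion is reported.
#'
#' @inheritParams voxelwise_ttest
#' @param voxel_p cluster-forming p (two-sided handling as in
#'   [grf_cluster_correction()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the sampled permutations.
#' @param connectivity cluster connectivity.
#' @param tails `"two"` or `"one"`.
#' @return data.frame of observed clusters (`sign`, `extent_voxels`,
#'   `peak_t`, `corrected_p`) with attribute `null_max_extent`.
#' @export
permutation_cluster_oracle <- function(maps_a, maps_b, mask, voxel_p = 0.05,
                                       n_perm = 1000L, seed = 1L,
                                       connectivity = 18L,
                                       tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n_perm < 100L) stop("`n_perm` must be at least 100")
  A <- map_matrix(maps_a, mask)
  B <- map_matrix(maps_b, mask)
  M <- cbind(A, B)
  na <- ncol(A); nb <- ncol(B); n <- na + nb
  df <- n - 2L
  u <- qnorm(1 - if (tails == "two") voxel_p / 2 else voxel_p)
  # threshold in t units equivalent to the z threshold
  t_u <- qt(pnorm(u, lower.tail = FALSE), df, lower.tail = FALSE)
  d <- dim(mask)
  idx <- which(mask)
  M2 <- M^2

  t_for <- function(sel_a) {
    ga <- numeric(n); ga[sel_a] <- 1
    sa <- as.numeric(M %*% ga); sb <- rowSums(M) - sa
    qa <- as.numeric(M2 %*% ga); qb <- rowSums(M2) - qa
    ma <- sa / na; mb <- sb / nb
    va <- (qa - sa^2 / na) / (na - 1)
    vb <- (qb - sb^2 / nb) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(pmax(sp2, 0) * (1 / na + 1 / nb))
    ifelse(se > 0, (ma - mb) / se, 0)
  }
  max_extent <- function(tv) {
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra <- array(FALSE, d)
      supra[idx] <- sgn * tv > t_u
      sz <- extract_clusters(supra, connectivity)$sizes
      if (length(sz)) mx <- max(mx, max(sz))
    }
    mx
  }

  t_obs <- t_for(seq_len(na))
  obs_rows <- list()
  tmap <- array(0, d); tmap[idx] <- t_obs
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, d)
    supra[idx] <- sgn * t_obs > t_u
    cls <- extract_clusters(supra, connectivity)
    for (ci in seq_along(cls$sizes)) {
      vox <- which(cls$labels == ci)
      pk <- vox[which.max(sgn * tmap[vox])]
      obs_rows[[length(obs_rows) + 1L]] <-
        data.frame(sign = sgn, extent_voxels = cls$sizes[ci],
                   peak_t = tmap[pk], corrected_p = NA_real_)
    }
  }

  n_distinct <- choose(n, na)
  exhaustive <- n_distinct <= n_perm
  if (exhaustive) {
    warning(sprintf("only %d distinct group assignments; enumerating all",
                    n_distinct))
    combs <- combn(n, na)
    null_max <- apply(combs, 2, function(s) max_extent(t_for(s)))
  } else {
    set.seed(as.integer(seed))
    null_max <- vapply(seq_len(n_perm), function(i) {
      max_extent(t_for(sample.int(n, na)))
    }, integer(1))
  }

  out <- if (length(obs_rows)) do.call(rbind, obs_rows) else
    data.frame(sign = numeric(0), extent_voxels = integer(0),
               peak_t = numeric(0), corrected_p = numeric(0))
  if (nrow(out)) {
    out$corrected_p <- vapply(out$extent_voxels, function(k) {
      if (exhaustive) mean(null_max >= k)
      else (1 + sum(null_max >= k)) / (length(null_max) + 1)
    }, numeric(1))
  }
  attr(out, "null_max_extent") <- null_max
  attr(out, "exhaustive") <- exhaustive
  out
}
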