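flat_mask <- function(n) array(TRUE, c(n, 1, 1))

make_maps <- function(M) {
  # columns of M become flat 3D maps
  lapply(seq_len(ncol(M)), function(j) array(M[, j], c(nrow(M), 1, 1)))
}

test_that("the voxel-wise t map matches the scalar two-sample oracle", {
  set.seed(21)
  V <- 40
  A <- matrix(rnorm(V * 6, 0.3), V, 6)
  B <- matrix(rnorm(V * 5), V, 5)
  stat <- voxelwise_ttest(make_maps(A), make_maps(B), flat_mask(V))
  expect_equal(stat$df, 9)
  for (v in c(1, 7, 40)) {
    oracle <- t.test(A[v, ], B[v, ], var.equal = TRUE)
    expect_equal(stat$t[v, 1, 1], unname(oracle$statistic), tolerance = 1e-12)
  }
  # antisymmetry under group swap
  swapped <- voxelwise_ttest(make_maps(B), make_maps(A), flat_mask(V))
  expect_equal(swapped$t, -stat$t, tolerance = 1e-12)
  # group sizes 48/41 give df = 87
  A2 <- matrix(rnorm(3 * 48), 3, 48); B2 <- matrix(rnorm(3 * 41), 3, 41)
  expect_equal(voxelwise_ttest(make_maps(A2), make_maps(B2), flat_mask(3))$df, 87)
  # zero-variance voxels get t = 0 and are counted
  A3 <- matrix(1, 4, 3); B3 <- matrix(1, 4, 3)
  s3 <- voxelwise_ttest(make_maps(A3), make_maps(B3), flat_mask(4))
  expect_true(all(s3$t == 0))
  expect_equal(s3$n_zero_variance, 4)
  expect_error(voxelwise_ttest(make_maps(A)[1], make_maps(B), flat_mask(V)),
               "at least 2")
})

test_that("smoothness estimates recover the applied kernel and floor at a voxel", {
  d <- c(20, 20, 20)
  interior <- array(FALSE, d); interior[3:18, 3:18, 3:18] <- TRUE
  aff <- diag(c(3, 3, 3, 1))
  set.seed(77)
  est_for <- function(fwhm, nsim = 50) {
    mean(replicate(nsim, {
      maps <- lapply(1:6, function(i) {
        a <- array(rnorm(prod(d)), d)
        if (fwhm > 0) a <- smooth_within_mask(a, array(TRUE, d), fwhm, aff)
        a
      })
      res <- group_residuals(maps[1:3], maps[4:6], interior)
      mean(estimate_smoothness(res, interior, 3)$fwhm_mm)
    }))
  }
  est4 <- est_for(4)
  expect_lt(abs(est4 - 4) / 4, 0.15)
  est0 <- est_for(0, nsim = 20)
  expect_lt(abs(est0 - 3) / 3, 0.15)       # white noise: about one voxel
  expect_error(estimate_smoothness(list(array(0, d)), interior), "at least 3")
})

test_that("resel count scales with the search volume at fixed smoothness", {
  d <- c(24, 16, 16)
  m1 <- array(FALSE, d); m1[2:12, 2:15, 2:15] <- TRUE
  m2 <- array(FALSE, d); m2[2:23, 2:15, 2:15] <- TRUE   # double the slab
  set.seed(31)
  maps <- lapply(1:8, function(i) {
    smooth_within_mask(array(rnorm(prod(d)), d), array(TRUE, d), 5,
                       diag(c(3, 3, 3, 1)))
  })
  res <- group_residuals(maps[1:4], maps[5:8], array(TRUE, d))
  r1 <- estimate_smoothness(res, m1, 3)
  r2 <- estimate_smoothness(res, m2, 3)
  ratio <- r2$resel_count / r1$resel_count
  expect_equal(r2$search_voxels / r1$search_voxels, 2)
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("connected components follow the 6/18/26 neighbourhood semantics", {
  d <- c(6, 6, 6)
  b <- array(FALSE, d)
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE       # corner contact
  expect_length(extract_clusters(b, 26)$sizes, 1)
  expect_length(extract_clusters(b, 18)$sizes, 2)
  expect_length(extract_clusters(b, 6)$sizes, 2)
  e <- array(FALSE, d)
  e[1, 1, 1] <- TRUE; e[2, 2, 1] <- TRUE       # edge contact
  expect_length(extract_clusters(e, 18)$sizes, 1)
  expect_length(extract_clusters(e, 6)$sizes, 2)
  # two blobs separated by more than one voxel on every axis
  f <- array(FALSE, d); f[1:2, 1:2, 1:2] <- TRUE; f[5:6, 5:6, 5:6] <- TRUE
  cl <- extract_clusters(f, 26)
  expect_equal(sort(cl$sizes), c(8L, 8L))
  s <- array(FALSE, d); s[3, 3, 3] <- TRUE
  expect_equal(extract_clusters(s)$sizes, 1L)
  expect_length(extract_clusters(array(FALSE, d))$sizes, 0)
})

test_that("GRF corrected p decreases with extent and an empty map yields no rows", {
  p_at <- function(k) wmalff:::grf_cluster_pvalue(k, u = 1.96, resels = 200,
                                                  search_voxels = 2000)
  ks <- c(1, 5, 10, 20, 50, 100)
  ps <- vapply(ks, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
  mask <- array(TRUE, c(8, 8, 8))
  stat <- structure(list(t = array(0, c(8, 8, 8)), df = 20L, n_a = 11L,
                         n_b = 11L, mask = mask, n_zero_variance = 0L),
                    class = "stat_map")
  sm <- structure(list(fwhm_mm = rep(6, 3), fwhm_vox = rep(2, 3),
                       resel_count = 64, search_voxels = 512),
                  class = "smoothness_estimate")
  tab <- grf_cluster_correction(stat, sm)
  expect_equal(nrow(tab), 0)
  expect_error(grf_cluster_correction(stat, sm, voxel_p = 0), "\\(0, 1\\)")
})

test_that("t-to-z conversion preserves tail probabilities", {
  tz <- wmalff:::t_to_z
  expect_equal(tz(0, 10), 0)
  for (tv in c(1.5, -2.5, 8)) {
    expect_equal(pnorm(tz(tv, 12)), pt(tv, 12), tolerance = 1e-10)
  }
  expect_true(is.finite(tz(50, 30)))
})

test_that("cluster reports carry peaks, world coordinates and atlas labels", {
  an <- small_anatomy()
  lab <- small_labels()
  wm <- lab == 2L
  d <- dim(wm)
  tmap <- array(0, d)
  wmv <- which(wm)
  blob <- arrayInd(wmv[100], d)
  tmap[blob[1], blob[2], blob[3]] <- -5
  stat <- structure(list(t = tmap, df = 30L, n_a = 16L, n_b = 16L,
                         mask = wm, n_zero_variance = 0L), class = "stat_map")
  clusters <- list(list(id = 1L, sign = -1, extent = 1L, p = 0.01,
                        vox = wmv[100]))
  tab <- report_clusters(clusters, stat, an$atlas_labels, an$atlas_names,
                         an$affine)
  expect_equal(tab$peak_t, -5)
  expect_false(tab$off_atlas)
  expect_true(tab$atlas_label %in% an$atlas_names$name)
  expect_equal(c(tab$peak_i, tab$peak_j, tab$peak_k), as.integer(blob))
  world <- an$affine %*% c(blob - 1, 1)
  expect_equal(c(tab$peak_x_mm, tab$peak_y_mm, tab$peak_z_mm),
               as.numeric(world[1:3]))
  # a peak outside the atlas is retained but flagged
  csfv <- which(lab == 3L)[1]
  stat$t[csfv] <- -4
  tab2 <- report_clusters(list(list(id = 1L, sign = -1, extent = 1L,
                                    p = 0.02, vox = csfv)),
                          stat, an$atlas_labels, an$atlas_names, an$affine)
  expect_true(tab2$off_atlas)
  expect_equal(tab2$atlas_label, "unlabeled")
  # reference-style row rendering: label, extent, coordinates, peak t
  row <- sprintf("%s %d %g %g %g %.4f", tab$atlas_label, tab$extent_voxels,
                 tab$peak_x_mm, tab$peak_y_mm, tab$peak_z_mm, tab$peak_t)
  expect_match(row, "^[A-Za-z_]+ \\d+ -?[0-9.]+ -?[0-9.]+ -?[0-9.]+ -?[0-9.]+$")
})

test_that("the permutation oracle bounds p by the sampling convention", {
  d <- c(10, 10, 4)
  mask <- array(TRUE, d)
  set.seed(61)
  mk <- function(shift) {
    a <- array(rnorm(prod(d)), d)
    a[4:6, 4:6, 2:3] <- a[4:6, 4:6, 2:3] + shift
    smooth_within_mask(a, mask, 4, diag(c(3, 3, 3, 1)))
  }
  maps_a <- lapply(1:8, function(i) mk(2.5))
  maps_b <- lapply(1:8, function(i) mk(0))
  out <- permutation_cluster_oracle(maps_a, maps_b, mask, n_perm = 100,
                                    seed = 5)
  big <- out[which.max(out$extent_voxels), ]
  expect_gt(big$extent_voxels, 5)
  expect_equal(big$corrected_p, 1 / 101)       # beats every sampled maximum
  expect_true(all(out$corrected_p >= 1 / 101 & out$corrected_p <= 1))
  expect_error(permutation_cluster_oracle(maps_a, maps_b, mask, n_perm = 50),
               "at least 100")
  # few subjects: all distinct assignments are enumerated with a warning
  expect_warning(
    small <- permutation_cluster_oracle(maps_a[1:3], maps_b[1:3], mask,
                                        n_perm = 100, seed = 1),
    "enumerating")
  expect_true(isTRUE(attr(small, "exhaustive")))
})

test_that("null fields rarely produce permutation-significant clusters", {
  d <- c(10, 10, 4)
  mask <- array(TRUE, d)
  set.seed(71)
  n_sig <- 0
  for (r in 1:5) {
    maps_a <- lapply(1:8, function(i)
      smooth_within_mask(array(rnorm(prod(d)), d), mask, 4, diag(c(3, 3, 3, 1))))
    maps_b <- lapply(1:8, function(i)
      smooth_within_mask(array(rnorm(prod(d)), d), mask, 4, diag(c(3, 3, 3, 1))))
    out <- permutation_cluster_oracle(maps_a, maps_b, mask, n_perm = 100,
                                      seed = r)
    if (nrow(out) && any(out$corrected_p <= 0.05)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 2)
})
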