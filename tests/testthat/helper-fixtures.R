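# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_anatomy <- function() {
  cached("anat20", function() make_phantom_anatomy(c(20, 20, 20), 3, seed = 1))
}

small_labels <- function() {
  an <- small_anatomy()
  cached("lab20", function() {
    assign_tissue_maxprob(an$prob_gm, an$prob_wm, an$prob_csf)
  })
}

# A smoothed (or raw) Gaussian noise map restricted to a mask.
noise_map <- function(mask, fwhm = 0, voxel_mm = 3) {
  a <- array(rnorm(length(mask)), dim(mask))
  if (fwhm > 0) {
    smooth_within_mask(a, mask, fwhm, affine = diag(c(rep(voxel_mm, 3), 1)))
  } else {
    a * mask
  }
}

# Tiny volume4d with given voxel time series in a flat grid.
toy_bold <- function(series_matrix, tr_s = 2) {
  nt <- nrow(series_matrix)
  v <- ncol(series_matrix)
  volume4d(array(t(series_matrix), c(v, 1, 1, nt)), diag(4), tr_s)
}

# Linearly separable two-class feature fixture (class means +/- mu).
separable_features <- function(n_patients = 48, n_controls = 41, p = 6,
                               mu = 0.6, sd = 0.1, seed = 11) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_patients * p, -mu, sd), n_patients),
             matrix(rnorm(n_controls * p, mu, sd), n_controls))
  feature_matrix(X, c(rep("patient", n_patients), rep("control", n_controls)))
}
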