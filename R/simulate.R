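#' Specify planted band-limited amplitude deficits
#'
#' An effect specification lists spherical seed regions inside the white
#' matter in which the oscillatory (band-limited) signal amplitude of the
#' patient group is multiplied by `amplitude_ratio`, emulating a group-wise
#' reduction of low-frequency fluctuation amplitude. The mean signal level
#' and the noise are untouched, so the induced ALFF/fALFF effect is
#' analytically predictable.
#'
#' @param cluster_seeds list of `list(center = c(i, j, k), radius = r)` in
#'   voxel units (1-based centers).
#' @param amplitude_ratio multiplicative factor in (0, 1]; the patient
#'   in-cluster oscillation amplitude relative to controls. 1 plants no
#'   effect.
#' @param band frequency interval in Hz within which the oscillatory
#'   frequencies are drawn.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(cluster_seeds, amplitude_ratio = 0.6,
                        band = c(0.01, 0.15)) {
  if (!is.list(cluster_seeds) || length(cluster_seeds) == 0) {
    stop("`cluster_seeds` must be a non-empty list of (center, radius) seeds")
  }
  if (!(amplitude_ratio > 0 && amplitude_ratio <= 1)) {
    stop("`amplitude_ratio` must lie in (0, 1]")
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("`band` must be increasing positive frequencies (Hz)")
  }
  structure(list(cluster_seeds = cluster_seeds,
                 amplitude_ratio = amplitude_ratio,
                 band = band),
            class = "effect_spec")
}

#' Default effect specification for a phantom
#'
#' Places `n_clusters` spheres in the WM interior at fixed directions from
#' the phantom center (away from the subcortical block), patterned on the
#' scale of reported cluster extents (~30-120 voxels).
#'
#' @param anatomy a `phantom_anatomy`.
#' @param amplitude_ratio see [effect_spec()].
#' @param n_clusters number of spheres (1-3).
#' @param radius sphere radius in voxels.
#' @param band frequency interval in Hz.
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(anatomy, amplitude_ratio = 0.6,
                                n_clusters = 3L, radius = 2,
                                band = c(0.01, 0.15)) {
  stopifnot(inherits(anatomy, "phantom_anatomy"), n_clusters >= 1, n_clusters <= 3)
  wm <- assign_tissue_maxprob(anatomy$prob_gm, anatomy$prob_wm,
                              anatomy$prob_csf) == TISSUE_WM
  d <- anatomy$grid_shape
  allowed <- wm & !anatomy$subcortical_mask
  # erode by the sphere radius: centers whose whole sphere stays in `allowed`
  og <- as.matrix(expand.grid(dx = -ceiling(radius):ceiling(radius),
                              dy = -ceiling(radius):ceiling(radius),
                              dz = -ceiling(radius):ceiling(radius)))
  og <- og[rowSums(og^2) <= radius^2, , drop = FALSE]
  shift3 <- function(a, off) {
    out <- array(FALSE, d)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]) + off[ax]
      i[i >= 1 & i <= d[ax]]
    })
    dst <- lapply(1:3, function(ax) src[[ax]] - off[ax])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  eroded <- Reduce(`&`, lapply(seq_len(nrow(og)),
                               function(r) shift3(allowed, og[r, ])))
  cand <- which(eroded)
  if (!length(cand)) {
    stop("no WM placement found for an effect sphere of radius ", radius,
         "; use a larger grid or a smaller radius")
  }
  coords <- arrayInd(cand, d)
  # greedy max-min-distance spread, deterministically seeded at the
  # candidate farthest from the subcortical block
  sub_ctr <- colMeans(arrayInd(which(anatomy$subcortical_mask), d))
  chosen <- integer(0)
  dist_to_sub <- sqrt(rowSums(sweep(coords, 2, sub_ctr)^2))
  chosen[1] <- which.max(dist_to_sub)
  while (length(chosen) < n_clusters) {
    dmin <- rep(Inf, nrow(coords))
    for (c0 in chosen) {
      dmin <- pmin(dmin, sqrt(rowSums(sweep(coords, 2, coords[c0, ])^2)))
    }
    nxt <- which.max(dmin)
    if (dmin[nxt] <= 2 * radius + 1) {
      stop("cannot place ", n_clusters, " non-adjacent effect spheres of ",
           "radius ", radius, " in this phantom's WM")
    }
    chosen <- c(chosen, nxt)
  }
  seeds <- lapply(chosen, function(ci) {
    list(center = as.integer(coords[ci, ]), radius = radius)
  })
  effect_spec(seeds, amplitude_ratio = amplitude_ratio, band = band)
}

# Logical array of voxels inside any effect sphere.
effect_cluster_mask <- function(anatomy, effect) {
  d <- anatomy$grid_shape
  tmp <- array(0, d)
  ii <- slice.index(tmp, 1); jj <- slice.index(tmp, 2); kk <- slice.index(tmp, 3)
  m <- array(FALSE, d)
  for (s in effect$cluster_seeds) {
    ctr <- s$center
    m <- m | ((ii - ctr[1])^2 + (jj - ctr[2])^2 + (kk - ctr[3])^2 <= s$radius^2)
  }
  m
}

#' Default noise and signal-level configuration for the simulator
#'
#' The oscillatory component is a sum of `n_freq` sinusoids at frequencies
#' drawn uniformly within the effect band, each of amplitude `osc_amp`, with
#' independent uniform phases per voxel. Noise is first-order autoregressive
#' Gaussian (marginal SD `ar_sd`, lag-1 coefficient `ar_coef`) plus white
#' thermal noise (`white_sd`). Setting `ar_sd = 0` and `white_sd = 0`
#' disables noise, making spectra exactly the configured sinusoids.
#'
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param ar_sd marginal SD of the AR(1) component (signal units).
#' @param white_sd SD of the white noise component.
#' @param baseline mean signal level added everywhere.
#' @param osc_amp per-sinusoid amplitude of the oscillatory component.
#' @param n_freq number of sinusoids.
#' @param freqs optional fixed frequency vector (Hz) overriding the draw.
#' @param spike_volumes integer indices of volumes carrying a motion-spike
#'   artifact (global signal jump plus a motion-trace jump); empty by default.
#' @param spike_signal signal jump added at spike volumes.
#' @param spike_motion_mm translation jump (mm) added to the motion trace at
#'   spike volumes.
#' @param motion_step_mm SD of the per-volume translation random-walk step.
#' @param motion_step_deg SD of the per-volume rotation random-walk step
#'   (degrees).
#' @return A list of class `noise_params`.
#' @export
default_noise_params <- function(ar_coef = 0.3, ar_sd = 1, white_sd = 0.5,
                                 baseline = 100, osc_amp = 1, n_freq = 4L,
                                 freqs = NULL, spike_volumes = integer(0),
                                 spike_signal = 5, spike_motion_mm = 1.5,
                                 motion_step_mm = 0.02, motion_step_deg = 0.01) {
  stopifnot(ar_coef >= 0, ar_coef < 1, ar_sd >= 0, white_sd >= 0,
            osc_amp >= 0, n_freq >= 1)
  structure(list(ar_coef = ar_coef, ar_sd = ar_sd, white_sd = white_sd,
                 baseline = baseline, osc_amp = osc_amp,
                 n_freq = as.integer(n_freq), freqs = freqs,
                 spike_volumes = as.integer(spike_volumes),
                 spike_signal = spike_signal,
                 spike_motion_mm = spike_motion_mm,
                 motion_step_mm = motion_step_mm,
                 motion_step_deg = motion_step_deg),
            class = "noise_params")
}

#' Simulate one subject's 4D BOLD series and motion trace
#'
#' Per voxel the signal is
#' `baseline + a(v) * sum_k sin(2*pi*f_k*t + phi_vk) + AR(1) + white noise`,
#' with the oscillatory amplitude `a(v)` equal to `osc_amp` inside the brain
#' (GM or WM by maximum probability) and scaled by the effect's
#' `amplitude_ratio` inside effect clusters when `group = "patient"`. Random
#' draws do not depend on the group label, so two calls differing only in
#' `group` share frequencies, phases, noise, and motion; with noise disabled
#' the patient/control spectra then differ exactly by the amplitude ratio at
#' every non-DC bin of cluster voxels.
#'
#' Motion traces are smooth Gaussian random walks (translations in mm,
#' rotations in degrees), with a translation jump at configured spike volumes.
#'
#' @param anatomy a `phantom_anatomy`.
#' @param group `"patient"` or `"control"`.
#' @param effect an `effect_spec`; every cluster voxel must be WM by maximum
#'   probability, otherwise an error is raised.
#' @param n_volumes number of time points (>= 20); the default 240 leaves 230
#'   analysed volumes after dropping the first 10.
#' @param tr_s repetition time in seconds.
#' @param noise_params a [default_noise_params()] list.
#' @param seed integer seed.
#' @param subject_id optional id string.
#' @return An object of class `subject_record`: `subject_id`, `group`,
#'   `bold` (a `volume4d`), `motion6` (n_volumes x 6 matrix), `clinical`
#'   (filled by [simulate_cohort()]), `seed`.
#' @export
simulate_subject <- function(anatomy, group = c("patient", "control"), effect,
                             n_volumes = 240L, tr_s = 2,
                             noise_params = default_noise_params(),
                             seed = 1L, subject_id = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(anatomy, "phantom_anatomy"), inherits(effect, "effect_spec"))
  if (n_volumes < 20L) stop("`n_volumes` must be at least 20")
  if (tr_s <= 0) stop("`tr_s` must be positive")
  np <- noise_params

  labels <- assign_tissue_maxprob(anatomy$prob_gm, anatomy$prob_wm, anatomy$prob_csf)
  cl_mask <- effect_cluster_mask(anatomy, effect)
  if (any(labels[cl_mask] != TISSUE_WM)) {
    stop("effect cluster extends outside the WM compartment")
  }

  set.seed(as.integer(seed))
  freqs <- if (!is.null(np$freqs)) np$freqs else
    runif(np$n_freq, effect$band[1], effect$band[2])
  K <- length(freqs)
  V <- prod(anatomy$grid_shape)
  phases <- matrix(runif(V * K, 0, 2 * pi), V, K)

  amp <- numeric(V)
  brain <- labels == TISSUE_GM | labels == TISSUE_WM
  amp[brain] <- np$osc_amp
  if (group == "patient") {
    amp[cl_mask & brain] <- amp[cl_mask & brain] * effect$amplitude_ratio
  }

  extra <- numeric(n_volumes)
  sv <- np$spike_volumes[np$spike_volumes >= 1 & np$spike_volumes <= n_volumes]
  extra[sv] <- np$spike_signal

  tsec <- (seq_len(n_volumes) - 1) * tr_s
  mat <- synth_bold_cpp(amp, phases, 2 * pi * freqs, tsec, np$baseline,
                        np$ar_coef, np$ar_sd, np$white_sd, extra)
  bold <- volume4d(array(mat, c(anatomy$grid_shape, n_volumes)),
                   affine = anatomy$affine, tr_s = tr_s)

  motion6 <- cbind(
    matrix(rnorm(3 * n_volumes, 0, np$motion_step_mm), n_volumes, 3),
    matrix(rnorm(3 * n_volumes, 0, np$motion_step_deg), n_volumes, 3)
  )
  motion6 <- apply(motion6, 2, cumsum)
  motion6[sv, 1] <- motion6[sv, 1] + np$spike_motion_mm
  colnames(motion6) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                         "rot_x_deg", "rot_y_deg", "rot_z_deg")

  structure(list(subject_id = subject_id %||% sprintf("sub-%05d", seed),
                 group = group, bold = bold, motion6 = motion6,
                 clinical = NULL, seed = as.integer(seed)),
            class = "subject_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-group cohort with a clinical covariate table
#'
#' Generates `n_patients` patient and `n_controls` control subjects from the
#' same anatomy and effect specification (per-subject seeds are derived from
#' `seed`), together with a clinical covariate table whose continuous
#' variables are drawn per group from independent normal distributions with
#' the reference means and SDs of [table1_summaries()], and whose binary
#' covariates follow the reference rates. A fraction of controls
#' (6 of 41 at reference size) carry missing biochemical values, matching the
#' reference table's footnote, and a fraction of patients (4 of 48) drop out
#' of follow-up.
#'
#' @param anatomy a `phantom_anatomy`.
#' @param effect an `effect_spec`.
#' @param n_patients,n_controls group sizes, both >= 2.
#' @param n_volumes,tr_s,noise_params forwarded to [simulate_subject()].
#' @param seed integer master seed; the whole cohort is deterministic in it.
#' @return An object of class `wm_cohort`: `subjects` (list of
#'   `subject_record`), `clinical` (data.frame), `anatomy`, `effect`, `seed`.
#' @export
simulate_cohort <- function(anatomy, effect, n_patients = 48L, n_controls = 41L,
                            n_volumes = 240L, tr_s = 2,
                            noise_params = default_noise_params(), seed = 1L) {
  if (n_patients < 2L || n_controls < 2L) {
    stop("both group sizes must be at least 2")
  }
  set.seed(as.integer(seed))
  n_tot <- n_patients + n_controls
  sub_seeds <- sample.int(2147483646L, n_tot + 1L)
  clinical <- simulate_clinical(n_patients, n_controls, seed = sub_seeds[n_tot + 1L])

  groups <- c(rep("patient", n_patients), rep("control", n_controls))
  subjects <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    rec <- simulate_subject(anatomy, groups[i], effect,
                            n_volumes = n_volumes, tr_s = tr_s,
                            noise_params = noise_params,
                            seed = sub_seeds[i],
                            subject_id = clinical$subject_id[i])
    rec$clinical <- as.list(clinical[i, setdiff(names(clinical), "subject_id")])
    subjects[[i]] <- rec
  }
  structure(list(subjects = subjects, clinical = clinical,
                 anatomy = anatomy, effect = effect, seed = as.integer(seed)),
            class = "wm_cohort")
}

#' @export
print.wm_cohort <- function(x, ...) {
  cat(sprintf("<wm_cohort> %d subjects (%d patients, %d controls), grid %s\n",
              length(x$subjects), sum(x$clinical$group == "patient"),
              sum(x$clinical$group == "control"),
              paste(x$anatomy$grid_shape, collapse = "x")))
  invisible(x)
}
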