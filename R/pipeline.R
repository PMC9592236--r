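# Default run configuration: the analysis parameters of the study design
# (band 0.01-0.15 Hz over a 0-0.25 Hz axis, 10 dropped volumes, 4 mm
# smoothing, >60% WM overlap, voxel/cluster p 0.05, gamma 0.9, alpha 0.001)
# plus the phantom/simulation defaults.
pipeline_defaults <- function() {
  list(
    seed = 1L,
    grid = c(32L, 32L, 32L), voxel_size_mm = 3,
    n_patients = 48L, n_controls = 41L,
    n_volumes = 240L, tr_s = 2,
    amplitude_ratio = 0.6, effect_radius = 2, n_effect_clusters = 3L,
    ar_coef = 0.3, ar_sd = 1, white_sd = 0.5, baseline = 100,
    osc_amp = 1, n_freq = 4L, spike_volumes = integer(0),
    drop = 10L, fwhm_mm = 4, fd_threshold_mm = 0.5,
    wm_threshold = 0.6,
    band_low = 0.01, band_high = 0.15, full_low = 0, full_high = 0.25,
    voxel_p = 0.05, cluster_p = 0.05, tails = "two", connectivity = 18L,
    gamma = 0.9, alpha = 0.001, epochs = 1000L, epsilon0 = 0.3,
    metrics = c("ALFF", "fALFF")
  )
}

#' Validate and complete a run configuration
#'
#' Merges user settings into the default parameter set; unknown keys are
#' rejected by name and all range violations are reported together.
#'
#' @param config named list of overrides, or a path to a JSON file of them;
#'   empty input yields the full default set.
#' @return A completed configuration of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(all(cfg$grid >= 16), "grid: every dimension must be >= 16")
  chk(cfg$voxel_size_mm > 0, "voxel_size_mm must be positive")
  chk(cfg$n_patients >= 2 && cfg$n_controls >= 2, "group sizes must be >= 2")
  chk(cfg$n_volumes >= 20, "n_volumes must be >= 20")
  chk(cfg$tr_s > 0, "tr_s must be positive")
  chk(cfg$amplitude_ratio > 0 && cfg$amplitude_ratio <= 1,
      "amplitude_ratio must lie in (0, 1]")
  chk(cfg$drop >= 0 && cfg$drop < cfg$n_volumes,
      "drop must lie in [0, n_volumes)")
  chk(cfg$fwhm_mm >= 0, "fwhm_mm must be non-negative")
  chk(cfg$fd_threshold_mm > 0, "fd_threshold_mm must be positive")
  chk(cfg$wm_threshold >= 0 && cfg$wm_threshold < 1,
      "wm_threshold must lie in [0, 1)")
  chk(cfg$band_low >= 0 && cfg$band_high > cfg$band_low,
      "band: need 0 <= band_low < band_high")
  chk(cfg$full_low <= cfg$band_low && cfg$full_high >= cfg$band_high,
      "full band must contain the metric band")
  chk(cfg$voxel_p > 0 && cfg$voxel_p < 1, "voxel_p must lie in (0, 1)")
  chk(cfg$cluster_p > 0 && cfg$cluster_p < 1, "cluster_p must lie in (0, 1)")
  chk(cfg$tails %in% c("one", "two"), "tails must be 'one' or 'two'")
  chk(cfg$connectivity %in% c(6, 18, 26), "connectivity must be 6, 18 or 26")
  chk(cfg$gamma >= 0 && cfg$gamma < 1, "gamma must lie in [0, 1)")
  chk(cfg$alpha >= 0, "alpha must be non-negative")
  chk(cfg$epochs >= 1, "epochs must be >= 1")
  chk(all(cfg$metrics %in% c("ALFF", "fALFF")) && length(cfg$metrics) >= 1,
      "metrics must be a subset of ALFF, fALFF")
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

config_band <- function(cfg) {
  band_spec(cfg$band_low, cfg$band_high, cfg$full_low, cfg$full_high)
}

#' Preprocess one subject's BOLD series
#'
#' Applies the fixed stage order: trim leading volumes, remove the linear
#' trend, regress Friston-24 + mean-CSF + motion-spike regressors within the
#' brain, then smooth within the WM compartment.
#'
#' @param record a `subject_record`.
#' @param labels tissue label array for the subject's grid.
#' @param cfg a `run_config`.
#' @return list with `bold` (preprocessed `volume4d`), `spikes` (spike
#'   report), `wm_mask`.
#' @export
preprocess_subject <- function(record, labels, cfg) {
  bold <- drop_initial_volumes(record$bold, cfg$drop)
  motion <- record$motion6[(cfg$drop + 1):nrow(record$motion6), , drop = FALSE]
  bold <- detrend_linear(bold)
  csf_mask <- labels == TISSUE_CSF
  brain <- labels == TISSUE_GM | labels == TISSUE_WM
  spikes <- detect_spikes(motion, cfg$fd_threshold_mm)
  design <- build_nuisance_design(motion,
                                  csf_series = mean_roi_signal(bold, csf_mask),
                                  spike_indices = spikes$indices)
  bold <- nuisance_regress(bold, design, mask = brain)
  wm_mask <- labels == TISSUE_WM
  bold <- smooth_within_mask(bold, wm_mask, cfg$fwhm_mm)
  list(bold = bold, spikes = spikes, wm_mask = wm_mask)
}

#' Compute normalised metric maps for one subject
#'
#' ALFF maps are mALFF-normalised then z-transformed; fALFF maps are
#' z-transformed, following the metric definitions' final-step ordering.
#'
#' @param bold preprocessed `volume4d`.
#' @param mask individual WM mask.
#' @param cfg a `run_config`.
#' @return named list of z-scored `metric_map`s (subset of ALFF, fALFF).
#' @export
subject_metric_maps <- function(bold, mask, cfg) {
  band <- config_band(cfg)
  out <- list()
  if ("ALFF" %in% cfg$metrics) {
    out$ALFF <- ztransform_map(malff_normalize(
      metric_map(bold, mask, "alff", band)))
  }
  if ("fALFF" %in% cfg$metrics) {
    out$fALFF <- ztransform_map(metric_map(bold, mask, "falff", band))
  }
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> tissue masks -> spectral metrics ->
#' group inference -> feature extraction -> classification -> clinical
#' statistics, collecting per-stage content hashes into a run manifest.
#' Re-running with an identical configuration reproduces identical hashes.
#'
#' @param config a `run_config` from [validate_config()] (or a list passed
#'   through it).
#' @param out_dir optional output directory for artifacts (t-maps, masks,
#'   cluster tables, features, reports, manifest), each with a JSON sidecar
#'   naming the producing stage and parameters.
#' @param force recompute even when `out_dir` holds a manifest with the same
#'   configuration hash.
#' @param verbose print stage progress.
#' @return list of class `wm_pipeline_result`: `config`, `cluster_tables`,
#'   `stat_maps`, `smoothness`, `classification`, `features`,
#'   `clinical_tests`, `correlations`, `group_mask`, `manifest`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL,
                         force = FALSE, verbose = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  cfg <- config
  cfg_hash <- rlang::hash(unclass(cfg))
  if (!is.null(out_dir) && !force) {
    mpath <- file.path(out_dir, "manifest.json")
    if (file.exists(mpath)) {
      prev <- jsonlite::read_json(mpath, simplifyVector = TRUE)
      if (identical(prev$config_hash, cfg_hash)) {
        if (verbose) message("outputs up to date; skipping (use force = TRUE)")
        prev$reused <- TRUE
        return(structure(list(config = cfg, manifest = prev),
                         class = "wm_pipeline_result"))
      }
    }
  }
  say <- function(...) if (verbose) message(sprintf(...))
  warnings_log <- character(0)
  hashes <- list()

  say("simulate: %d + %d subjects on a %s grid",
      cfg$n_patients, cfg$n_controls, paste(cfg$grid, collapse = "x"))
  anatomy <- make_phantom_anatomy(cfg$grid, cfg$voxel_size_mm, seed = cfg$seed)
  effect <- default_effect_spec(anatomy, cfg$amplitude_ratio,
                                n_clusters = cfg$n_effect_clusters,
                                radius = cfg$effect_radius,
                                band = c(cfg$band_low, cfg$band_high))
  noise <- default_noise_params(ar_coef = cfg$ar_coef, ar_sd = cfg$ar_sd,
                                white_sd = cfg$white_sd, baseline = cfg$baseline,
                                osc_amp = cfg$osc_amp, n_freq = cfg$n_freq,
                                spike_volumes = cfg$spike_volumes)
  cohort <- simulate_cohort(anatomy, effect, cfg$n_patients, cfg$n_controls,
                            n_volumes = cfg$n_volumes, tr_s = cfg$tr_s,
                            noise_params = noise, seed = cfg$seed)
  hashes$simulate <- rlang::hash(cohort$clinical)

  labels <- assign_tissue_maxprob(anatomy$prob_gm, anatomy$prob_wm,
                                  anatomy$prob_csf)
  say("preprocess + metrics: %d subjects", length(cohort$subjects))
  maps <- list()
  wm_masks <- list()
  n_spike_total <- 0L
  for (i in seq_along(cohort$subjects)) {
    pp <- preprocess_subject(cohort$subjects[[i]], labels, cfg)
    n_spike_total <- n_spike_total + length(pp$spikes$indices)
    wm_masks[[i]] <- pp$wm_mask
    maps[[i]] <- subject_metric_maps(pp$bold, pp$wm_mask, cfg)
  }
  hashes$preprocess <- rlang::hash(lapply(maps, function(m)
    lapply(m, function(x) x$values)))

  say("group WM mask")
  gmask <- group_wm_mask(wm_masks, cfg$wm_threshold)
  gmask <- remove_subcortical(gmask, anatomy$subcortical_mask)
  hashes$mask <- rlang::hash(gmask$mask)

  is_pat <- cohort$clinical$group == "patient"
  say("group inference")
  stat_maps <- list(); smoothness <- list(); cluster_tables <- list()
  for (m in cfg$metrics) {
    mm <- lapply(maps, `[[`, m)
    stat <- voxelwise_ttest(mm[is_pat], mm[!is_pat], gmask$mask)
    if (stat$n_zero_variance > 0) {
      warnings_log <- c(warnings_log, sprintf(
        "%s: %d zero-variance voxels set to t = 0", m, stat$n_zero_variance))
    }
    res <- group_residuals(mm[is_pat], mm[!is_pat], gmask$mask)
    sm <- estimate_smoothness(res, gmask$mask,
                              voxel_sizes(anatomy$affine))
    tab <- grf_cluster_correction(stat, sm, voxel_p = cfg$voxel_p,
                                  cluster_p = cfg$cluster_p,
                                  tails = cfg$tails,
                                  connectivity = cfg$connectivity,
                                  atlas_labels = anatomy$atlas_labels,
                                  atlas_names = anatomy$atlas_names,
                                  affine = anatomy$affine)
    stat_maps[[m]] <- stat; smoothness[[m]] <- sm; cluster_tables[[m]] <- tab
  }
  hashes$inference <- rlang::hash(lapply(cluster_tables, function(t)
    t[, c("extent_voxels", "peak_t", "corrected_p")]))

  n_clusters <- sum(vapply(cluster_tables, nrow, integer(1)))
  features <- NULL; classification <- NULL
  if (n_clusters > 0) {
    say("features + classification: %d clusters", n_clusters)
    features <- extract_features(
      lapply(cfg$metrics, function(m) lapply(maps, `[[`, m)) |>
        stats::setNames(cfg$metrics),
      cluster_tables, cohort$clinical$group)
    classification <- loocv(features, gamma = cfg$gamma, alpha = cfg$alpha,
                            epochs = cfg$epochs, epsilon0 = cfg$epsilon0,
                            seed = cfg$seed)
    hashes$classification <- rlang::hash(list(features$values,
                                              classification$confusion))
  } else {
    warnings_log <- c(warnings_log,
                      "no significant clusters; classification skipped")
  }

  say("clinical statistics")
  clin <- cohort$clinical
  cont_vars <- table1_summaries()$variable
  clin_rows <- lapply(cont_vars, function(v) {
    p <- ttest_from_samples(clin[[v]][is_pat], clin[[v]][!is_pat], "pooled")
    w <- ttest_from_samples(clin[[v]][is_pat], clin[[v]][!is_pat], "welch")
    data.frame(variable = v, t_pooled = p$statistic, p_pooled = p$p_two_tailed,
               t_welch = w$statistic, p_welch = w$p_two_tailed)
  })
  clinical_tests <- do.call(rbind, clin_rows)
  sex_tab <- table(factor(clin$group, c("patient", "control")),
                   factor(clin$sex, c("M", "F")))
  sex_test <- chisq_2x2(as.matrix(sex_tab))
  clinical_tests <- rbind(clinical_tests,
                          data.frame(variable = "sex(chi-square)",
                                     t_pooled = sex_test$statistic,
                                     p_pooled = sex_test$p_two_tailed,
                                     t_welch = NA, p_welch = NA))
  correlations <- NULL
  if (!is.null(features)) {
    corr_vars <- setdiff(cont_vars, "age")
    rows <- list()
    for (f in seq_len(ncol(features$values))) {
      for (v in corr_vars) {
        ct <- pearson_corr(features$values[is_pat, f], clin[[v]][is_pat])
        rows[[length(rows) + 1L]] <- data.frame(
          feature = features$feature_names[f], variable = v,
          r = ct$statistic, p = ct$p_two_tailed)
      }
    }
    correlations <- do.call(rbind, rows)
  }
  hashes$clinical <- rlang::hash(clinical_tests)

  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    config_hash = cfg_hash,
    stage_hashes = hashes,
    n_spike_volumes = n_spike_total,
    n_significant_clusters = n_clusters,
    warnings = warnings_log,
    parameters = unclass(cfg)
  )

  result <- structure(list(config = cfg, cluster_tables = cluster_tables,
                           stat_maps = stat_maps, smoothness = smoothness,
                           features = features, classification = classification,
                           clinical_tests = clinical_tests,
                           correlations = correlations,
                           group_mask = gmask, manifest = manifest),
                      class = "wm_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, anatomy, out_dir)
  result
}

# Serialise pipeline artifacts; every file gets a stage/parameter sidecar.
write_pipeline_outputs <- function(result, anatomy, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  for (m in names(result$stat_maps)) {
    p <- file.path(out_dir, sprintf("tmap_%s.nii.gz", m))
    write_nifti_volume(result$stat_maps[[m]]$t, p, affine = anatomy$affine)
    write_sidecar(p, "group_inference",
                  list(metric = m, voxel_p = cfg$voxel_p,
                       cluster_p = cfg$cluster_p, tails = cfg$tails))
    tabp <- file.path(out_dir, sprintf("clusters_%s.tsv", m))
    write_tsv(result$cluster_tables[[m]], tabp)
    write_sidecar(tabp, "group_inference",
                  list(metric = m, connectivity = cfg$connectivity))
  }
  gp <- file.path(out_dir, "group_wm_mask.nii.gz")
  write_nifti_volume(result$group_mask$mask + 0, gp, affine = anatomy$affine)
  write_sidecar(gp, "tissue_masks", list(threshold = cfg$wm_threshold))
  if (!is.null(result$features)) {
    fp <- file.path(out_dir, "features.tsv")
    write_tsv(cbind(data.frame(group = result$features$labels),
                    as.data.frame(result$features$values)), fp)
    write_sidecar(fp, "rl_classifier", list(source = "cluster means"))
  }
  if (!is.null(result$classification)) {
    jsonlite::write_json(
      list(confusion = as.list(result$classification$confusion),
           accuracy = result$classification$accuracy,
           sensitivity = result$classification$sensitivity,
           specificity = result$classification$specificity,
           precision = result$classification$precision,
           auc = result$classification$auc),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tsv(result$classification$roc, file.path(out_dir, "roc_points.tsv"))
  }
  write_tsv(result$clinical_tests, file.path(out_dir, "clinical_tests.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.wm_pipeline_result <- function(x, ...) {
  cat("<wm_pipeline_result>\n")
  for (m in names(x$cluster_tables)) {
    cat(sprintf("  %s: %d significant cluster(s)\n", m,
                nrow(x$cluster_tables[[m]])))
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  LOOCV accuracy %.2f%%, AUC %.3f\n",
                x$classification$accuracy, x$classification$auc))
  }
  invisible(x)
}
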