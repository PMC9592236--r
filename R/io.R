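#' Write a volume to a NIfTI-1 file
#'
#' @param vol a `volume4d` or a 3D/4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 grid-to-world transform; taken from the `volume4d` when
#'   omitted.
#' @param tr_s repetition time stored in the time pixdim (4D only).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(vol, path, affine = NULL, tr_s = NULL) {
  if (inherits(vol, "volume4d")) {
    affine <- affine %||% vol$affine
    tr_s <- tr_s %||% vol$tr_s
    vol <- vol$data
  }
  if (is.null(affine)) affine <- diag(4)
  storage.mode(vol) <- "double"
  img <- RNifti::asNifti(vol)
  if (!is.null(tr_s) && length(dim(vol)) == 4L) {
    pd <- RNifti::pixdim(img)
    pd[4] <- tr_s
    RNifti::pixdim(img) <- pd
  }
  # sform only, set after pixdim: the qform/pixdim setters rebuild each other
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a `volume4d` (4D) or array (3D)
#'
#' @param path NIfTI file path.
#' @param tr_s override for the repetition time; defaults to the file's time
#'   pixdim.
#' @return `volume4d` for 4D images, plain array otherwise.
#' @export
read_nifti_volume <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 4L) {
    tr <- tr_s %||% RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    volume4d(arr, affine = RNifti::xform(img), tr_s = tr)
  } else {
    arr
  }
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# Sidecar JSON recording the producing stage and its parameters.
write_sidecar <- function(path, stage, params) {
  jsonlite::write_json(list(stage = stage, parameters = params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Per subject: the BOLD series as NIfTI-1 and the motion trace as a
#' 6-column TSV; cohort-wide: the clinical table as TSV, tissue probability
#' and label volumes, and a JSON sidecar with the TR, seed and effect
#' specification.
#'
#' @param cohort a `wm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  an <- cohort$anatomy
  for (nm in c("prob_gm", "prob_wm", "prob_csf")) {
    write_nifti_volume(an[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                       affine = an$affine)
  }
  write_nifti_volume(an$atlas_labels + 0, file.path(dir, "atlas_labels.nii.gz"),
                     affine = an$affine)
  write_nifti_volume(an$subcortical_mask + 0,
                     file.path(dir, "subcortical_mask.nii.gz"),
                     affine = an$affine)
  write_tsv(an$atlas_names, file.path(dir, "atlas_labels.tsv"))
  for (s in cohort$subjects) {
    write_nifti_volume(s$bold, file.path(dir, paste0(s$subject_id, "_bold.nii.gz")))
    write_tsv(as.data.frame(s$motion6),
              file.path(dir, paste0(s$subject_id, "_motion.tsv")))
  }
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(
    list(tr_s = cohort$subjects[[1]]$bold$tr_s,
         seed = cohort$seed,
         n_patients = sum(cohort$clinical$group == "patient"),
         n_controls = sum(cohort$clinical$group == "control"),
         effect = list(amplitude_ratio = cohort$effect$amplitude_ratio,
                       band = cohort$effect$band,
                       cluster_seeds = cohort$effect$cluster_seeds)),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write a metric map with its JSON sidecar
#'
#' The sidecar records the metric, band and normalisation state.
#'
#' @param map a `metric_map`.
#' @param path output NIfTI path.
#' @param affine optional grid-to-world transform.
#' @return the path, invisibly.
#' @export
write_metric_map <- function(map, path, affine = NULL) {
  stopifnot(inherits(map, "metric_map"))
  write_nifti_volume(map$values, path, affine = affine)
  write_sidecar(path, "spectral_metrics",
                list(metric = map$metric,
                     band = unclass(map$band),
                     normalization = map$normalization,
                     tr_s = map$tr_s))
  invisible(path)
}

#' Serialise a trained Q-model to JSON
#'
#' Stores the weight matrix, hyperparameters and seed; the model can be
#' restored with [read_q_model()].
#'
#' @param model a `q_model`.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_q_model <- function(model, path) {
  stopifnot(inherits(model, "q_model"))
  jsonlite::write_json(
    list(weights = model$weights, gamma = model$gamma, alpha = model$alpha,
         epochs = model$epochs, epsilon0 = model$epsilon0, seed = model$seed,
         feature_names = model$feature_names),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_q_model
#' @export
read_q_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(unlist(x$weights), nrow = 2, byrow = FALSE)
  if (!is.null(dim(x$weights))) w <- x$weights
  rownames(w) <- c("predict_patient", "predict_control")
  colnames(w) <- c(x$feature_names, "bias")
  structure(list(weights = w, gamma = x$gamma, alpha = x$alpha,
                 epochs = as.integer(x$epochs), epsilon0 = x$epsilon0,
                 seed = as.integer(x$seed), feature_names = x$feature_names),
            class = "q_model")
}
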