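#' Reference group summaries for the clinical covariates
#'
#' Per-variable mean, SD and measured sample size for the TIA patient group
#' (n = 48) and the healthy-control group (n = 41, of whom 6 have missing
#' physiological/biochemical measurements, leaving n = 35 for those rows).
#' These summaries drive the clinical covariate generator and the desk-check
#' group comparisons.
#'
#' @return data.frame with columns `variable`, `patient_mean`, `patient_sd`,
#'   `patient_n`, `control_mean`, `control_sd`, `control_n`,
#'   `control_missing` (whether controls carry missing values for the row).
#' @export
table1_summaries <- function() {
  data.frame(
    variable = c("age", "systolic_bp", "diastolic_bp", "blood_sugar",
                 "total_cholesterol", "triglycerides", "hdl_c", "ldl_c"),
    patient_mean = c(57.60, 145.54, 86.67, 6.30, 5.24, 1.60, 1.11, 3.31),
    patient_sd   = c(9.78, 20.75, 10.38, 2.11, 1.14, 0.94, 0.24, 0.97),
    patient_n    = 48L,
    control_mean = c(55.02, 127.55, 80.03, 5.12, 4.75, 1.92, 1.05, 2.69),
    control_sd   = c(8.03, 19.53, 10.90, 0.74, 1.01, 1.35, 0.29, 0.90),
    control_n    = c(41L, rep(35L, 7)),
    control_missing = c(FALSE, rep(TRUE, 7)),
    stringsAsFactors = FALSE
  )
}

# Reference binary covariate rates (patients) and cohort structure constants.
table1_rates <- function() {
  list(
    sex_male = c(patient = 37 / 48, control = 30 / 41),
    smoking = 31 / 48, drinking = 20 / 48, hypertension = 22 / 48,
    diabetes = 8 / 48, coronary_artery_disease = 2 / 48,
    atrial_fibrillation = 1 / 48, statins = 2 / 48,
    dwi_hyperintensity = 6 / 48, vessel_stenosis = 9 / 48,
    followup_events = 12L, followup_dropouts = 4L,
    control_missing = 6L, reference_n_patients = 48L, reference_n_controls = 41L
  )
}

#' Simulate a clinical covariate table
#'
#' Continuous covariates are independent normals per group with the
#' [table1_summaries()] means and SDs (the reference table reports no
#' covariance structure). Binary covariates are Bernoulli at the reference
#' rates; they are recorded for patients only, as in the reference table.
#' The last `round(n_controls * 6/41)` controls have their
#' physiological/biochemical values set to `NA`, and
#' `round(n_patients * 4/48)` patients drop out of follow-up (`NA` outcome);
#' events among the remainder occur at rate 12/44.
#'
#' @param n_patients,n_controls group sizes.
#' @param seed integer seed.
#' @return data.frame with one row per subject; `group` is
#'   `"patient"`/`"control"`.
#' @export
simulate_clinical <- function(n_patients = 48L, n_controls = 41L, seed = 1L) {
  set.seed(as.integer(seed))
  ref <- table1_summaries()
  rates <- table1_rates()
  n <- n_patients + n_controls
  grp <- c(rep("patient", n_patients), rep("control", n_controls))
  out <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = grp, stringsAsFactors = FALSE
  )
  out$sex <- ifelse(
    runif(n) < ifelse(grp == "patient", rates$sex_male["patient"],
                      rates$sex_male["control"]),
    "M", "F")
  for (i in seq_len(nrow(ref))) {
    v <- ref$variable[i]
    out[[v]] <- c(rnorm(n_patients, ref$patient_mean[i], ref$patient_sd[i]),
                  rnorm(n_controls, ref$control_mean[i], ref$control_sd[i]))
  }
  n_miss <- round(n_controls * rates$control_missing /
                    rates$reference_n_controls)
  if (n_miss > 0) {
    miss_rows <- n_patients + (n_controls - n_miss + 1):n_controls
    out[miss_rows, ref$variable[ref$control_missing]] <- NA_real_
  }
  out$abcd2 <- NA_integer_
  out$abcd2[grp == "patient"] <-
    sample(2:6, n_patients, replace = TRUE, prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  for (v in c("smoking", "drinking", "hypertension", "diabetes",
              "coronary_artery_disease", "atrial_fibrillation", "statins",
              "dwi_hyperintensity", "vessel_stenosis")) {
    out[[v]] <- NA
    out[[v]][grp == "patient"] <- runif(n_patients) < rates[[v]]
  }
  n_drop <- round(n_patients * rates$followup_dropouts /
                    rates$reference_n_patients)
  ref_at_risk <- rates$reference_n_patients - rates$followup_dropouts
  out$followup_event <- NA
  p_event <- rates$followup_events / ref_at_risk
  out$followup_event[grp == "patient"] <- runif(n_patients) < p_event
  if (n_drop > 0) {
    out$followup_event[seq_len(n_drop)] <- NA   # dropouts, outcome unknown
  }
  out
}
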