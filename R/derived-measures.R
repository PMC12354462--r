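#' Body mass index
#'
#' BMI = weight (kg) / height (m)^2, with height supplied in centimetres as
#' recorded on the cohort table.
#'
#' @param weight_kg Body weight in kilograms; must be positive.
#' @param height_cm Standing height in centimetres; must be positive.
#' @return BMI in kg/m^2. Vectorised over both arguments.
#' @examples
#' compute_bmi(100, 200) # 25
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("compute_bmi: weight must be finite and positive")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("compute_bmi: height must be finite and positive")
  weight_kg / (height_cm / 100)^2
}

#' Skeletal muscle index
#'
#' SMI = appendicular lean mass (kg) / height (m)^2. This is the quantity the
#' AWGS-2019 low-muscle-mass cutoffs are defined on.
#'
#' @param alm_kg Appendicular lean mass in kilograms; must be non-negative.
#' @param height_cm Standing height in centimetres; must be positive.
#' @return SMI in kg/m^2. Vectorised.
#' @export
compute_smi <- function(alm_kg, height_cm) {
  if (any(!is.finite(alm_kg)) || any(alm_kg < 0))
    stop("compute_smi: ALM must be finite and non-negative")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0))
    stop("compute_smi: height must be finite and positive")
  alm_kg / (height_cm / 100)^2
}

#' Left ventricular mass (linear-method cube formula)
#'
#' Devereux-convention LVM from end-diastolic echo dimensions:
#' \deqn{LVM = 0.8 \cdot 1.04 \cdot ((LVDd + IVSTd + LVPWTd)^3 - LVDd^3) + 0.6}
#' with all lengths in centimetres. Inputs are taken in millimetres (the unit
#' echo reports are tabulated in) and converted internally; the 0.8*1.04
#' constant is only valid on the cm scale, where typical adult values land in
#' the 100-200 g range.
#'
#' @param lvdd_mm Left ventricular end-diastolic diameter, mm (> 0).
#' @param ivstd_mm Interventricular septal thickness at end-diastole, mm (>= 0).
#' @param lvpwtd_mm Posterior wall thickness at end-diastole, mm (>= 0).
#' @return LVM in grams. Vectorised. Zero wall thicknesses are allowed as a
#'   degenerate case (the cube difference vanishes and the 0.6 g offset is
#'   returned).
#' @export
compute_lvm <- function(lvdd_mm, ivstd_mm, lvpwtd_mm) {
  if (any(!is.finite(lvdd_mm)) || any(lvdd_mm <= 0))
    stop("compute_lvm: LVDd must be finite and positive")
  if (any(!is.finite(ivstd_mm)) || any(ivstd_mm < 0))
    stop("compute_lvm: IVSTd must be finite and non-negative")
  if (any(!is.finite(lvpwtd_mm)) || any(lvpwtd_mm < 0))
    stop("compute_lvm: LVPWTd must be finite and non-negative")
  d <- lvdd_mm / 10
  s <- ivstd_mm / 10
  p <- lvpwtd_mm / 10
  0.8 * 1.04 * ((d + s + p)^3 - d^3) + 0.6
}

#' AWGS-2019 SMI cutoff for a sex label
#'
#' @param sex Character vector of "male"/"female".
#' @return Cutoff in kg/m^2: 7.0 for males, 5.4 for females.
#' @export
awgs_smi_cutoff <- function(sex) {
  bad <- !(sex %in% c("male", "female"))
  if (any(bad)) stop("awgs_smi_cutoff: unknown sex label: ",
                     paste(unique(sex[bad]), collapse = ", "))
  ifelse(sex == "male", 7.0, 5.4)
}

#' Classify low skeletal muscle mass (AWGS 2019)
#'
#' TRUE iff SMI is strictly below the sex-specific cutoff
#' (< 7.0 kg/m^2 male, < 5.4 kg/m^2 female).
#'
#' @param smi SMI in kg/m^2 (>= 0).
#' @param sex "male" or "female"; recycled against `smi`.
#' @return Logical vector.
#' @export
classify_low_smm <- function(smi, sex) {
  if (any(!is.finite(smi)) || any(smi < 0))
    stop("classify_low_smm: SMI must be finite and non-negative")
  smi < awgs_smi_cutoff(sex)
}

#' Append derived columns to a cohort table
#'
#' Adds/overwrites `bmi`, `smi`, `lvm` and `low_smm_flag` computed from the
#' raw anthropometric and echo columns.
#'
#' @param cohort Data frame with columns weight, height, alm, lvdd, ivstd,
#'   lvpwtd, sex.
#' @return The cohort with derived columns appended.
#' @export
add_derived_measures <- function(cohort) {
  need <- c("weight", "height", "alm", "lvdd", "ivstd", "lvpwtd", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("add_derived_measures: missing columns: ", paste(miss, collapse = ", "))
  cohort$bmi <- compute_bmi(cohort$weight, cohort$height)
  cohort$smi <- compute_smi(cohort$alm, cohort$height)
  cohort$lvm <- compute_lvm(cohort$lvdd, cohort$ivstd, cohort$lvpwtd)
  cohort$low_smm_flag <- classify_low_smm(cohort$smi, cohort$sex)
  cohort
}
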