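#' Covariate roster used by all regression stages
#'
#' The 14 subject-level covariates LVM is regressed on, in table order:
#' age, gender (1 = female), the four collinear muscle/body-size measures
#' (SMI, SMM, ALM, BMI) and the eight comorbidity/lifestyle flags.
#'
#' @return Character vector of column names.
#' @export
covariate_roster <- function() {
  c("age", "gender", "smi", "smm", "alm", "bmi",
    "t2dm", "hyperthyroidism", "malignant_tumor", "hypertension",
    "rheumatic", "dyslipidemia", "smoking", "alcohol")
}

#' Generator configuration
#'
#' Builds and validates the configuration of the synthetic-cohort generator.
#' Defaults encode the study conditions the downstream analyses assume:
#' 278 subjects aged 18-91, ~57% female, exactly 80 subjects below the
#' AWGS-2019 SMI cutoffs, a shared latent body-size factor putting the
#' VIF of SMI/SMM/ALM/BMI above 10, and a right-skewed LVM outcome
#' (skew-t regression noise calibrated to sample skewness near 0.92).
#'
#' @param n_subjects Cohort size (>= 10).
#' @param seed Integer seed; the whole cohort is a deterministic function of it.
#' @param age_range Numeric (min, max) in years, within [18, 91].
#' @param female_fraction Proportion of females; the realized count is
#'   `round(n_subjects * female_fraction)`.
#' @param beta_true Named vector of true coefficients (grams of LVM per SD of
#'   predictor) over [covariate_roster()].
#' @param intercept_true True intercept (grams) before skew-t noise.
#' @param alpha_true Skew-t slant of the LVM noise.
#' @param nu_true Skew-t degrees of freedom (> 2).
#' @param sigma_true Skew-t scale (grams).
#' @param collinearity_rho Correlation of SMI/SMM/BMI latent scores with the
#'   shared body-size factor squared (pairwise correlation of scores), in [0, 1).
#' @param comorbidity_prevalences Named vector of Bernoulli prevalences for the
#'   eight flags.
#' @param target_low_smm_count Exact number of subjects below the sex-specific
#'   AWGS cutoff, achieved by a one-off multiplicative calibration of the SMI
#'   distribution.
#' @return A list of class `lvmskew_generator_config`.
#' @export
generator_config <- function(n_subjects = 278L,
                             seed = 20170101L,
                             age_range = c(18, 91),
                             female_fraction = 159 / 278,
                             beta_true = c(
                               age = 4.5, gender = -0.6, smi = 5.5,
                               smm = -8.0, alm = 16.8, bmi = 1.8,
                               t2dm = -3.1, hyperthyroidism = -1.0,
                               malignant_tumor = 1.1, hypertension = -0.8,
                               rheumatic = 2.9, dyslipidemia = 0.6,
                               smoking = -4.0, alcohol = 2.8),
                             intercept_true = 96,
                             alpha_true = 6,
                             nu_true = 8,
                             sigma_true = 40,
                             collinearity_rho = 0.95,
                             comorbidity_prevalences = c(
                               t2dm = 67 / 278, hyperthyroidism = 39 / 278,
                               malignant_tumor = 10 / 278,
                               hypertension = 50 / 278, rheumatic = 11 / 278,
                               dyslipidemia = 28 / 278, smoking = 103 / 278,
                               alcohol = 116 / 278),
                             target_low_smm_count = 80L) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              age_range = as.numeric(age_range),
              female_fraction = female_fraction, beta_true = beta_true,
              intercept_true = intercept_true, alpha_true = alpha_true,
              nu_true = nu_true, sigma_true = sigma_true,
              collinearity_rho = collinearity_rho,
              comorbidity_prevalences = comorbidity_prevalences,
              target_low_smm_count = as.integer(target_low_smm_count))
  validate_generator_config(cfg)
  class(cfg) <- "lvmskew_generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 10)
  if (cfg$age_range[1] < 18 || cfg$age_range[2] > 91 ||
      cfg$age_range[1] >= cfg$age_range[2])
    stop("generator_config: age_range must be an increasing pair within [18, 91]")
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1)
    stop("generator_config: female_fraction must be in [0, 1]")
  if (cfg$nu_true <= 2) stop("generator_config: nu_true must be > 2")
  if (cfg$sigma_true <= 0) stop("generator_config: sigma_true must be > 0")
  if (cfg$collinearity_rho < 0 || cfg$collinearity_rho >= 1)
    stop("generator_config: collinearity_rho must be in [0, 1)")
  if (any(cfg$comorbidity_prevalences < 0 | cfg$comorbidity_prevalences > 1))
    stop("generator_config: comorbidity prevalences must be in [0, 1]")
  flags <- covariate_roster()[7:14]
  if (!all(flags %in% names(cfg$comorbidity_prevalences)))
    stop("generator_config: comorbidity_prevalences must name all eight flags")
  if (!all(covariate_roster() %in% names(cfg$beta_true)))
    stop("generator_config: beta_true must name all 14 covariates")
  if (cfg$target_low_smm_count < 0 || cfg$target_low_smm_count > cfg$n_subjects)
    stop("generator_config: target_low_smm_count must be in [0, n_subjects]")
  invisible(cfg)
}

# Calibrate a multiplicative SMI shift so that exactly `target` subjects fall
# strictly below their sex cutoff. Returns the shifted SMI vector. Fails when
# the shift required would distort the configured SMI distribution by more
# than a factor of exp(0.7) (~2x), i.e. the target is infeasible for it.
calibrate_smi_to_target <- function(smi, sex, target) {
  n <- length(smi)
  margin <- log(awgs_smi_cutoff(sex)) - log(smi) # smi*c < cutoff <=> log(c) < margin
  ms <- sort(margin, decreasing = TRUE)
  if (target == 0) {
    logc <- ms[1] + 0.01
  } else if (target == n) {
    logc <- ms[n] - 0.01
  } else {
    if (ms[target] <= ms[target + 1])
      stop("calibrate_smi_to_target: tied SMI margins make an exact count of ",
           target, " infeasible")
    logc <- (ms[target] + ms[target + 1]) / 2
  }
  if (abs(logc) > 0.7)
    stop("calibrate_smi_to_target: target_low_smm_count = ", target,
         " is infeasible for the configured SMI distribution (would require ",
         "a ", sprintf("%.2f", exp(-logc)), "-fold rescaling)")
  smi * exp(logc)
}

#' Generate a synthetic cohort
#'
#' Deterministically (given `config$seed`) simulates a subject-level cohort
#' with the structure the downstream analyses assume:
#' \itemize{
#'   \item sex assigned to hit `round(n * female_fraction)` females; age
#'     uniform on `age_range`; heights lognormal around sex-specific centres;
#'   \item SMI, SMM and BMI driven by one latent body-size factor at
#'     `collinearity_rho`, ALM defined as SMI x height^2, so the four measures
#'     are severely collinear (VIF > 10 at the default rho);
#'   \item the SMI distribution calibrated multiplicatively so that exactly
#'     `target_low_smm_count` subjects are below the AWGS-2019 cutoffs;
#'   \item LVM generated as intercept + (standardized covariates) %*% beta_true
#'     + skew-t(alpha_true, nu_true, sigma_true) noise, and echo dimensions
#'     (LVDd fixed distribution, wall thicknesses back-solved from the cube
#'     formula) so that recomputing LVM from them reproduces the target
#'     exactly.
#' }
#' Random sub-streams are drawn in a fixed documented order from a single
#' seeded stream, so equal configs give byte-identical tables.
#'
#' @param config A [generator_config()].
#' @return Data frame (one row per subject) with identifiers, demographics,
#'   DXA measures, echo dimensions, comorbidity flags, derived columns
#'   (`bmi`, `smi`, `lvm`, `low_smm_flag`) and a `group` label
#'   ("study" = low SMM, "control" otherwise).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n_subjects
  set.seed(config$seed)

  # stream 1: sex (exact female count, random placement)
  n_f <- round(n * config$female_fraction)
  sex <- rep("male", n)
  sex[sample.int(n, n_f)] <- "female"
  female <- sex == "female"

  # stream 2: age
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  # stream 3: latent body-size factor and measure-specific scores
  rho <- config$collinearity_rho
  u <- stats::rnorm(n)
  s_smi <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
  s_smm <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
  s_bmi <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)

  # stream 4: anthropometrics (lognormal around sex-specific centres)
  height <- exp(ifelse(female, log(158), log(170)) + 0.035 * stats::rnorm(n))
  smi_raw <- exp(ifelse(female, log(5.9), log(7.6)) +
                   ifelse(female, 0.14, 0.13) * s_smi)
  smi <- calibrate_smi_to_target(smi_raw, sex, config$target_low_smm_count)
  alm <- smi * (height / 100)^2
  up_smm <- 0.26 * alm * exp(0.05 * stats::rnorm(n))
  low_smm <- 0.74 * alm * exp(0.05 * stats::rnorm(n))
  smm <- exp(ifelse(female, log(34), log(45)) + 0.16 * s_smm)
  bmi <- exp(log(24.3) + 0.15 * s_bmi)
  weight <- bmi * (height / 100)^2

  # stream 5: comorbidity / lifestyle flags, independent Bernoulli
  prev <- config$comorbidity_prevalences
  flags <- covariate_roster()[7:14]
  flag_mat <- sapply(flags, function(f) stats::rbinom(n, 1L, prev[[f]]))

  # stream 6: LVM from the skew-t regression truth on standardized covariates
  X <- cbind(age = age, gender = as.numeric(female), smi = smi, smm = smm,
             alm = alm, bmi = bmi, flag_mat)
  Xs <- scale(X)
  beta <- config$beta_true[covariate_roster()]
  signal <- config$intercept_true + drop(Xs %*% beta)
  noise <- rskewt(n, config$sigma_true, config$alpha_true, config$nu_true)
  lvm <- signal + noise
  # redraw the (exponentially rare) draws that would give a non-physical LVM
  for (round in 1:100) {
    bad <- which(lvm <= 5)
    if (!length(bad)) break
    lvm[bad] <- signal[bad] +
      rskewt(length(bad), config$sigma_true, config$alpha_true, config$nu_true)
  }
  if (any(lvm <= 5))
    stop("generate_cohort: could not produce positive LVM; check beta_true scale")

  # stream 7: echo dimensions back-solved from the target LVM
  lvdd <- stats::rnorm(n, 45.8, 3.0)
  wall_sum <- 10 * ((lvdd / 10)^3 + (lvm - 0.6) / 0.832)^(1 / 3) - lvdd
  asym <- stats::rnorm(n, 0, 0.15)
  asym <- pmin(pmax(asym, -(wall_sum / 2 - 0.5)), wall_sum / 2 - 0.5)
  ivstd <- wall_sum / 2 + asym
  lvpwtd <- wall_sum / 2 - asym

  # stream 8: fractional shortening
  fs <- stats::rnorm(n, 30.5, 2.5)

  cohort <- data.frame(
    id = sprintf("S%04d", seq_len(n)), age = age, sex = sex,
    height = height, weight = weight, smm = smm, alm = alm,
    up_smm = up_smm, low_smm = low_smm,
    lvdd = lvdd, ivstd = ivstd, lvpwtd = lvpwtd, fs = fs,
    as.data.frame(flag_mat), stringsAsFactors = FALSE)
  cohort <- add_derived_measures(cohort)
  cohort$group <- ifelse(cohort$low_smm_flag, "study", "control")
  cohort
}

#' Blank out fractional-shortening values
#'
#' Marks exactly `n_missing` FS values as missing at positions reproducible
#' from `seed`, emulating unrecorded echo measurements.
#'
#' @param cohort Cohort data frame with an `fs` column.
#' @param n_missing Number of values to blank; must be < nrow(cohort).
#' @param seed Integer seed for the positions.
#' @return The cohort with `fs` set to NA at the chosen rows.
#' @export
inject_missing_fs <- function(cohort, n_missing, seed = 1L) {
  n <- nrow(cohort)
  if (n_missing >= n)
    stop("inject_missing_fs: n_missing must be smaller than the cohort size")
  if (n_missing == 0) return(cohort)
  set.seed(seed)
  cohort$fs[sample.int(n, n_missing)] <- NA_real_
  cohort
}

#' Write a cohort as CSV
#'
#' UTF-8, one header row, missing values as empty fields.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Column dictionary for the cohort CSV
#'
#' @return Named list mapping every column to a short description with units.
#' @export
cohort_data_dictionary <- function() {
  list(
    id = "opaque subject label",
    age = "age, years",
    sex = "male/female",
    height = "standing height, cm",
    weight = "body weight, kg",
    smm = "total skeletal muscle mass (DXA), kg",
    alm = "appendicular lean mass (DXA), kg",
    up_smm = "upper-limb skeletal muscle mass, kg",
    low_smm = "lower-limb skeletal muscle mass, kg",
    lvdd = "LV end-diastolic diameter, mm",
    ivstd = "interventricular septal thickness at end-diastole, mm",
    lvpwtd = "LV posterior wall thickness at end-diastole, mm",
    fs = "fractional shortening, percent (may be missing)",
    t2dm = "type 2 diabetes flag, 0/1",
    hyperthyroidism = "hyperthyroidism flag, 0/1",
    malignant_tumor = "malignant tumour flag, 0/1",
    hypertension = "hypertension flag, 0/1",
    rheumatic = "rheumatic/autoimmune disease flag, 0/1",
    dyslipidemia = "dyslipidemia flag, 0/1",
    smoking = "smoking-history flag, 0/1",
    alcohol = "alcohol-consumption flag, 0/1",
    bmi = "derived body mass index, kg/m^2",
    smi = "derived skeletal muscle index ALM/height^2, kg/m^2",
    lvm = "derived left ventricular mass (cube formula), g",
    low_smm_flag = "TRUE iff SMI below sex-specific AWGS-2019 cutoff",
    group = "study (low SMM) vs control")
}
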