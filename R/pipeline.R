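#' Full run configuration
#'
#' @param input "simulate" (default) or a path to a cohort CSV.
#' @param generator A [generator_config()] (used when `input = "simulate"`).
#' @param ridge_penalty NULL to select by GCV, or a fixed k >= 0.
#' @param bayes_spec A [skew_t_model_spec()].
#' @param n_chains,n_iter Chain settings; `full_scale = TRUE` overrides them
#'   to 32 chains x 20000 iterations.
#' @param lowess_frac,lowess_robust_iters LOWESS settings.
#' @param split_age Age-stratification threshold, years.
#' @param alpha_level Significance level used for normality routing.
#' @param seed Master seed for the Bayesian stage.
#' @param output_dir Directory the stage outputs are written into.
#' @param full_scale Use the full-scale chain settings.
#' @return List of class `lvmskew_run_config`.
#' @export
run_config <- function(input = "simulate", generator = generator_config(),
                       ridge_penalty = NULL,
                       bayes_spec = skew_t_model_spec(),
                       n_chains = 4, n_iter = 2000,
                       lowess_frac = 2 / 3, lowess_robust_iters = 3,
                       split_age = 60, alpha_level = 0.05, seed = 1L,
                       output_dir = "lvmskew-run", full_scale = FALSE) {
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("run_config: alpha_level must be in (0, 1)")
  if (!identical(input, "simulate") && !file.exists(input))
    stop("run_config: input file does not exist: ", input)
  if (full_scale) { n_chains <- 32; n_iter <- 20000 }
  structure(list(input = input, generator = generator,
                 ridge_penalty = ridge_penalty, bayes_spec = bayes_spec,
                 n_chains = n_chains, n_iter = n_iter,
                 lowess_frac = lowess_frac,
                 lowess_robust_iters = lowess_robust_iters,
                 split_age = split_age, alpha_level = alpha_level,
                 seed = as.integer(seed), output_dir = output_dir,
                 full_scale = full_scale),
            class = "lvmskew_run_config")
}

#' Read and validate a cohort CSV
#'
#' Checks mandatory columns, coerces types, recomputes the derived columns,
#' and collects unit-range warnings (height 100-220 cm, echo dimensions
#' 1-80 mm) plus a missingness report.
#'
#' @param path CSV file (UTF-8, header row, empty fields = missing).
#' @return The validated cohort data frame, with attributes
#'   `validation_warnings` (character) and `missingness` (named counts).
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("validate_cohort_csv: file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (nrow(cohort) == 0) stop("validate_cohort_csv: empty cohort file")
  mandatory <- c("age", "sex", "height", "weight", "smm", "alm",
                 "lvdd", "ivstd", "lvpwtd",
                 "t2dm", "hyperthyroidism", "malignant_tumor", "hypertension",
                 "rheumatic", "dyslipidemia", "smoking", "alcohol")
  miss <- setdiff(mandatory, names(cohort))
  if (length(miss))
    stop("validate_cohort_csv: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  warnings <- character(0)
  rng_check <- function(col, lo, hi, unit) {
    bad <- sum(is.finite(cohort[[col]]) & (cohort[[col]] < lo | cohort[[col]] > hi))
    if (bad > 0)
      warnings <<- c(warnings, sprintf(
        "%d %s value(s) outside the plausible range %g-%g %s",
        bad, col, lo, hi, unit))
  }
  rng_check("height", 100, 220, "cm")
  for (ec in c("lvdd", "ivstd", "lvpwtd")) rng_check(ec, 1, 80, "mm")
  cohort <- add_derived_measures(cohort)
  if (!"group" %in% names(cohort))
    cohort$group <- ifelse(cohort$low_smm_flag, "study", "control")
  if (!"fs" %in% names(cohort)) cohort$fs <- NA_real_
  missingness <- vapply(cohort, function(col) sum(is.na(col)), integer(1))
  attr(cohort, "validation_warnings") <- warnings
  attr(cohort, "missingness") <- missingness
  cohort
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate-or-load the cohort; derive clinical measures;
#' two-group comparison table; VIF screening and ridge regression (GCV
#' penalty unless fixed); Bayesian skew-t regression; Gelman-Rubin
#' diagnostics and shrink trajectories; LOWESS trends (overall LVM vs muscle
#' measures, plus age-stratified SMI and LVM). Every stage writes a CSV/JSON
#' under `config$output_dir` and the manifest records seeds, settings and
#' per-file checksums; a rerun with the same config is bit-identical.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "lvmskew_run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$output_dir, "lowess"), showWarnings = FALSE)
  stage <- "synthetic_cohort"
  manifest <- list(seed = config$seed,
                   generator_seed = config$generator$seed,
                   n_chains = config$n_chains, n_iter = config$n_iter,
                   full_scale = config$full_scale, stages = character(0))
  fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    cohort <- if (identical(config$input, "simulate")) {
      generate_cohort(config$generator)
    } else {
      stage <- "derived_measures"
      validate_cohort_csv(config$input)
    }
    write_cohort_csv(cohort, file.path(config$output_dir, "cohort.csv"))
    jsonlite::write_json(cohort_data_dictionary(),
                         file.path(config$output_dir, "data_dictionary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest$stages <- c(manifest$stages, "cohort")

    stage <- "descriptive_stats"
    t1 <- build_table_one(cohort, alpha_level = config$alpha_level)
    t1$statistic <- round(t1$statistic, 2)
    t1$p_value <- signif(t1$p_value, 4)
    write_stage_csv(t1, config$output_dir, "table_one.csv")
    manifest$stages <- c(manifest$stages, "table_one")

    stage <- "ridge_model"
    X <- as.matrix(cbind(cohort[, c("age")],
                         gender = as.numeric(cohort$sex == "female"),
                         cohort[, covariate_roster()[-(1:2)]]))
    colnames(X)[1] <- "age"
    y <- cohort$lvm
    vif <- compute_vif(X)
    write_stage_csv(data.frame(variable = names(vif), vif = unname(vif)),
                    config$output_dir, "vif.csv")
    k <- if (is.null(config$ridge_penalty)) select_penalty(X, y)
         else config$ridge_penalty
    rfit <- fit_ridge(X, y, penalty_k = k)
    rt <- ridge_table(rfit)
    rt[, -1] <- round(rt[, -1], 4)
    write_stage_csv(rt, config$output_dir, "ridge.csv")
    manifest$ridge_penalty <- k
    manifest$ridge_residual_df <- rfit$residual_df
    manifest$stages <- c(manifest$stages, "vif", "ridge")

    stage <- "bayes_skew_model"
    Xs <- scale(X)
    chains <- run_sampler(Xs, y, config$bayes_spec,
                          n_chains = config$n_chains, n_iter = config$n_iter,
                          seed = config$seed)
    post <- summarize_posterior(chains)
    write_stage_csv(post, config$output_dir, "bayes_posterior.csv")
    err <- posterior_fit_error(chains, Xs, y)
    jsonlite::write_json(err, file.path(config$output_dir, "rmse_mae.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$acceptance_rates <- chains$acceptance
    manifest$seed_per_chain <- chains$seed_per_chain
    manifest$stages <- c(manifest$stages, "bayes_posterior", "rmse_mae")

    stage <- "mcmc_diagnostics"
    gr <- gelman_rubin_table(chains)
    gr$rhat <- round(gr$rhat, 3)
    write_stage_csv(gr, config$output_dir, "gelman_rubin.csv")
    traj <- do.call(rbind, lapply(dimnames(chains$draws)[[1]], function(p) {
      tr <- shrink_trajectory(chains, p)
      tr$variable <- p
      tr
    }))
    write_stage_csv(traj, config$output_dir, "shrink_trajectory.csv")
    manifest$stages <- c(manifest$stages, "gelman_rubin")

    stage <- "lowess_trends"
    for (v in c("age", "smi", "smm", "alm")) {
      cu <- lowess_fit(cohort[[v]], cohort$lvm, frac = config$lowess_frac,
                       robust_iters = config$lowess_robust_iters)
      write_stage_csv(lowess_curve_df(cu), file.path(config$output_dir),
                      file.path("lowess", paste0("lvm_vs_", v, ".csv")))
    }
    for (resp in c("smi", "lvm")) {
      st <- stratified_trends(cohort, "age", resp,
                              split_age = config$split_age,
                              frac = config$lowess_frac,
                              robust_iters = config$lowess_robust_iters)
      write_stage_csv(lowess_curve_df(st$younger), config$output_dir,
                      file.path("lowess", paste0(resp, "_vs_age_under", config$split_age, ".csv")))
      write_stage_csv(lowess_curve_df(st$older), config$output_dir,
                      file.path("lowess", paste0(resp, "_vs_age_over", config$split_age, ".csv")))
    }
    manifest$stages <- c(manifest$stages, "lowess")
  }, error = fail)

  files <- list.files(config$output_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", config$output_dir, "/?"), "", names(sums))
  manifest$checksums <- as.list(sums)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
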