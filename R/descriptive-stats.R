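#' Sample skewness (population-moment convention)
#'
#' \eqn{g_1 = m_3 / m_2^{3/2}} with central moments
#' \eqn{m_k = n^{-1}\sum (x_i - \bar x)^k}.
#'
#' @param values Numeric vector, at least 3 finite values with nonzero variance.
#' @return Dimensionless skewness.
#' @export
sample_skewness <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3) stop("sample_skewness: need at least 3 finite values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample_skewness: zero variance")
  mean((x - m)^3) / m2^1.5
}

#' Normality report: Shapiro-Wilk and skewness
#'
#' W statistic and p-value from the Shapiro-Wilk test (AS R94 approximation,
#' via [stats::shapiro.test()]), together with the sample skewness.
#'
#' @param values Numeric vector, 3 <= n <= 5000 after dropping non-finite values.
#' @return List with `skewness`, `sw_statistic`, `sw_p`.
#' @export
shapiro_wilk <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3 || length(x) > 5000)
    stop("shapiro_wilk: sample size must be in [3, 5000]")
  sw <- stats::shapiro.test(x)
  list(skewness = sample_skewness(x),
       sw_statistic = unname(sw$statistic), sw_p = sw$p.value)
}

#' Median imputation
#'
#' Replaces missing entries by the median of the observed entries; observed
#' entries are untouched.
#'
#' @param values Numeric vector possibly containing NA.
#' @return Vector with NAs imputed.
#' @export
median_impute <- function(values) {
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("median_impute: all values missing")
  values[is.na(values)] <- stats::median(obs)
  values
}

#' Two-group comparison of a continuous variable
#'
#' `kind = "t"`: two-sample t test (Welch by default, pooled optional).
#' `kind = "mann_whitney"`: Mann-Whitney U with the large-sample normal
#' approximation z (tie-corrected variance, no continuity correction); when
#' both groups have <= 10 observations and the pooled data are tie-free, the
#' exact two-sided p-value is used instead (the z is still reported).
#'
#' @param x,y Numeric vectors, each with >= 2 observations.
#' @param kind "t" or "mann_whitney".
#' @param pooled_var For `kind = "t"`, use the pooled-variance t test.
#' @return List with `test_kind`, `statistic`, `p_value`, and for the
#'   Mann-Whitney branch `exact` (logical).
#' @export
two_group_compare <- function(x, y, kind = c("t", "mann_whitney"),
                              pooled_var = FALSE) {
  kind <- match.arg(kind)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("two_group_compare: each group needs at least 2 observations")
  if (kind == "t") {
    tt <- stats::t.test(x, y, var.equal = pooled_var)
    return(list(test_kind = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value))
  }
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U for x
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_adj)
  if (v <= 0) stop("two_group_compare: degenerate pooled sample (all ties)")
  z <- (u - mu) / sqrt(v)
  exact <- n1 <= 10 && n2 <= 10 && !any(ties > 1)
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(test_kind = "mann_whitney", statistic = z, p_value = p, exact = exact)
}

#' Pearson chi-square on a 2x2 table, no continuity correction
#'
#' Cells are (a, b) in row 1 and (c, d) in row 2. Equals the closed form
#' \eqn{n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with df = 1.
#'
#' @param a,b,c,d Non-negative counts; all four margins must be nonzero.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(!is.finite(cells)))
    stop("chi_square_2x2: counts must be finite and non-negative")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi_square_2x2: zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Default table-one roster: 25 variables mirroring the printed comparison
# table (Male-/Female-SMI are within-sex subgroup comparisons; the
# age-group split is reported separately by callers that want it).
table_one_roster <- function() {
  list(
    continuous = c("age", "height", "weight", "bmi", "smi", "smm",
                   "up_smm", "low_smm", "alm",
                   "lvdd", "ivstd", "lvpwtd", "fs", "lvm"),
    continuous_by_sex = c(male_smi = "smi", female_smi = "smi"),
    categorical = c("sex", "t2dm", "hyperthyroidism", "malignant_tumor",
                    "hypertension", "rheumatic", "dyslipidemia",
                    "smoking", "alcohol"))
}

summarize_continuous <- function(x, normal) {
  if (normal) sprintf("%.2f +/- %.2f", mean(x), stats::sd(x))
  else sprintf("%.2f (%.2f)", stats::median(x), stats::IQR(x))
}

compare_continuous_row <- function(variable, xs, xc, alpha_level = 0.05) {
  normal <- shapiro_wilk(xs)$sw_p >= alpha_level &&
    shapiro_wilk(xc)$sw_p >= alpha_level
  res <- two_group_compare(xs, xc,
                           kind = if (normal) "t" else "mann_whitney")
  data.frame(variable = variable,
             summary_study = summarize_continuous(xs, normal),
             summary_control = summarize_continuous(xc, normal),
             test_kind = res$test_kind,
             statistic = res$statistic, p_value = res$p_value,
             stringsAsFactors = FALSE)
}

#' Build the two-group comparison table
#'
#' One row per variable in the roster: continuous variables are summarised as
#' mean +/- sd or median (IQR) and routed to a t test or Mann-Whitney U by a
#' per-group Shapiro-Wilk verdict at `alpha_level`; categorical variables get
#' count (%) summaries and a Pearson chi-square without continuity correction.
#' Missing FS values are median-imputed first. Male-SMI / Female-SMI rows
#' compare SMI between groups within each sex.
#'
#' @param cohort Cohort data frame with a `group` column ("study"/"control").
#' @param roster Optional character vector restricting/ordering the variables;
#'   unknown names are an error. Default: the full 25-row roster.
#' @param alpha_level Normality-routing significance level.
#' @return Data frame of comparison rows.
#' @export
build_table_one <- function(cohort, roster = NULL, alpha_level = 0.05) {
  if (!"group" %in% names(cohort))
    stop("build_table_one: cohort must carry a 'group' column")
  full <- table_one_roster()
  known <- c(full$continuous, names(full$continuous_by_sex), full$categorical)
  if (is.null(roster)) roster <- known
  bad <- setdiff(roster, known)
  if (length(bad))
    stop("build_table_one: unknown variable(s): ", paste(bad, collapse = ", "))
  cohort$fs <- median_impute(cohort$fs)
  study <- cohort[cohort$group == "study", , drop = FALSE]
  control <- cohort[cohort$group == "control", , drop = FALSE]

  rows <- lapply(roster, function(v) {
    if (v %in% full$continuous) {
      return(compare_continuous_row(v, study[[v]], control[[v]], alpha_level))
    }
    if (v %in% names(full$continuous_by_sex)) {
      sx <- if (v == "male_smi") "male" else "female"
      return(compare_continuous_row(
        v, study$smi[study$sex == sx], control$smi[control$sex == sx],
        alpha_level))
    }
    # categorical: 2x2 of trait (yes/no) vs group
    yes <- if (v == "sex") cohort$sex == "female" else cohort[[v]] == 1
    a <- sum(yes & cohort$group == "study")
    b <- sum(!yes & cohort$group == "study")
    c_ <- sum(yes & cohort$group == "control")
    d <- sum(!yes & cohort$group == "control")
    res <- chi_square_2x2(a, b, c_, d)
    data.frame(variable = v,
               summary_study = sprintf("%d (%.2f)", a, 100 * a / (a + b)),
               summary_control = sprintf("%d (%.2f)", c_, 100 * c_ / (c_ + d)),
               test_kind = "chi_square",
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
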