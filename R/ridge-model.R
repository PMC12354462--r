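#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors (computed as the diagonal of the inverse correlation matrix,
#' which is the same quantity). Values above 10 flag severe multicollinearity;
#' exact collinearity yields Inf.
#'
#' @param design Numeric matrix or data frame of predictors (n > p, no
#'   constant columns).
#' @return Named numeric vector of VIFs (>= 1 up to rounding).
#' @export
compute_vif <- function(design) {
  X <- as.matrix(design)
  if (nrow(X) <= ncol(X)) stop("compute_vif: need n > p")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("compute_vif: constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  ri <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(ri)) {
    # exact collinearity: report Inf for the offending predictors
    vif <- rep(Inf, ncol(X))
    ev <- eigen(R, symmetric = TRUE)
    ok <- ev$values > 1e-12
    if (any(ok)) {
      Rplus <- ev$vectors[, ok, drop = FALSE] %*%
        diag(1 / ev$values[ok], sum(ok)) %*% t(ev$vectors[, ok, drop = FALSE])
      vif <- diag(Rplus)
      vif[vif > 1e12] <- Inf
    }
    names(vif) <- colnames(X)
    return(vif)
  }
  stats::setNames(diag(ri), colnames(X))
}

#' Ridge regression with sandwich standard errors
#'
#' Fits \eqn{\hat\beta = (X^\top X + kI)^{-1} X^\top y} on internally
#' standardized predictors (zero mean, unit sd) with the response centred and
#' the intercept left unpenalized (reported on the original scale, i.e. the
#' response mean). Coefficient covariance uses the standard ridge sandwich
#' \eqn{\hat\sigma^2 (X^\top X + kI)^{-1} X^\top X (X^\top X + kI)^{-1}} with
#' \eqn{\hat\sigma^2} from the residuals at `residual_df = n - p - 1`;
#' t statistics, two-sided p-values and t-based 95 percent confidence
#' intervals follow.
#'
#' @param design Predictor matrix/data frame (binary covariates as 0/1 are
#'   standardized like continuous ones).
#' @param response Numeric response vector.
#' @param penalty_k Ridge penalty k >= 0. k = 0 requires a nonsingular design.
#' @return List of class `lvmskew_ridge_fit`: `intercept`, `intercept_se`,
#'   `coefficients`, `se`, `t_values`, `p_values`, `ci_low`, `ci_high`,
#'   `penalty_k`, `residual_df`, `rmse`, and the scaling used.
#' @export
fit_ridge <- function(design, response, penalty_k = 0) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("fit_ridge: dimension mismatch")
  if (n <= p + 1) stop("fit_ridge: need n > p + 1")
  if (!is.finite(penalty_k) || penalty_k < 0)
    stop("fit_ridge: penalty_k must be >= 0")
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) stop("fit_ridge: constant column(s) in design")
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y); yc <- y - my

  XtX <- crossprod(Xs)
  A <- XtX + diag(penalty_k, p)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    if (penalty_k == 0)
      stop("fit_ridge: singular X'X at k = 0; use a penalty_k > 0")
    stop("fit_ridge: could not invert penalized normal equations")
  }
  beta <- drop(Ainv %*% crossprod(Xs, yc))
  fitted <- drop(Xs %*% beta)
  resid <- yc - fitted
  residual_df <- n - p - 1
  sigma2 <- sum(resid^2) / residual_df
  covb <- sigma2 * Ainv %*% XtX %*% Ainv
  se <- sqrt(diag(covb))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = residual_df)
  tcrit <- stats::qt(0.975, df = residual_df)
  fit <- list(intercept = my, intercept_se = sqrt(sigma2 / n),
              coefficients = stats::setNames(beta, colnames(X)),
              se = stats::setNames(se, colnames(X)),
              t_values = tval, p_values = pval,
              ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
              penalty_k = penalty_k, residual_df = residual_df,
              rmse = sqrt(mean(resid^2)),
              center = mx, scale = sx, y_mean = my)
  class(fit) <- "lvmskew_ridge_fit"
  fit
}

#' t-based confidence interval from a point estimate and its SE
#'
#' The CI rule used in the ridge table: estimate +/- t_{1-level/2, df} * se.
#'
#' @param estimate,se Point estimate and standard error.
#' @param residual_df Degrees of freedom for the t quantile.
#' @param level Confidence level (default 0.95).
#' @return Numeric c(low, high).
#' @export
ridge_ci <- function(estimate, se, residual_df, level = 0.95) {
  tcrit <- stats::qt(1 - (1 - level) / 2, df = residual_df)
  c(low = estimate - tcrit * se, high = estimate + tcrit * se)
}

#' Select the ridge penalty by generalized cross-validation
#'
#' GCV(k) = n * RSS(k) / (n - edf(k))^2 on the standardized, centred problem,
#' with edf(k) = 1 + sum d_i^2/(d_i^2 + k) (singular values d of the
#' standardized design; the +1 counts the unpenalized intercept). Ties break
#' to the smallest k.
#'
#' @param design,response As in [fit_ridge()].
#' @param grid Non-empty vector of candidate penalties (>= 0).
#' @return The selected k.
#' @export
select_penalty <- function(design, response,
                           grid = c(0, 10^seq(-3, 3, length.out = 25))) {
  if (!length(grid)) stop("select_penalty: empty grid")
  if (any(grid < 0)) stop("select_penalty: penalties must be >= 0")
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(X)
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) stop("select_penalty: constant column(s) in design")
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  yc <- y - mean(y)
  sv <- svd(Xs)
  uty <- crossprod(sv$u, yc)
  gcv <- vapply(grid, function(k) {
    shrink <- sv$d^2 / (sv$d^2 + k)
    fitted <- sv$u %*% (shrink * uty)
    rss <- sum((yc - fitted)^2)
    edf <- 1 + sum(shrink)
    n * rss / (n - edf)^2
  }, numeric(1))
  grid[which.min(gcv)] # which.min takes the first (smallest-k) minimum
}

#' Ridge results as a publication-shaped table
#'
#' One row per predictor plus an intercept row, with beta, SE, t, p and the
#' 95 percent CI (full precision; round for display).
#'
#' @param fit A [fit_ridge()] result.
#' @return Data frame.
#' @export
ridge_table <- function(fit) {
  stopifnot(inherits(fit, "lvmskew_ridge_fit"))
  tcrit <- stats::qt(0.975, df = fit$residual_df)
  data.frame(
    variable = c("const", names(fit$coefficients)),
    beta = c(fit$intercept, unname(fit$coefficients)),
    se = c(fit$intercept_se, unname(fit$se)),
    t = c(fit$intercept / fit$intercept_se, fit$t_values),
    p = c(2 * stats::pt(-abs(fit$intercept / fit$intercept_se),
                        fit$residual_df), fit$p_values),
    ci_low = c(fit$intercept - tcrit * fit$intercept_se, fit$ci_low),
    ci_high = c(fit$intercept + tcrit * fit$intercept_se, fit$ci_high),
    stringsAsFactors = FALSE)
}
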