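#' LOWESS: locally weighted scatterplot smoothing
#'
#' At every observed x value, fits a weighted local linear regression over the
#' `max(2, floor(frac * n))` nearest neighbours (by |x - x0|, stable index
#' tie-break) with tricube weights \eqn{(1 - (d/h)^3)^3} scaled by the
#' farthest neighbour distance h, then applies `robust_iters` rounds of
#' bisquare reweighting on the residuals (weights \eqn{(1 - (r/6m)^2)^2} for
#' |r| < 6m, 0 otherwise, m = median |r|), Cleveland's classic scheme.
#' Local linear fits reproduce straight lines exactly; when the local design
#' is degenerate (all neighbour x equal) the weighted mean is used.
#'
#' @param x,y Numeric vectors (n >= 5, finite x, non-constant x).
#' @param frac Bandwidth fraction in (0, 1]; `frac * n` must be >= 2.
#' @param robust_iters Number of bisquare robustifying passes (>= 0,
#'   default 3).
#' @return List of class `lvmskew_lowess`: sorted `x_grid`, `fitted` values at
#'   the grid, `frac`, `robust_iters`.
#' @export
lowess_fit <- function(x, y, frac = 2 / 3, robust_iters = 3) {
  if (length(x) != length(y)) stop("lowess_fit: x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("lowess_fit: need at least 5 points")
  if (frac <= 0 || frac > 1) stop("lowess_fit: frac must be in (0, 1]")
  q <- max(2, floor(frac * n))
  if (floor(frac * n) < 2) stop("lowess_fit: frac * n must be >= 2")
  if (stats::sd(x) == 0) stop("lowess_fit: constant x")
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  rw <- rep(1, n) # robustness weights

  fit_pass <- function(rw) {
    fitted <- numeric(n)
    for (i in seq_len(n)) {
      d <- abs(xs - xs[i])
      nb <- order(d)[seq_len(q)] # stable tie-break: order() is stable
      h <- max(d[nb])
      w <- if (h > 0) (1 - pmin(d[nb] / h, 1)^3)^3 else rep(1, q)
      w <- w * rw[nb]
      if (sum(w) == 0) { fitted[i] <- ys[i]; next }
      xw <- xs[nb]; yw <- ys[nb]
      sw <- sum(w); xbar <- sum(w * xw) / sw; ybar <- sum(w * yw) / sw
      sxx <- sum(w * (xw - xbar)^2)
      if (sxx > 1e-12 * sw * max(1, xbar^2)) {
        b <- sum(w * (xw - xbar) * (yw - ybar)) / sxx
        fitted[i] <- ybar + b * (xs[i] - xbar)
      } else {
        fitted[i] <- ybar
      }
    }
    fitted
  }

  fitted <- fit_pass(rw)
  iter <- 0
  while (iter < robust_iters) {
    r <- ys - fitted
    s <- 6 * stats::median(abs(r))
    rw <- if (s > 0) pmax(1 - (r / s)^2, 0)^2 else rep(1, n)
    fitted <- fit_pass(rw)
    iter <- iter + 1
  }
  structure(list(x_grid = xs, fitted = fitted, frac = frac,
                 robust_iters = robust_iters),
            class = "lvmskew_lowess")
}

#' Age-stratified LOWESS trends
#'
#' Fits independent LOWESS curves of `response` against `predictor` for the
#' subjects younger than `split_age` and those at or above it.
#'
#' @param cohort Cohort data frame with an `age` column.
#' @param predictor,response Column names.
#' @param split_age Stratification age in years (default 60).
#' @param frac,robust_iters Passed to [lowess_fit()].
#' @return List with `younger` and `older` curves and `n_younger`, `n_older`.
#' @export
stratified_trends <- function(cohort, predictor, response, split_age = 60,
                              frac = 2 / 3, robust_iters = 3) {
  for (v in c("age", predictor, response))
    if (!v %in% names(cohort)) stop("stratified_trends: missing column ", v)
  lower <- cohort[cohort$age < split_age, , drop = FALSE]
  upper <- cohort[cohort$age >= split_age, , drop = FALSE]
  if (nrow(lower) < 5)
    stop("stratified_trends: stratum 'age < ", split_age, "' too small (",
         nrow(lower), " subjects)")
  if (nrow(upper) < 5)
    stop("stratified_trends: stratum 'age >= ", split_age, "' too small (",
         nrow(upper), " subjects)")
  list(younger = lowess_fit(lower[[predictor]], lower[[response]],
                            frac = frac, robust_iters = robust_iters),
       older = lowess_fit(upper[[predictor]], upper[[response]],
                          frac = frac, robust_iters = robust_iters),
       n_younger = nrow(lower), n_older = nrow(upper))
}

#' LOWESS curve as a data frame
#'
#' @param curve A `lvmskew_lowess` object.
#' @return Data frame with `x` and `fitted`.
#' @export
lowess_curve_df <- function(curve) {
  stopifnot(inherits(curve, "lvmskew_lowess"))
  data.frame(x = curve$x_grid, fitted = curve$fitted)
}
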