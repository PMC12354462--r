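#' Azzalini-Capitanio skew-t log-density
#'
#' Log-density of the skew-t distribution with location 0, scale `sigma`,
#' slant `alpha` and `nu` degrees of freedom:
#' \deqn{f(e) = \frac{2}{\sigma}\, t_\nu(z)\,
#'   T_{\nu+1}\!\Big(\alpha z \sqrt{\tfrac{\nu+1}{\nu+z^2}}\Big)},
#' where \eqn{z = e/\sigma}, \eqn{t_\nu} is the Student-t density and
#' \eqn{T_{\nu+1}} its CDF with one extra degree of freedom. `alpha = 0`
#' recovers the scaled Student t; large `nu` recovers the skew normal.
#'
#' @param residual Numeric vector of residuals (location already removed).
#' @param sigma Scale, > 0.
#' @param alpha Slant/skewness shape (real; 0 = symmetric).
#' @param nu Degrees of freedom, > 0.
#' @return Vector of log-densities.
#' @export
skew_t_logpdf <- function(residual, sigma, alpha, nu) {
  if (!is.finite(sigma) || sigma <= 0) stop("skew_t_logpdf: sigma must be > 0")
  if (!is.finite(nu) || nu <= 0) stop("skew_t_logpdf: nu must be > 0")
  z <- residual / sigma
  log(2) + stats::dt(z, df = nu, log = TRUE) - log(sigma) +
    stats::pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), df = nu + 1,
              log.p = TRUE)
}

#' Skew-t random residuals (stochastic representation)
#'
#' Draws from the same skew-t law as [skew_t_logpdf()] via the scale-mixture
#' representation \eqn{e = \sigma \lambda^{-1/2} (\delta |Z_0| +
#' \sqrt{1-\delta^2} Z_1)} with \eqn{\lambda \sim Gamma(\nu/2, \nu/2)},
#' \eqn{Z_0, Z_1} iid standard normal and \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}.
#'
#' @param n Number of draws.
#' @inheritParams skew_t_logpdf
#' @return Numeric vector of length `n`.
#' @export
rskewt <- function(n, sigma, alpha, nu) {
  delta <- alpha / sqrt(1 + alpha^2)
  lambda <- stats::rgamma(n, shape = nu / 2, rate = nu / 2)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  sigma * (delta * z0 + sqrt(1 - delta^2) * z1) / sqrt(lambda)
}

#' Closed-form skew-t moments
#'
#' Mean, variance and (for nu > 3) skewness of the skew-t law of
#' [skew_t_logpdf()]. Used as the analytic oracle for the synthetic-cohort
#' generator's noise and for calibrating its default skewness.
#'
#' @inheritParams skew_t_logpdf
#' @return List with `mean`, `var` (requires nu > 2) and `skewness`
#'   (NA unless nu > 3).
#' @export
skew_t_moments <- function(sigma, alpha, nu) {
  if (nu <= 2) stop("skew_t_moments: nu must be > 2 for a finite variance")
  delta <- alpha / sqrt(1 + alpha^2)
  b <- sqrt(nu / pi) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
  mu <- delta * b
  v <- nu / (nu - 2) - mu^2
  g1 <- NA_real_
  if (nu > 3) {
    g1 <- mu * (nu * (3 - delta^2) / (nu - 3) - 3 * nu / (nu - 2) +
                  2 * mu^2) / v^1.5
  }
  list(mean = sigma * mu, var = sigma^2 * v, skewness = g1)
}
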