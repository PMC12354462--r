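test_that("skew-t log-density: symmetry point, normal limit, normalization", {
  # at residual 0 the skewing factor is exactly 1/2 * 2 for any alpha
  for (a in c(-4, 0, 2, 10)) {
    expect_equal(skew_t_logpdf(0, 1, a, 7), dt(0, 7, log = TRUE))
  }
  expect_equal(skew_t_logpdf(0, 1, 3, 1e6), log(dnorm(0)), tolerance = 1e-4)
  # alpha = 0, huge nu: standard normal within 1e-4 across the bulk
  e <- seq(-5, 5, by = 0.25)
  expect_equal(skew_t_logpdf(e, 1, 0, 1e6), dnorm(e, log = TRUE),
               tolerance = 1e-4)
  # density integrates to 1
  f <- function(u) exp(skew_t_logpdf(u, 2, 3, 5))
  expect_equal(integrate(f, -100, 100, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # scale family: f(e; sigma) = f(e/sigma; 1)/sigma
  expect_equal(skew_t_logpdf(1.7, 2.5, 3, 5),
               skew_t_logpdf(1.7 / 2.5, 1, 3, 5) - log(2.5))
  expect_error(skew_t_logpdf(1, -1, 0, 5), "sigma")
  expect_error(skew_t_logpdf(1, 1, 0, 0), "nu")
})

test_that("marginalizing the augmented Gaussian likelihood recovers the density", {
  # e | z, lambda ~ N(sigma delta z, sigma^2 (1-delta^2)/lambda),
  # z | lambda ~ half-normal(0, 1/lambda), lambda ~ Gamma(nu/2, nu/2);
  # nested quadrature over (z, lambda) must reproduce skew_t_logpdf.
  sigma <- 1.3; alpha <- 2; nu <- 6
  delta <- alpha / sqrt(1 + alpha^2)
  marg <- function(e) {
    outer_f <- function(lam) {
      vapply(lam, function(l) {
        inner <- integrate(function(z)
          dnorm(e, sigma * delta * z, sigma * sqrt((1 - delta^2) / l)) *
            2 * dnorm(z, 0, 1 / sqrt(l)),
          0, Inf, rel.tol = 1e-10)$value
        inner * dgamma(l, nu / 2, rate = nu / 2)
      }, numeric(1))
    }
    integrate(outer_f, 0, Inf, rel.tol = 1e-9)$value
  }
  set.seed(10)
  pts <- c(-3.2, -1, -0.2, 0.4, 1.1, 2.5, 4, runif(3, -2, 2))
  for (e in pts) {
    expect_equal(marg(e), exp(skew_t_logpdf(e, sigma, alpha, nu)),
                 tolerance = 1e-6)
  }
})

test_that("rskewt matches the closed-form moments", {
  set.seed(11)
  x <- rskewt(2e5, 2, 3, 5)
  mo <- skew_t_moments(2, 3, 5)
  expect_equal(mean(x), mo$mean, tolerance = 0.02)
  expect_equal(var(x), mo$var, tolerance = 0.05)
  expect_gt(sample_skewness(x), 1)
  expect_error(skew_t_moments(1, 0, 2), "nu")
})

test_that("with alpha fixed at 0 and huge nu the posterior matches OLS", {
  set.seed(12)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(n)
  ch <- run_sampler(X, y, skew_t_model_spec(alpha_fixed = 0, nu = 1e6),
                    n_chains = 2, n_iter = 1200, seed = 31)
  sm <- summarize_posterior(ch)
  ols <- coef(lm(y ~ X))
  b <- sm[match(c("(Intercept)", "x1", "x2"), sm$variable), ]
  expect_true(all(abs(b$mean - ols) < 2 * b$sd))
  # alpha stays pinned
  expect_equal(sm$sd[sm$variable == "alpha"], 0)
})

test_that("the sampler recovers skew-t truth and covers a null slant", {
  d <- make_skewt_data(400, beta = c(2, -1), sigma = 1, alpha = 3, nu = 5,
                       seed = 13)
  ch <- run_sampler(d$X, d$y, skew_t_model_spec(nu = 5),
                    n_chains = 2, n_iter = 2000, seed = 17)
  sm <- summarize_posterior(ch)
  truth <- c(`(Intercept)` = 0, x1 = 2, x2 = -1, sigma = 1, alpha = 3)
  got <- sm[match(names(truth), sm$variable), ]
  expect_true(all(abs(got$mean - truth) < 3 * got$sd))
  expect_true(all(ch$acceptance > 0.05 & ch$acceptance < 0.8))

  # data simulated without skew: the 95% interval for alpha covers 0
  set.seed(14)
  n <- 300
  X <- cbind(x1 = rnorm(n))
  y <- drop(X %*% 1.5) + rskewt(n, 1, 0, 5)
  ch0 <- run_sampler(X, y, skew_t_model_spec(nu = 5),
                     n_chains = 2, n_iter = 1500, seed = 19)
  a <- summarize_posterior(ch0)
  a <- a[a$variable == "alpha", ]
  expect_lt(a$ci_low, 0)
  expect_gt(a$ci_high, 0)
})

test_that("posterior sd contracts roughly like 1/sqrt(n)", {
  sds <- sapply(c(300, 600), function(n) {
    d <- make_skewt_data(n, beta = c(1.5), sigma = 1, alpha = 3, nu = 5,
                         seed = 100 + n)
    ch <- run_sampler(d$X, d$y, skew_t_model_spec(nu = 5),
                      n_chains = 2, n_iter = 1500, seed = 23)
    sm <- summarize_posterior(ch)
    sm$sd[sm$variable == "x1"]
  })
  ratio <- sds[2] / sds[1]
  expect_gt(ratio, 1 / sqrt(2) * 0.75)
  expect_lt(ratio, 1 / sqrt(2) * 1.35)
})

test_that("posterior means are insensitive to the ridge-prior scale", {
  d <- make_skewt_data(400, beta = c(2, -1), sigma = 1, alpha = 3, nu = 5,
                       seed = 15)
  sums <- lapply(c(1, 10, 100), function(tau)
    summarize_posterior(run_sampler(
      d$X, d$y, skew_t_model_spec(prior_beta = "gaussian", tau = tau, nu = 5),
      n_chains = 2, n_iter = 1500, seed = 29)))
  for (v in c("x1", "x2")) {
    means <- sapply(sums, function(s) s$mean[s$variable == v])
    sds <- sapply(sums, function(s) s$sd[s$variable == v])
    expect_lt(max(means) - min(means), 0.5 * min(sds))
  }
})

test_that("nu grid sampling concentrates away from heavy tails on normal data", {
  set.seed(16)
  n <- 400
  X <- cbind(x1 = rnorm(n))
  y <- drop(X %*% 2) + rnorm(n)
  ch <- run_sampler(X, y, skew_t_model_spec(nu_treatment = "grid",
                                            nu_grid = c(3, 5, 10, 20, 30)),
                    n_chains = 2, n_iter = 1000, seed = 37)
  sm <- summarize_posterior(ch)
  expect_gt(sm$mean[sm$variable == "nu"], 5)
})

test_that("posterior summaries: constants, normal quantiles, chain symmetry", {
  ch <- chain_set(matrix(5, nrow = 200, ncol = 3), burn_in = 0)
  sm <- summarize_posterior(ch)
  expect_equal(sm$mean, 5)
  expect_equal(sm$sd, 0)
  expect_equal(sm$ci_low, 5)
  expect_equal(sm$ci_high, 5)

  set.seed(18)
  big <- matrix(rnorm(1e6), ncol = 2)
  smn <- summarize_posterior(chain_set(big, burn_in = 0))
  expect_equal(smn$ci_low, qnorm(0.025), tolerance = 0.01)
  expect_equal(smn$ci_high, qnorm(0.975), tolerance = 0.01)

  perm <- chain_set(big[, 2:1], burn_in = 0)
  expect_equal(summarize_posterior(perm)[, -1], smn[, -1])

  expect_error(summarize_posterior(chain_set(matrix(1:20, 10, 2),
                                             burn_in = 5)),
               "fewer than 100")
})

test_that("posterior fit error equals the direct RMSE/MAE formulas", {
  set.seed(20)
  n <- 50
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rnorm(n)
  # fake chains whose posterior mean coefficients are known exactly
  b <- c(`(Intercept)` = 0.3, x1 = 1.2, x2 = -0.7)
  draws <- array(NA_real_, c(5, 2, 200),
                 dimnames = list(c(names(b), "sigma", "alpha"),
                                 c("chain1", "chain2"), NULL))
  for (p in seq_along(c(b, 1, 0))) draws[p, , ] <- c(b, 1, 0)[p]
  ch <- chain_set(draws, burn_in = 0)
  err <- posterior_fit_error(ch, X, y)
  resid <- y - (b[1] + drop(X %*% b[-1]))
  expect_equal(err$rmse, sqrt(mean(resid^2)), tolerance = 1e-12)
  expect_equal(err$mae, mean(abs(resid)), tolerance = 1e-12)
  # perfect predictions give zero error
  y2 <- b[1] + drop(X %*% b[-1])
  err2 <- posterior_fit_error(ch, X, y2)
  expect_equal(err2$rmse, 0)
  expect_equal(err2$mae, 0)
  # constant unit residuals: rmse = mae = 1
  err3 <- posterior_fit_error(ch, X, y2 + 1)
  expect_equal(err3$rmse, 1)
  expect_equal(err3$mae, 1)
  expect_error(posterior_fit_error(ch, X[, 1, drop = FALSE], y), "match")
})

test_that("sampler input validation", {
  X <- cbind(x1 = rnorm(30))
  y <- rnorm(30)
  expect_error(run_sampler(X, y, skew_t_model_spec(), n_iter = 100,
                           burn_in = 100), "exceed burn_in")
  expect_error(run_sampler(X, y[1:10], skew_t_model_spec()), "mismatch")
  expect_error(run_sampler(X, y, list()), "skew_t_model_spec")
  expect_error(skew_t_model_spec(nu = 2), "nu must be > 2")
  expect_error(skew_t_model_spec(prior_beta = "gaussian", tau = -1), "tau")
})
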