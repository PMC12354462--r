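# Lower-truncated (at 0) normal draws, vectorised and tail-safe.
# Inverse-CDF in the bulk; Robert's exponential-rejection sampler when the
# truncation point is far in the upper tail of the untruncated normal.
rtnorm_pos <- function(mean, sd) {
  n <- length(mean)
  a <- -mean / sd # standardized lower bound
  x <- numeric(n)
  easy <- a < 5
  if (any(easy)) {
    pt_ <- stats::pnorm(a[easy], lower.tail = FALSE)
    v <- stats::runif(sum(easy)) * pt_
    x[easy] <- stats::qnorm(v, lower.tail = FALSE)
  }
  hard <- which(!easy)
  for (i in hard) {
    ai <- a[i]
    astar <- (ai + sqrt(ai^2 + 4)) / 2
    repeat {
      cand <- ai + stats::rexp(1, astar)
      if (stats::runif(1) <= exp(-(cand - astar)^2 / 2)) { x[i] <- cand; break }
    }
  }
  mean + sd * x
}

#' Skew-t regression model specification
#'
#' Residuals follow the Azzalini-Capitanio skew-t of [skew_t_logpdf()];
#' the regression function is linear in the (externally standardized)
#' predictors.
#'
#' @param prior_beta "flat" (default) or "gaussian"; the latter is the
#'   ridge-type prior N(0, tau^2) on every slope (the intercept is always
#'   flat).
#' @param tau Prior sd for `prior_beta = "gaussian"` (grams per SD).
#' @param prior_sigma c(a0, b0) of the inverse-gamma prior on sigma^2;
#'   the default (0.001, 0.001) is non-informative.
#' @param prior_alpha_sd Gaussian prior sd for the slant alpha (centred at 0);
#'   `Inf` gives a flat prior. Default 100 (effectively non-informative).
#' @param nu Degrees of freedom: a fixed value (> 2; default 4) when
#'   `nu_treatment = "fixed"`, ignored otherwise.
#' @param nu_treatment "fixed" or "grid" (discrete Gibbs over `nu_grid`).
#' @param nu_grid Candidate df values for `nu_treatment = "grid"`.
#' @param alpha_fixed Optionally pin the slant at a known value (e.g. 0 for a
#'   symmetric-t fit); NULL (default) samples it.
#' @return List of class `lvmskew_skewt_spec`.
#' @export
skew_t_model_spec <- function(prior_beta = c("flat", "gaussian"), tau = 10,
                              prior_sigma = c(0.001, 0.001),
                              prior_alpha_sd = 100,
                              nu = 4, nu_treatment = c("fixed", "grid"),
                              nu_grid = 3:30, alpha_fixed = NULL) {
  prior_beta <- match.arg(prior_beta)
  nu_treatment <- match.arg(nu_treatment)
  if (prior_beta == "gaussian" && (!is.finite(tau) || tau <= 0))
    stop("skew_t_model_spec: tau must be > 0 for the gaussian prior")
  if (any(prior_sigma <= 0))
    stop("skew_t_model_spec: inverse-gamma hyperparameters must be > 0")
  if (prior_alpha_sd <= 0)
    stop("skew_t_model_spec: prior_alpha_sd must be > 0")
  if (nu_treatment == "fixed" && nu <= 2)
    stop("skew_t_model_spec: fixed nu must be > 2")
  if (nu_treatment == "grid" && any(nu_grid <= 2))
    stop("skew_t_model_spec: nu_grid values must be > 2")
  structure(list(prior_beta = prior_beta, tau = tau,
                 prior_sigma = prior_sigma, prior_alpha_sd = prior_alpha_sd,
                 nu = nu, nu_treatment = nu_treatment, nu_grid = nu_grid,
                 alpha_fixed = alpha_fixed),
            class = "lvmskew_skewt_spec")
}

# log of the conditional density of (log sigma, alpha) given the augmentation
# latents: Gaussian likelihood of the residuals given (z, lambda) plus the
# inverse-gamma prior on sigma^2 (with the log-scale Jacobian) and the
# Gaussian prior on alpha.
logpost_sigma_alpha <- function(logsig, alpha, e, z, lambda, spec) {
  sigma <- exp(logsig)
  delta <- alpha / sqrt(1 + alpha^2)
  s2 <- sigma^2 * (1 - delta^2)
  ll <- -length(e) / 2 * log(s2) -
    sum(lambda * (e - sigma * delta * z)^2) / (2 * s2)
  a0 <- spec$prior_sigma[1]; b0 <- spec$prior_sigma[2]
  lp <- -2 * a0 * logsig - b0 * exp(-2 * logsig) # IG(a0,b0) on sigma^2 + Jacobian
  if (is.finite(spec$prior_alpha_sd))
    lp <- lp - alpha^2 / (2 * spec$prior_alpha_sd^2)
  ll + lp
}

run_one_chain <- function(X, y, spec, n_iter, burn_in, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  prior_prec <- rep(0, p)
  if (spec$prior_beta == "gaussian") {
    prior_prec <- rep(1 / spec$tau^2, p)
    prior_prec[colnames(X) == "(Intercept)"] <- 0
  }
  # initial state: OLS-ish beta, residual-scale sigma
  beta <- drop(solve(crossprod(X) + diag(1e-8, p), crossprod(X, y)))
  e <- y - drop(X %*% beta)
  sigma <- max(stats::sd(e), 1e-6)
  alpha <- if (is.null(spec$alpha_fixed)) 0.5 else spec$alpha_fixed
  nu <- if (spec$nu_treatment == "fixed") spec$nu else spec$nu_grid[1]
  lambda <- rep(1, n)
  z <- abs(stats::rnorm(n))

  sample_alpha <- is.null(spec$alpha_fixed)
  track_nu <- spec$nu_treatment == "grid"
  par_names <- c(colnames(X), "sigma", "alpha", if (track_nu) "nu")
  draws <- matrix(NA_real_, n_iter, length(par_names),
                  dimnames = list(NULL, par_names))
  step <- c(logsig = 0.1, alpha = 0.25)
  acc <- 0L; acc_window <- 0L
  lp_cur <- logpost_sigma_alpha(log(sigma), alpha, e, z, lambda, spec)

  for (it in seq_len(n_iter)) {
    delta <- alpha / sqrt(1 + alpha^2)
    om2 <- sigma^2 * (1 - delta^2) # conditional residual variance factor

    # z_i | rest ~ TN(delta * e_i / sigma, (1 - delta^2) / lambda_i) on [0, Inf)
    z <- rtnorm_pos(delta * e / sigma, sqrt((1 - delta^2) / lambda))

    # (nu, lambda) | rest as one block: nu from its lambda-marginalized
    # conditional on the grid (the Gamma integral is closed-form), then
    # lambda_i | nu ~ Gamma((nu + 2)/2, (nu + z^2 + (e - sigma delta z)^2/om2)/2)
    r <- e - sigma * delta * z
    s_i <- z^2 + r^2 / om2
    if (track_nu) {
      lw <- vapply(spec$nu_grid, function(v)
        n * (v / 2 * log(v / 2) + lgamma((v + 2) / 2) - lgamma(v / 2)) -
          (v + 2) / 2 * sum(log((v + s_i) / 2)),
        numeric(1))
      lw <- lw - max(lw)
      nu <- spec$nu_grid[sample.int(length(lw), 1, prob = exp(lw))]
    }
    lambda <- stats::rgamma(n, shape = (nu + 2) / 2, rate = (nu + s_i) / 2)

    # beta | rest: Gaussian (weighted LS on the shifted response)
    w <- lambda / om2
    ytil <- y - sigma * delta * z
    P <- crossprod(X * sqrt(w)) + diag(prior_prec, p)
    ch <- tryCatch(chol(P), error = function(err) NULL)
    if (is.null(ch))
      stop("run_sampler: divergent state (singular precision) at iteration ", it)
    m <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w * ytil)))
    beta <- drop(m + backsolve(ch, stats::rnorm(p)))
    e <- y - drop(X %*% beta)

    # (log sigma, alpha) | latents: joint random-walk Metropolis
    lp_cur <- logpost_sigma_alpha(log(sigma), alpha, e, z, lambda, spec)
    prop_logsig <- log(sigma) + step["logsig"] * stats::rnorm(1)
    prop_alpha <- if (sample_alpha) alpha + step["alpha"] * stats::rnorm(1) else alpha
    lp_prop <- logpost_sigma_alpha(prop_logsig, prop_alpha, e, z, lambda, spec)
    if (!is.finite(lp_cur))
      stop("run_sampler: divergent state (non-finite log-posterior) at iteration ", it)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
      sigma <- exp(prop_logsig); alpha <- prop_alpha
      lp_cur <- lp_prop
      acc <- acc + 1L; acc_window <- acc_window + 1L
    }
    # step-size adaptation, burn-in only (frozen afterwards)
    if (it <= burn_in && it %% 50 == 0) {
      rate <- acc_window / 50
      step <- step * exp(0.5 * (rate - 0.3))
      acc_window <- 0L
    }

    draws[it, ] <- c(beta, sigma, alpha, if (track_nu) nu)
  }
  list(draws = draws, acceptance = acc / n_iter, step = step)
}

#' MCMC sampler for the Bayesian skew-t regression
#'
#' Metropolis-within-Gibbs targeting the joint posterior of
#' (beta, sigma, alpha[, nu]) under the scale-mixture augmentation of the
#' skew-t residual law: per observation a Gamma(nu/2, nu/2) mixing scale
#' lambda_i and a half-normal skewness latent z_i, giving conjugate Gaussian
#' beta draws, Gamma lambda draws and truncated-normal z draws;
#' (log sigma, alpha) move by joint random-walk Metropolis with step sizes
#' adapted during burn-in only. Chains are independently seeded from `seed`.
#'
#' @param design Numeric predictor matrix (standardize beforehand for
#'   commensurate coefficients; see [scale()]).
#' @param response Numeric response vector.
#' @param spec A [skew_t_model_spec()].
#' @param n_chains Number of independent chains (>= 1).
#' @param n_iter Iterations per chain.
#' @param seed Integer master seed; chain c uses `seed + c - 1`.
#' @param burn_in Iterations to discard (default `n_iter / 2`); must be
#'   < `n_iter`.
#' @param intercept Add an unpenalized intercept column (default TRUE).
#' @return List of class `lvmskew_chains`: `draws` (parameter x chain x
#'   iteration array), `n_chains`, `n_iter`, `burn_in`, `seed_per_chain`,
#'   `acceptance` (per chain), `spec`.
#' @export
run_sampler <- function(design, response, spec = skew_t_model_spec(),
                        n_chains = 4, n_iter = 2000, seed = 1,
                        burn_in = floor(n_iter / 2), intercept = TRUE) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  y <- as.numeric(response)
  if (nrow(X) != length(y)) stop("run_sampler: dimension mismatch")
  if (nrow(X) <= ncol(X)) stop("run_sampler: need n > p")
  if (!inherits(spec, "lvmskew_skewt_spec"))
    stop("run_sampler: spec must come from skew_t_model_spec()")
  if (burn_in >= n_iter) stop("run_sampler: n_iter must exceed burn_in")
  seeds <- as.integer(seed) + seq_len(n_chains) - 1L
  chains <- lapply(seeds, function(s)
    run_one_chain(X, y, spec, n_iter, burn_in, s))
  par_names <- colnames(chains[[1]]$draws)
  draws <- array(NA_real_, c(length(par_names), n_chains, n_iter),
                 dimnames = list(par_names, paste0("chain", seq_len(n_chains)),
                                 NULL))
  for (c_ in seq_len(n_chains)) draws[, c_, ] <- t(chains[[c_]]$draws)
  structure(list(draws = draws, n_chains = n_chains, n_iter = n_iter,
                 burn_in = burn_in, seed_per_chain = seeds,
                 acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
                 spec = spec),
            class = "lvmskew_chains")
}

#' Assemble a chain set from a draws array
#'
#' Mainly for fixtures and diagnostics on externally produced chains.
#'
#' @param draws Parameter x chain x iteration array (or an iteration x chain
#'   matrix for a single parameter, which is promoted).
#' @param burn_in Burn-in length (< number of iterations).
#' @param parameter Name used when promoting a matrix.
#' @return A `lvmskew_chains` object.
#' @export
chain_set <- function(draws, burn_in = 0, parameter = "theta") {
  if (is.matrix(draws)) {
    a <- array(NA_real_, c(1, ncol(draws), nrow(draws)),
               dimnames = list(parameter, colnames(draws), NULL))
    for (c_ in seq_len(ncol(draws))) a[1, c_, ] <- draws[, c_]
    draws <- a
  }
  stopifnot(length(dim(draws)) == 3)
  if (burn_in >= dim(draws)[3]) stop("chain_set: burn_in must be < n_iter")
  structure(list(draws = draws, n_chains = dim(draws)[2],
                 n_iter = dim(draws)[3], burn_in = burn_in,
                 seed_per_chain = rep(NA_integer_, dim(draws)[2]),
                 acceptance = NULL, spec = NULL),
            class = "lvmskew_chains")
}

# post-burn-in draws for one parameter as an iteration x chain matrix
post_burn <- function(chains, parameter) {
  stopifnot(inherits(chains, "lvmskew_chains"))
  if (!parameter %in% dimnames(chains$draws)[[1]])
    stop("unknown parameter: ", parameter)
  idx <- (chains$burn_in + 1):chains$n_iter
  m <- chains$draws[parameter, , idx, drop = FALSE] # 1 x chains x iters
  matrix(aperm(m, c(3, 2, 1)), nrow = length(idx), ncol = dim(m)[2])
}

#' Posterior summary table
#'
#' Mean, posterior sd and equal-tailed 95 percent credible interval per
#' parameter, pooled across chains after discarding burn-in. Requires at
#' least 100 retained draws per chain.
#'
#' @param chains A `lvmskew_chains` object.
#' @return Data frame with variable, mean, sd, ci_low, ci_high.
#' @export
summarize_posterior <- function(chains) {
  stopifnot(inherits(chains, "lvmskew_chains"))
  kept <- chains$n_iter - chains$burn_in
  if (kept < 100)
    stop("summarize_posterior: fewer than 100 post-burn-in draws per chain")
  pars <- dimnames(chains$draws)[[1]]
  idx <- (chains$burn_in + 1):chains$n_iter
  rows <- lapply(pars, function(p) {
    d <- as.numeric(chains$draws[p, , idx])
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(variable = p, mean = mean(d), sd = stats::sd(d),
               ci_low = q[1], ci_high = q[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In-sample fit error at the posterior mean
#'
#' Predictions use the posterior mean of the regression coefficients
#' (intercept included when the sampler added one).
#'
#' @param chains Output of [run_sampler()].
#' @param design,response The data the model was fitted on (same design as
#'   passed to [run_sampler()], without the intercept column).
#' @return List with `rmse` and `mae` (response units).
#' @export
posterior_fit_error <- function(chains, design, response) {
  sm <- summarize_posterior(chains)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if ("(Intercept)" %in% sm$variable) X <- cbind(`(Intercept)` = 1, X)
  bn <- setdiff(sm$variable, c("sigma", "alpha", "nu"))
  if (!identical(sort(bn), sort(colnames(X))))
    stop("posterior_fit_error: design does not match the sampled coefficients")
  beta <- stats::setNames(sm$mean[match(bn, sm$variable)], bn)[colnames(X)]
  yhat <- drop(X %*% beta)
  if (length(yhat) != length(response))
    stop("posterior_fit_error: dimension mismatch")
  resid <- as.numeric(response) - yhat
  list(rmse = sqrt(mean(resid^2)), mae = mean(abs(resid)))
}
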