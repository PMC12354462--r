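# Small fixtures shared across test files. Everything is generated in code.

# A cohort-shaped data frame whose continuous columns are all exactly normal
# enough to route every two-group comparison to the t test.
make_normal_cohort <- function(n_per_group = 60, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_group
  sex <- rep(c("male", "female"), length.out = n)
  height <- rnorm(n, 165, 6)
  weight <- rnorm(n, 65, 8)
  alm <- rnorm(n, 16, 2)
  df <- data.frame(
    id = sprintf("N%03d", 1:n),
    age = rnorm(n, 50, 10), sex = sex, height = height, weight = weight,
    smm = rnorm(n, 38, 5), alm = alm,
    up_smm = rnorm(n, 4, 0.5), low_smm = rnorm(n, 12, 1.5),
    lvdd = rnorm(n, 46, 3), ivstd = rnorm(n, 9, 1), lvpwtd = rnorm(n, 9, 1),
    fs = rnorm(n, 30, 2),
    t2dm = rbinom(n, 1, 0.3), hyperthyroidism = rbinom(n, 1, 0.3),
    malignant_tumor = rbinom(n, 1, 0.3), hypertension = rbinom(n, 1, 0.3),
    rheumatic = rbinom(n, 1, 0.3), dyslipidemia = rbinom(n, 1, 0.3),
    smoking = rbinom(n, 1, 0.4), alcohol = rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE)
  df <- add_derived_measures(df)
  df$group <- rep(c("study", "control"), each = n_per_group)
  df
}

# Simulated skew-t regression data with known truth.
make_skewt_data <- function(n, beta = c(2, -1), sigma = 1, alpha = 3, nu = 5,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  list(X = X, y = drop(X %*% beta) + rskewt(n, sigma, alpha, nu),
       beta = beta, sigma = sigma, alpha = alpha, nu = nu)
}

# Brute-force per-point weighted-least-squares LOWESS oracle: independent of
# lowess_fit(), uses lm.wfit for each local regression.
lowess_oracle <- function(x, y, frac, robust_iters = 0) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  q <- max(2, floor(frac * n))
  one_pass <- function(rw) {
    sapply(seq_len(n), function(i) {
      d <- abs(xs - xs[i])
      nb <- order(d)[1:q]
      h <- max(d[nb])
      w <- if (h > 0) (1 - pmin(d[nb] / h, 1)^3)^3 else rep(1, q)
      w <- w * rw[nb]
      pos <- w > 0
      f <- lm.wfit(cbind(1, xs[nb][pos]), ys[nb][pos], w[pos])
      cf <- f$coefficients
      if (any(is.na(cf))) cf[is.na(cf)] <- 0
      cf[1] + cf[2] * xs[i]
    })
  }
  rw <- rep(1, n)
  fitted <- one_pass(rw)
  for (k in seq_len(robust_iters)) {
    r <- ys - fitted
    s <- 6 * median(abs(r))
    rw <- if (s > 0) pmax(1 - (r / s)^2, 0)^2 else rep(1, n)
    fitted <- one_pass(rw)
  }
  list(x = xs, fitted = fitted)
}
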