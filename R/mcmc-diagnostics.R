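#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split, non-rank-normalized) estimator on the post-burn-in
#' draws: with m chains of length n, within-chain variance W (mean of the
#' per-chain sample variances) and between-chain variance B = n Var(chain
#' means),
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n\, W + B/n}{W}}.}
#' Values near 1 indicate convergence; a conventional warning is emitted
#' above `warn_above` (the estimate is still returned — on short or
#' unconverged chains the classic estimator can sit well above 1, even
#' around 2). `split = TRUE` computes the split-chain variant (each chain
#' halved before the same formula).
#'
#' @param chains A `lvmskew_chains` object.
#' @param parameter Parameter name.
#' @param split Use split chains (default FALSE, the classic estimator).
#' @param warn_above Warning threshold (default 1.1).
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains, parameter, split = FALSE, warn_above = 1.1) {
  draws <- post_burn(chains, parameter) # iterations x chains
  if (ncol(draws) < 2) stop("gelman_rubin: need at least 2 chains")
  if (split) {
    half <- floor(nrow(draws) / 2)
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[(nrow(draws) - half + 1):nrow(draws), , drop = FALSE])
  }
  n <- nrow(draws)
  if (n < 2) stop("gelman_rubin: need at least 2 post-burn-in draws per chain")
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) stop("gelman_rubin: degenerate chains (zero within-chain variance)")
  B <- n * stats::var(colMeans(draws))
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  if (is.finite(rhat) && rhat > warn_above)
    warning(sprintf("gelman_rubin: R-hat = %.3f for '%s' exceeds %.2f; chains look unconverged",
                    rhat, parameter, warn_above))
  rhat
}

#' R-hat evolution over growing chain prefixes
#'
#' Evaluates the Gelman-Rubin statistic on the first k post-burn-in draws of
#' every chain for each checkpoint k, producing the shrink-factor trajectory
#' used to visualise convergence.
#'
#' @param chains A `lvmskew_chains` object.
#' @param parameter Parameter name.
#' @param checkpoints Increasing integer prefix lengths, each >= 10 and at
#'   most the post-burn-in chain length.
#' @param split Passed to [gelman_rubin()].
#' @return Data frame with `iterations` and `rhat`.
#' @export
shrink_trajectory <- function(chains, parameter,
                              checkpoints = NULL, split = FALSE) {
  draws <- post_burn(chains, parameter)
  n <- nrow(draws)
  if (is.null(checkpoints))
    checkpoints <- unique(round(seq(max(10, n %/% 10), n, length.out = 10)))
  if (any(diff(checkpoints) <= 0))
    stop("shrink_trajectory: checkpoints must be strictly increasing")
  if (any(checkpoints < 10))
    stop("shrink_trajectory: checkpoints must be >= 10")
  if (max(checkpoints) > n)
    stop("shrink_trajectory: checkpoint exceeds post-burn-in chain length (", n, ")")
  rhat <- vapply(checkpoints, function(k) {
    prefix <- chain_set(draws[seq_len(k), , drop = FALSE], burn_in = 0,
                        parameter = parameter)
    suppressWarnings(gelman_rubin(prefix, parameter, split = split))
  }, numeric(1))
  data.frame(iterations = checkpoints, rhat = rhat)
}

#' Gelman-Rubin table for every parameter of a chain set
#'
#' @param chains A `lvmskew_chains` object.
#' @param split Passed to [gelman_rubin()].
#' @return Data frame with `variable` and `rhat`.
#' @export
gelman_rubin_table <- function(chains, split = FALSE) {
  pars <- dimnames(chains$draws)[[1]]
  data.frame(variable = pars,
             rhat = vapply(pars, function(p)
               suppressWarnings(gelman_rubin(chains, p, split = split)),
               numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
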