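#' Probability of direction
#'
#' Share of the posterior lying on the same side of zero as the median
#' response, expressed in percent. Draws exactly equal to zero are split
#' evenly between the two sides, so the result always lies in [50, 100].
#' A PD near 100 indicates high confidence that an effect has a consistent
#' sign; a PD near 50 indicates no directional information.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @return Scalar percentage in [50, 100].
#' @export
p_direction <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 2) stop("at least 2 draws are required")
  n <- length(draws)
  pos <- sum(draws > 0) + 0.5 * sum(draws == 0)
  neg <- n - pos
  100 * max(pos, neg) / n
}

#' Equal-tailed credible interval
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Numeric vector `c(lo, hi)` of percentile bounds.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) == 0) stop("empty draws")
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  a <- (1 - level) / 2
  q <- unname(stats::quantile(as.numeric(draws), c(a, 1 - a), names = FALSE))
  c(lo = q[1], hi = q[2])
}

#' Posterior predictive check with a sum-of-squares discrepancy
#'
#' For each posterior draw, replicate data are simulated from the Normal
#' likelihood at that draw and the discrepancy T = sum((y - mu)^2) is
#' compared between the replicate and the observed data. The reported value
#' is the fraction of draws where the replicate discrepancy exceeds the
#' observed one (exact ties count one half). Values near 0.5 indicate that
#' the observed dispersion around the model mean is typical of the fitted
#' model; values near 0 or 1 indicate mis-fit.
#'
#' This is the low-level engine; use [ppc()] on fitted model objects.
#'
#' @param y Observed response vector (length n).
#' @param mu Matrix of per-draw predicted means, draws x n.
#' @param sigma Vector of per-draw residual standard deviations (length =
#'   number of draws), or a draws x n matrix for observation-specific sds.
#' @param seed Optional integer seed for the replicate simulation.
#' @return Scalar PPC value in [0, 1].
#' @export
ppc_sumsq <- function(y, mu, sigma, seed = NULL) {
  mu <- as.matrix(mu)
  n <- length(y)
  if (ncol(mu) != n) stop("dimensions of `mu` and `y` do not match")
  ndraw <- nrow(mu)
  if (is.matrix(sigma)) {
    if (!all(dim(sigma) == dim(mu))) stop("dimensions of `sigma` mismatch")
    sd_mat <- sigma
  } else {
    if (length(sigma) != ndraw) stop("`sigma` must have one value per draw")
    sd_mat <- matrix(sigma, ndraw, n)
  }
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
  }
  resid_obs <- sweep(mu, 2, y, function(m, yy) yy - m)
  t_obs <- rowSums(resid_obs^2)
  eps <- matrix(rnorm(ndraw * n), ndraw, n) * sd_mat
  t_rep <- rowSums(eps^2)
  mean((t_rep > t_obs) + 0.5 * (t_rep == t_obs))
}

#' Posterior predictive check for a fitted model
#'
#' @param object A fitted `hbm` or `bsem` object.
#' @param ... Passed to methods (`max_draws`, `seed`).
#' @return For `hbm`, a scalar PPC value; for `bsem`, a named vector with one
#'   PPC per endogenous equation and their mean.
#' @seealso [ppc_sumsq()]
#' @export
ppc <- function(object, ...) UseMethod("ppc")

#' Deviance information criterion from posterior draws
#'
#' DIC = Dbar + pD with deviance D(theta) = -2 log L(theta), Dbar the
#' posterior mean deviance and pD = Dbar - D(theta_bar) the effective number
#' of parameters, theta_bar being the posterior mean of the draws.
#'
#' @param object A fitted model object, or (for the default method) a matrix
#'   of draws with one row per draw.
#' @param log_lik For the default method, a function mapping a parameter
#'   vector to the scalar log-likelihood.
#' @param ... Unused.
#' @return List with elements `DIC`, `pD` and `Dbar`.
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @rdname dic
#' @export
dic.default <- function(object, log_lik, ...) {
  draws <- as.matrix(object)
  dev <- apply(draws, 1, function(th) -2 * as.numeric(log_lik(th)))
  dbar <- mean(dev)
  dhat <- -2 * as.numeric(log_lik(colMeans(draws)))
  if (!is.finite(dhat)) stop("deviance is not finite at the posterior mean")
  pd <- dbar - dhat
  list(DIC = dbar + pd, pD = pd, Dbar = dbar)
}
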