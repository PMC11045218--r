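#' Blocked adaptive random-walk Metropolis sampling
#'
#' Runs several independent Markov chains targeting an arbitrary log-posterior
#' supplied as an R function. Parameters are updated in blocks; each block
#' proposal is a spherical Gaussian step whose overall scale and per-parameter
#' direction scales are adapted during burn-in (targeting roughly 20--50\%
#' acceptance) and frozen afterwards, so the retained portion of each chain is
#' a time-homogeneous Markov chain with the correct invariant distribution.
#'
#' @param log_posterior Function evaluating the (unnormalised) log posterior.
#'   Either `function(theta)` returning a scalar, or `function(theta, block)`
#'   where, when `block` is an integer block index, the function may return
#'   only the terms that involve parameters of that block (constant terms may
#'   be dropped; they cancel in the Metropolis ratio). With `block = NULL`
#'   the full log posterior must be returned.
#' @param init Either a numeric vector of length `p` (used, jittered, for all
#'   chains), a matrix with `n_chains` rows, or a `function(chain)` returning
#'   a numeric vector. Chains should be over-dispersed.
#' @param n_chains Number of independent chains (default 3).
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burn Burn-in iterations discarded from inference and used for
#'   proposal adaptation.
#' @param seed Integer seed; per-chain substreams are derived from it and the
#'   same seed reproduces the draws exactly.
#' @param blocks List of integer index vectors partitioning `1:p`; default a
#'   single block containing all parameters.
#' @param par_names Optional character vector of parameter names.
#' @param proposal_sd Optional numeric vector (length `p`) of initial
#'   per-parameter proposal scales (e.g. crude standard errors). These seed
#'   the adaptation; without them every parameter starts at scale 1.
#'
#' @return An object of class `posterior_draws`: a list with `draws` (array
#'   `chain x iteration x parameter`, all iterations), `n_burn`, `seed`,
#'   `acceptance` (chains x blocks acceptance rates over retained iterations),
#'   `par_names` and `blocks`.
#' @export
run_chains <- function(log_posterior, init, n_chains = 3L, n_iter = 10000L,
                       n_burn = 1000L, seed = 1L, blocks = NULL,
                       par_names = NULL, proposal_sd = NULL) {
  stopifnot(n_iter > n_burn, n_chains >= 1L, n_burn >= 1L)
  blockwise <- length(formals(log_posterior)) >= 2L

  lp <- if (blockwise) {
    function(theta, block = NULL) log_posterior(theta, block)
  } else {
    function(theta, block = NULL) log_posterior(theta)
  }

  init_fun <- if (is.function(init)) {
    init
  } else if (is.matrix(init)) {
    function(chain) init[chain, ]
  } else {
    function(chain) init
  }

  p <- length(init_fun(1L))
  if (is.null(blocks)) blocks <- list(seq_len(p))
  idx_all <- sort(unlist(blocks))
  if (!identical(idx_all, seq_len(p)))
    stop("`blocks` must partition the parameter vector")
  n_blocks <- length(blocks)
  if (is.null(par_names)) par_names <- paste0("par", seq_len(p))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)

  draws <- array(NA_real_, dim = c(n_chains, n_iter, p),
                 dimnames = list(NULL, NULL, par_names))
  acceptance <- matrix(0, n_chains, n_blocks)
  adapt_window <- 50L

  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    theta <- as.numeric(init_fun(ch))
    if (length(theta) != p) stop("initial values have inconsistent length")
    lp_full <- lp(theta, NULL)
    if (!is.finite(lp_full))
      stop("log_posterior is not finite at the initial value (chain ", ch, ")")

    scale <- vapply(blocks, function(b) 2.38 / sqrt(length(b)), 0)
    dir_sd <- if (is.null(proposal_sd)) rep(1, p) else
      pmax(as.numeric(proposal_sd), 1e-8)
    if (length(dir_sd) != p) stop("`proposal_sd` must have length p")
    win_acc <- integer(n_blocks)
    post_acc <- integer(n_blocks)
    burn_acc_total <- 0L

    for (it in seq_len(n_iter)) {
      adapting <- it <= n_burn
      for (b in seq_len(n_blocks)) {
        ix <- blocks[[b]]
        prop <- theta
        prop[ix] <- theta[ix] + scale[b] * dir_sd[ix] * rnorm(length(ix))
        lp_cur <- lp(theta, b)
        lp_new <- lp(prop, b)
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp_cur) {
          theta <- prop
          win_acc[b] <- win_acc[b] + 1L
          if (adapting) burn_acc_total <- burn_acc_total + 1L else
            post_acc[b] <- post_acc[b] + 1L
        } else if (!adapting) {
          # nothing; rejection
        }
      }
      draws[ch, it, ] <- theta

      if (adapting && it %% adapt_window == 0L) {
        rate <- win_acc / adapt_window
        scale <- scale * ifelse(rate < 0.15, 0.5,
                         ifelse(rate < 0.20, 0.8,
                         ifelse(rate > 0.60, 2.0,
                         ifelse(rate > 0.50, 1.25, 1.0))))
        win_acc[] <- 0L
        if (it >= 2L * adapt_window) {
          s <- apply(draws[ch, seq_len(it), , drop = FALSE], 3, stats::sd)
          live <- is.finite(s) & s > 1e-10
          dir_sd[live] <- s[live]
        }
      }
    }
    if (burn_acc_total == 0L)
      stop("no proposal was accepted during the entire burn-in (chain ", ch,
           "); the model is likely mis-scaled")
    acceptance[ch, ] <- post_acc / (n_iter - n_burn)
  }

  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  structure(list(draws = draws, n_burn = as.integer(n_burn),
                 seed = as.integer(seed), acceptance = acceptance,
                 par_names = par_names, blocks = blocks),
            class = "posterior_draws")
}

#' Retained (post burn-in) draws as a matrix
#'
#' @param x A `posterior_draws` object.
#' @return Numeric matrix with one column per parameter; chains stacked.
#' @export
retained_draws <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- x$draws[, -seq_len(x$n_burn), , drop = FALSE]
  m <- matrix(aperm(d, c(2, 1, 3)), ncol = dim(d)[3])
  colnames(m) <- x$par_names
  m
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior draws:", d[1], "chains x", d[2], "iterations x", d[3],
      "parameters\n")
  cat("Burn-in:", x$n_burn, " Seed:", x$seed, "\n")
  cat("Mean post-burn-in acceptance:",
      sprintf("%.2f", mean(x$acceptance)), "\n")
  invisible(x)
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain's retained draws are split in half and the classical
#' between/within variance ratio is computed over the resulting sequences.
#' Values near 1 indicate convergence; the conventional acceptance threshold
#' in this package's models is 1.1. A parameter with zero total variance
#' returns 1 by convention.
#'
#' @param x A `posterior_draws` object (at least 2 chains) or a numeric
#'   matrix/array shaped `chain x iteration x parameter`.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "posterior_draws")) {
    d <- x$draws[, -seq_len(x$n_burn), , drop = FALSE]
  } else {
    d <- x
    if (length(dim(d)) != 3) stop("expected a chain x iteration x parameter array")
  }
  n_chain <- dim(d)[1]
  if (n_chain < 2) stop("at least 2 chains are required for R-hat")
  n_it <- dim(d)[2]
  if (n_it < 10) stop("at least 10 retained iterations are required")
  half <- n_it %/% 2L
  p <- dim(d)[3]
  out <- numeric(p)
  for (j in seq_len(p)) {
    seqs <- vector("list", 2L * n_chain)
    for (ch in seq_len(n_chain)) {
      seqs[[2 * ch - 1]] <- d[ch, seq_len(half), j]
      seqs[[2 * ch]] <- d[ch, (half + 1L):(2L * half), j]
    }
    mns <- vapply(seqs, mean, 0)
    vrs <- vapply(seqs, stats::var, 0)
    W <- mean(vrs)
    B_n <- stats::var(mns)             # = B/n in the classical notation
    if (!is.finite(W) || (W < 1e-300 && B_n < 1e-300)) { out[j] <- 1; next }
    if (W < 1e-300) { out[j] <- Inf; next }
    out[j] <- sqrt(((half - 1) / half) * W / W + B_n / W)
  }
  names(out) <- dimnames(d)[[3]] %||% paste0("par", seq_len(p))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
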