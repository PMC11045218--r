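#' Hierarchical Bayesian models for herbivory, insect richness and
#' plant-level responses
#'
#' Fits the package's central model
#' \deqn{y_i = \alpha_{s(i)} + \sum_X \beta^X_{s(i)} X_i + \varepsilon_i,
#'       \quad \varepsilon_i \sim N(0, \sigma_{s(i)}^2)}
#' where `s(i)` is the site of observation `i`. Under `scope =
#' "cross_site"` the site intercepts and slopes are drawn from cross-site
#' hyperdistributions \eqn{\alpha_s \sim N(\mu_\alpha, \tau_\alpha^2)},
#' \eqn{\beta^X_s \sim N(\mu_X, \tau_X^2)} — the Bayesian analogue of a
#' random-effects model with site as the random factor. Under `scope =
#' "single_site"` the hyperprior becomes the direct prior on the (single
#' site's) coefficients. Priors are weakly informative on a 0--100 response
#' scale: Normal(0, sd 100) for location parameters and half-Cauchy(scale 5)
#' for all standard deviations.
#'
#' Sampling uses the blocked adaptive random-walk Metropolis engine
#' ([run_chains()]): one block per site plus one hyperparameter block.
#'
#' @param data A `piper_data` object ([as_piper_data()], [read_experiment()],
#'   [simulate_experiment()]).
#' @param response One of `"leaf_herbivory"`, `"leaf_insect_richness"`
#'   (leaf level), `"plant_pct_damaged"`, `"plant_herbivory_variance"`
#'   (plant level).
#' @param covariates Subset of `c("W", "A", "S", "R")`: water addition (0/1),
#'   high intraspecific richness (0/1), standardized realized interspecific
#'   richness (proportion of the site pool), and — for the herbivory response
#'   only — the leaf's insect damage richness (per-taxon effect).
#' @param interactions Optional subset of `c("W:A", "W:S")`. When present
#'   the sampler defaults to 20000 iterations with 5000 burn-in.
#' @param scope `"cross_site"` (site hierarchy; requires >= 2 sites) or
#'   `"single_site"`.
#' @param site Site name, required for `scope = "single_site"`.
#' @param n_chains,n_iter,n_burn,seed Passed to [run_chains()]; `n_iter` and
#'   `n_burn` default to 10000/1000 (20000/5000 with interactions).
#' @return An object of class `hbm` with methods `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate`, `plot`, plus [ppc()], [dic()],
#'   [summarize_effect()] and [interaction_contrast()].
#' @export
hbm <- function(data, response, covariates = c("A", "S"),
                interactions = NULL,
                scope = c("cross_site", "single_site"), site = NULL,
                n_chains = 3L, n_iter = NULL, n_burn = NULL, seed = 1L) {
  scope <- match.arg(scope)
  fr <- hbm_frame(data, response, covariates, interactions, scope, site)
  if (is.null(n_iter)) n_iter <- if (length(interactions)) 20000L else 10000L
  if (is.null(n_burn)) n_burn <- if (length(interactions)) 5000L else 1000L

  mdl <- if (scope == "cross_site") build_cross_site(fr) else build_single_site(fr)
  draws <- run_chains(mdl$log_post, mdl$init, n_chains = n_chains,
                      n_iter = n_iter, n_burn = n_burn, seed = seed,
                      blocks = mdl$blocks, par_names = mdl$par_names,
                      proposal_sd = mdl$proposal_sd)
  rhat <- tryCatch(gelman_rubin(draws), error = function(e) NULL)
  structure(list(draws = draws, spec = list(response = response,
                                            covariates = covariates,
                                            interactions = interactions,
                                            scope = scope),
                 frame = fr, log_lik = mdl$log_lik, rhat = rhat,
                 call = match.call()),
            class = "hbm")
}

# ---- model frame -----------------------------------------------------------

hbm_frame <- function(data, response, covariates, interactions, scope, site) {
  stopifnot(inherits(data, "piper_data"))
  responses <- c("leaf_herbivory", "leaf_insect_richness",
                 "plant_pct_damaged", "plant_herbivory_variance")
  response <- match.arg(response, responses)
  bad <- setdiff(covariates, c("W", "A", "S", "R"))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  if ("R" %in% covariates && response != "leaf_herbivory")
    stop("the insect-richness covariate R is only defined for leaf_herbivory")
  interactions <- interactions %||% character()
  bad <- setdiff(interactions, c("W:A", "W:S"))
  if (length(bad)) stop("unknown interaction(s): ", paste(bad, collapse = ", "))
  if (length(interactions) && !("W" %in% covariates))
    stop("interactions require the water covariate W")

  plots <- data$plots
  if (response %in% c("leaf_herbivory", "leaf_insect_richness")) {
    obs <- data$leaf
    obs$y <- if (response == "leaf_herbivory") obs$y_H else obs$y_R
    obs$R <- obs$y_R
  } else {
    obs <- data$plant_summary
    obs$y <- if (response == "plant_pct_damaged") obs$pct_leaves_damaged
             else obs$herbivory_variance
    if (response == "plant_herbivory_variance")
      obs <- obs[!obs$flagged & !is.na(obs$y), , drop = FALSE]
  }
  m <- match(obs$plot_id, plots$plot_id)
  obs$W <- plots$water[m]
  obs$A <- plots$intra_high[m]
  obs$S <- plots$S[m]
  obs <- obs[!plots$excluded[m], , drop = FALSE]

  if ("W" %in% covariates) {
    water_sites <- unique(plots$site[!is.na(plots$water)])
    obs <- obs[obs$site %in% water_sites, , drop = FALSE]
    if (nrow(obs) == 0) stop("no site carries the water treatment")
  } else obs$W <- ifelse(is.na(obs$W), 0L, obs$W)

  if (scope == "single_site") {
    if (is.null(site)) stop("`site` is required for single_site scope")
    if (!site %in% obs$site) stop("site not present in data: ", site)
    obs <- obs[obs$site == site, , drop = FALSE]
  }
  sites <- sort(unique(obs$site))
  if (scope == "cross_site" && length(sites) < 2)
    stop("cross_site scope requires at least 2 sites")

  # high mortality can empty water x intraspecific cells; such sites cannot
  # support the W:A interaction for non-survival responses
  if ("W:A" %in% interactions) {
    ok <- vapply(sites, function(s) {
      tb <- table(obs$W[obs$site == s], obs$A[obs$site == s])
      all(dim(tb) == c(2, 2)) && all(tb > 0)
    }, TRUE)
    if (!all(ok)) {
      if (scope == "single_site" || sum(ok) < 2)
        stop("water x intraspecific cells are empty at site(s): ",
             paste(sites[!ok], collapse = ", "),
             "; the W:A interaction cannot be modeled there")
      warning("dropping site(s) without full water x intraspecific cells: ",
              paste(sites[!ok], collapse = ", "))
      obs <- obs[obs$site %in% sites[ok], , drop = FALSE]
      sites <- sites[ok]
    }
  }

  if (length(unique(obs$y)) < 2) stop("response is constant (degenerate)")
  slopes <- c(covariates,
              sub("W:", "W", interactions, fixed = TRUE))  # WA, WS
  X_cols <- function(d) {
    cols <- list(intercept = rep(1, nrow(d)))
    for (cv in covariates) cols[[cv]] <- d[[cv]]
    if ("W:A" %in% interactions) cols$WA <- d$W * d$A
    if ("W:S" %in% interactions) cols$WS <- d$W * d$S
    do.call(cbind, cols)
  }
  X_s <- lapply(sites, function(s) X_cols(obs[obs$site == s, , drop = FALSE]))
  y_s <- lapply(sites, function(s) obs$y[obs$site == s])
  names(X_s) <- names(y_s) <- sites
  for (s in sites) {
    sds <- apply(X_s[[s]][, -1, drop = FALSE], 2, stats::sd)
    if (any(sds == 0))
      stop("covariate constant within site ", s, ": ",
           paste(colnames(X_s[[s]])[-1][sds == 0], collapse = ", "),
           " (unidentifiable)")
  }
  list(obs = obs, sites = sites, X_s = X_s, y_s = y_s,
       slope_names = colnames(X_s[[1]])[-1])
}

# least-squares starting values and crude scales used to seed the sampler
ols_start <- function(X, y) {
  f <- stats::lm.fit(X, y)
  co <- f$coefficients
  co[!is.finite(co)] <- 0
  sd_r <- stats::sd(f$residuals)
  if (!is.finite(sd_r) || sd_r <= 0) sd_r <- 1
  se <- tryCatch(sd_r * sqrt(diag(chol2inv(chol(crossprod(X))))),
                 error = function(e) rep(0.5, ncol(X)))
  se[!is.finite(se) | se <= 0] <- 0.5
  list(coef = co, log_sd = log(sd_r), se = se,
       log_sd_se = max(1 / sqrt(2 * length(y)), 0.02))
}

# paste0 pads zero-length inputs to ""; these keep empty slope sets empty
prefix_names <- function(prefix, nms) {
  if (length(nms)) paste0(prefix, nms) else character(0)
}
beta_names <- function(nms) prefix_names("beta_", nms)

# half-Cauchy(scale 5) log-density for sd parameters sampled on the log scale
# (includes the log Jacobian)
lp_half_cauchy_log <- function(log_s, scale = 5) {
  s <- exp(log_s)
  log(2 / (pi * scale)) - log1p((s / scale)^2) + log_s
}

site_loglik <- function(X, y, th_coef, log_sigma) {
  r <- y - as.vector(X %*% th_coef)
  n <- length(y)
  -0.5 * n * log(2 * pi) - n * log_sigma - sum(r * r) / (2 * exp(2 * log_sigma))
}

# ---- cross-site model ------------------------------------------------------

build_cross_site <- function(fr) {
  sites <- fr$sites
  S <- length(sites)
  k1 <- 1L + length(fr$slope_names)           # intercept + slopes
  coef_names <- c("alpha", beta_names(fr$slope_names))
  site_block_len <- k1 + 1L                   # + log_sigma
  par_names <- character()
  for (s in sites)
    par_names <- c(par_names, paste0(coef_names, "[", s, "]"),
                   paste0("log_sigma[", s, "]"))
  hyper_names <- c("mu_alpha", prefix_names("mu_", fr$slope_names),
                   "log_tau_alpha", prefix_names("log_tau_", fr$slope_names))
  par_names <- c(par_names, hyper_names)
  p <- length(par_names)
  site_ix <- lapply(seq_len(S), function(i)
    ((i - 1L) * site_block_len + 1L):(i * site_block_len))
  hyper_ix <- (S * site_block_len + 1L):p
  mu_ix <- hyper_ix[seq_len(k1)]
  tau_ix <- hyper_ix[k1 + seq_len(k1)]
  # mu and tau blocks are updated separately: the scale parameters sit in a
  # funnel-shaped conditional and mix better on their own
  hyper_blocks <- list(mu_ix, tau_ix)

  X_s <- fr$X_s; y_s <- fr$y_s

  site_term <- function(theta, i) {
    ix <- site_ix[[i]]
    th <- theta[ix]
    coefs <- th[seq_len(k1)]
    ls <- th[k1 + 1L]
    mu <- theta[mu_ix]; tau <- exp(theta[tau_ix])
    site_loglik(X_s[[i]], y_s[[i]], coefs, ls) +
      sum(stats::dnorm(coefs, mu, tau, log = TRUE)) +
      lp_half_cauchy_log(ls)
  }
  hyper_term <- function(theta) {
    mu <- theta[mu_ix]; log_tau <- theta[tau_ix]; tau <- exp(log_tau)
    s <- 0
    for (i in seq_len(S)) {
      coefs <- theta[site_ix[[i]]][seq_len(k1)]
      s <- s + sum(stats::dnorm(coefs, mu, tau, log = TRUE))
    }
    s + sum(stats::dnorm(mu, 0, 100, log = TRUE)) +
      sum(lp_half_cauchy_log(log_tau))
  }
  log_post <- function(theta, block = NULL) {
    if (is.null(block)) {
      tot <- hyper_term(theta)
      for (i in seq_len(S)) {
        ix <- site_ix[[i]]
        th <- theta[ix]
        tot <- tot + site_loglik(X_s[[i]], y_s[[i]], th[seq_len(k1)],
                                 th[k1 + 1L]) +
          lp_half_cauchy_log(th[k1 + 1L])
      }
      tot
    } else if (block <= S) site_term(theta, block) else hyper_term(theta)
  }
  # both hyper blocks share the same conditional terms; separate proposals

  log_lik <- function(theta) {
    tot <- 0
    for (i in seq_len(S)) {
      th <- theta[site_ix[[i]]]
      tot <- tot + site_loglik(X_s[[i]], y_s[[i]], th[seq_len(k1)], th[k1 + 1L])
    }
    tot
  }

  est <- lapply(seq_len(S), function(i) ols_start(X_s[[i]], y_s[[i]]))
  co_mat <- do.call(rbind, lapply(est, `[[`, "coef"))
  mu0 <- colMeans(co_mat)
  tau0 <- pmax(apply(co_mat, 2, stats::sd), 0.2)
  base <- c(unlist(lapply(est, function(e) c(e$coef, e$log_sd))),
            mu0, log(tau0))
  prop_sd <- c(unlist(lapply(est, function(e) c(e$se, e$log_sd_se))),
               pmax(tau0 / sqrt(S), 0.1), rep(0.5, k1))
  jit <- pmax(abs(base) * 0.25, 0.25)
  init <- function(chain) base + stats::rnorm(p) * jit

  list(log_post = log_post, log_lik = log_lik, init = init,
       blocks = c(site_ix, hyper_blocks), par_names = par_names,
       proposal_sd = prop_sd)
}

# ---- single-site model -----------------------------------------------------

build_single_site <- function(fr) {
  X <- fr$X_s[[1]]; y <- fr$y_s[[1]]
  k1 <- ncol(X)
  par_names <- c("alpha", beta_names(fr$slope_names), "log_sigma")
  p <- k1 + 1L
  log_post <- function(theta, block = NULL) {
    coefs <- theta[seq_len(k1)]; ls <- theta[k1 + 1L]
    site_loglik(X, y, coefs, ls) +
      sum(stats::dnorm(coefs, 0, 100, log = TRUE)) +
      lp_half_cauchy_log(ls)
  }
  log_lik <- function(theta)
    site_loglik(X, y, theta[seq_len(k1)], theta[k1 + 1L])
  est <- ols_start(X, y)
  base <- c(est$coef, est$log_sd)
  jit <- pmax(abs(base) * 0.25, 0.25)
  init <- function(chain) base + stats::rnorm(p) * jit
  list(log_post = log_post, log_lik = log_lik, init = init,
       blocks = list(seq_len(p)), par_names = par_names,
       proposal_sd = c(est$se, est$log_sd_se))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.hbm <- function(x, ...) {
  cat("Hierarchical Bayesian model (", x$spec$scope, ")\n", sep = "")
  cat("Response:", x$spec$response, "  Covariates:",
      paste(x$spec$covariates, collapse = ", "), "\n")
  if (length(x$spec$interactions))
    cat("Interactions:", paste(x$spec$interactions, collapse = ", "), "\n")
  cat("Sites:", paste(x$frame$sites, collapse = ", "), " n =",
      nrow(x$frame$obs), "\n")
  if (!is.null(x$rhat))
    cat("Max split R-hat:", sprintf("%.3f", max(x$rhat)), "\n")
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object A fitted `hbm` (or `bsem`) object.
#' @param ... Unused.
#' @return Data.frame with one row per parameter: posterior median, mean,
#'   equal-tailed 95\% interval, probability of direction and split R-hat.
#'   Standard-deviation parameters sampled on the log scale are reported on
#'   the natural scale.
#' @export
summary.hbm <- function(object, ...) {
  draws_summary(object$draws, object$rhat)
}

draws_summary <- function(pd, rhat = NULL) {
  m <- retained_draws(pd)
  nm <- colnames(m)
  is_log <- grepl("^log_", nm)
  m[, is_log] <- exp(m[, is_log])
  nm[is_log] <- sub("^log_", "", nm[is_log])
  out <- data.frame(
    parameter = nm,
    median = apply(m, 2, stats::median),
    mean = colMeans(m),
    lo95 = apply(m, 2, function(v) credible_interval(v)[1]),
    hi95 = apply(m, 2, function(v) credible_interval(v)[2]),
    pd = apply(m, 2, p_direction),
    stringsAsFactors = FALSE)
  out$rhat <- if (!is.null(rhat)) unname(rhat) else NA_real_
  rownames(out) <- NULL
  out
}

#' @export
coef.hbm <- function(object, ...) {
  m <- retained_draws(object$draws)
  stats::setNames(apply(m, 2, stats::median), colnames(m))
}

# posterior-median site coefficients as a matrix sites x (intercept, slopes)
site_coef_medians <- function(object) {
  co <- coef.hbm(object)
  k1 <- 1L + length(object$frame$slope_names)
  cn <- c("alpha", beta_names(object$frame$slope_names))
  if (object$spec$scope == "single_site") {
    m <- matrix(co[cn], 1, k1, dimnames = list(object$frame$sites, cn))
  } else {
    m <- t(vapply(object$frame$sites, function(s)
      co[paste0(cn, "[", s, "]")], numeric(k1)))
    dimnames(m) <- list(object$frame$sites, cn)
  }
  m
}

#' @export
predict.hbm <- function(object, newdata = NULL, ...) {
  cm <- site_coef_medians(object)
  if (is.null(newdata)) {
    fit <- numeric(nrow(object$frame$obs))
    pos <- 1L
    for (s in object$frame$sites) {
      X <- object$frame$X_s[[s]]
      idx <- which(object$frame$obs$site == s)
      fit[idx] <- as.vector(X %*% cm[s, ])
    }
    return(fit)
  }
  need <- c("site", object$frame$slope_names)
  miss <- setdiff(setdiff(need, c("WA", "WS")), names(newdata))
  if (length(miss)) stop("newdata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if ("WA" %in% object$frame$slope_names) newdata$WA <- newdata$W * newdata$A
  if ("WS" %in% object$frame$slope_names) newdata$WS <- newdata$W * newdata$S
  X <- cbind(1, as.matrix(newdata[object$frame$slope_names]))
  rowSums(X * cm[newdata$site, , drop = FALSE])
}

#' @export
residuals.hbm <- function(object, ...) {
  object$frame$obs$y - predict.hbm(object)
}

#' @export
simulate.hbm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- retained_draws(object$draws)
  pick <- sample.int(nrow(m), nsim, replace = nsim > nrow(m))
  obs <- object$frame$obs
  out <- matrix(NA_real_, nrow(obs), nsim)
  for (j in seq_len(nsim)) {
    th <- m[pick[j], ]
    for (s in object$frame$sites) {
      idx <- which(obs$site == s)
      pars <- hbm_site_pars(object, th, s)
      mu <- as.vector(object$frame$X_s[[s]] %*% pars$coefs)
      out[idx, j] <- stats::rnorm(length(idx), mu, pars$sigma)
    }
  }
  out
}

hbm_site_pars <- function(object, th, s) {
  cn <- c("alpha", beta_names(object$frame$slope_names))
  if (object$spec$scope == "single_site") {
    list(coefs = th[cn], sigma = exp(th["log_sigma"]))
  } else {
    list(coefs = th[paste0(cn, "[", s, "]")],
         sigma = exp(th[paste0("log_sigma[", s, "]")]))
  }
}

#' @export
plot.hbm <- function(x, parameters = NULL, ...) {
  d <- x$draws$draws
  nm <- x$draws$par_names
  if (is.null(parameters))
    parameters <- utils::head(grep("^mu_|^alpha$|^beta_",
                                   nm, value = TRUE), 4)
  old <- graphics::par(mfrow = c(length(parameters), 1),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in parameters) {
    j <- match(p, nm)
    graphics::matplot(t(d[, , j]), type = "l", lty = 1, ylab = p,
                      xlab = "iteration", main = NULL)
    graphics::abline(v = x$draws$n_burn, lty = 2)
  }
  invisible(x)
}

#' @rdname ppc
#' @param max_draws Maximum number of posterior draws used (thinned evenly).
#' @param seed Seed for the replicate simulation.
#' @export
ppc.hbm <- function(object, max_draws = 500, seed = 1, ...) {
  m <- retained_draws(object$draws)
  keep <- unique(round(seq(1, nrow(m), length.out = min(max_draws, nrow(m)))))
  m <- m[keep, , drop = FALSE]
  obs <- object$frame$obs
  n <- nrow(obs)
  mu <- matrix(NA_real_, nrow(m), n)
  sd_mat <- matrix(NA_real_, nrow(m), n)
  for (s in object$frame$sites) {
    idx <- which(obs$site == s)
    X <- object$frame$X_s[[s]]
    for (r in seq_len(nrow(m))) {
      pars <- hbm_site_pars(object, m[r, ], s)
      mu[r, idx] <- as.vector(X %*% pars$coefs)
      sd_mat[r, idx] <- pars$sigma
    }
  }
  ppc_sumsq(obs$y, mu, sd_mat, seed = seed)
}

#' @rdname dic
#' @export
dic.hbm <- function(object, ...) {
  dic.default(retained_draws(object$draws), object$log_lik)
}

#' Summarize a treatment effect from a fitted model
#'
#' Reports the posterior of a single parameter in the form used for
#' treatment effects: median, mean, an equal-tailed 95\% credible interval
#' expressed as a half-width about the median ("x +/- y"), and the
#' probability of direction. On the `"percentage_points"` scale the
#' coefficient is reported directly (appropriate for responses already on a
#' 0--100 scale); on the `"percent_relative"` scale the coefficient is
#' divided by a baseline — by default the observed mean response in the
#' reference condition (covariate at its minimum) — and multiplied by 100
#' (appropriate for richness/count responses).
#'
#' @param object A fitted `hbm` or `bsem` object, or a numeric vector of
#'   posterior draws.
#' @param parameter Parameter name (e.g. `"mu_W"`, `"beta_S[Peru]"`).
#'   Ignored when `object` is already a draw vector.
#' @param scale `"percentage_points"` or `"percent_relative"`.
#' @param baseline Denominator for the relative scale; computed from the
#'   model frame when omitted.
#' @return An object of class `effect_summary`.
#' @export
summarize_effect <- function(object, parameter = NULL,
                             scale = c("percentage_points", "percent_relative"),
                             baseline = NULL) {
  scale <- match.arg(scale)
  if (is.numeric(object)) {
    draws <- as.numeric(object)
  } else {
    m <- retained_draws(object$draws)
    if (!parameter %in% colnames(m))
      stop("parameter not found in draws: ", parameter)
    draws <- m[, parameter]
  }
  if (scale == "percent_relative") {
    if (is.null(baseline)) {
      if (is.numeric(object))
        stop("a baseline is required for percent_relative on raw draws")
      baseline <- reference_baseline(object, parameter)
    }
    if (!is.finite(baseline) || baseline == 0)
      stop("percent_relative requested with zero baseline")
    draws <- 100 * draws / baseline
  }
  effect_summary(draws, scale, baseline)
}

effect_summary <- function(draws, scale = "percentage_points",
                           baseline = NULL) {
  ci <- credible_interval(draws)
  md <- stats::median(draws)
  structure(list(median = md, mean = mean(draws),
                 ci95 = ci, half_width = max(ci[2] - md, md - ci[1]),
                 pd = p_direction(draws), scale = scale,
                 baseline = baseline, draws = draws),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  unit <- if (x$scale == "percentage_points") "pp" else "%"
  cat(sprintf("Effect: %.2f +/- %.2f %s (95%% CI %.2f to %.2f), PD = %.1f%%\n",
              x$median, x$half_width, unit, x$ci95[1], x$ci95[2], x$pd))
  invisible(x)
}

reference_baseline <- function(object, parameter) {
  cov <- sub("^(mu_|beta_)", "", sub("\\[.*$", "", parameter))
  obs <- object$frame$obs
  if (cov %in% names(obs)) {
    mean(obs$y[obs[[cov]] == min(obs[[cov]])])
  } else mean(obs$y)
}

#' Posterior contrast of the water effect between moderator levels
#'
#' For an interaction model, summarizes the posterior of the difference in
#' the water-addition slope between levels of the moderator: for `moderator
#' = "A"` the difference between high and low intraspecific richness plots
#' (the W:A coefficient itself); for `moderator = "S"` the difference in the
#' water effect between the highest and lowest observed standardized
#' interspecific richness (the W:S coefficient times the observed S range).
#' The reported PD is the probability that the two slopes differ in the
#' indicated direction.
#'
#' @param object A fitted `hbm` with the matching interaction.
#' @param moderator `"A"` or `"S"`.
#' @param site Optional site name to use that site's coefficient in a
#'   cross-site fit; default uses the cross-site mean (`mu_WA`/`mu_WS`).
#' @return An `effect_summary` of the slope difference.
#' @export
interaction_contrast <- function(object, moderator = c("A", "S"),
                                 site = NULL) {
  moderator <- match.arg(moderator)
  key <- paste0("W", moderator)          # WA or WS
  if (!key %in% object$frame$slope_names)
    stop("the model does not include the W:", moderator, " interaction")
  m <- retained_draws(object$draws)
  par <- if (object$spec$scope == "single_site") paste0("beta_", key)
         else if (is.null(site)) paste0("mu_", key)
         else paste0("beta_", key, "[", site, "]")
  if (!par %in% colnames(m)) stop("parameter not found: ", par)
  draws <- m[, par]
  if (moderator == "S") {
    rng <- range(object$frame$obs$S)
    draws <- draws * (rng[2] - rng[1])
  }
  effect_summary(draws)
}
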