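#' Bayesian structural equation (path) models for a single site
#'
#' Fits the two linked leaf-level regressions encoding the causal path
#' diagram among treatments, insect damage richness and herbivory:
#' \deqn{R_i = \alpha_R + a_A S_i + a_C A_i (+ a_G W_i) + \varepsilon_{R,i}}
#' \deqn{H_i = \alpha_H + a_B S_i + a_D A_i (+ a_F W_i) + a_E R_i +
#'       \varepsilon_{H,i}}
#' with independent Normal errors. Paths are labelled A (inter -> insect
#' richness), B (inter -> herbivory), C (intra -> insect richness),
#' D (intra -> herbivory), E (insect richness -> herbivory), F (water ->
#' herbivory), G (water -> insect richness). The candidate structures are:
#' \itemize{
#'   \item variant `"I"`: paths A--E plus both water paths F and G;
#'   \item variant `"II"`: water affects insect richness only (G, no F);
#'   \item variant `"III"`: water affects herbivory only (F, no G);
#'   \item variant `"no_water"`: neither water path (sites without the
#'     water treatment).
#' }
#' Priors and sampler match [hbm()] (Normal(0, 100) locations, half-Cauchy(5)
#' scales, blocked adaptive Metropolis with one block per equation). The DIC
#' and the sum-of-squares posterior predictive check are computed at fit time.
#'
#' @param data A `piper_data` object.
#' @param site Site name (the model is fit per site at the leaf level).
#' @param variant One of `"I"`, `"II"`, `"III"`, `"no_water"`.
#' @param interactions If `TRUE`, adds W:A and W:S terms to both equations.
#' @param n_chains,n_iter,n_burn,seed Sampler settings (defaults 10000/1000).
#' @return An object of class `bsem` with methods `print`, `summary`, `coef`,
#'   `predict`, `residuals`, plus [standardized_coefficients()],
#'   [indirect_effect()], [ppc()], [dic()] and [compare_bsem()].
#' @export
bsem <- function(data, site, variant = c("I", "II", "III", "no_water"),
                 interactions = FALSE, n_chains = 3L, n_iter = 10000L,
                 n_burn = 1000L, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(data, "piper_data"))
  plots <- data$plots
  if (!site %in% plots$site) stop("unknown site: ", site)
  has_F <- variant %in% c("I", "III")
  has_G <- variant %in% c("I", "II")
  site_has_water <- any(!is.na(plots$water[plots$site == site]))
  if ((has_F || has_G || interactions) && !site_has_water)
    stop("site ", site, " has no water treatment; variant ", variant,
         " requires the water variable")

  obs <- data$leaf[data$leaf$site == site, , drop = FALSE]
  m <- match(obs$plot_id, plots$plot_id)
  obs$W <- ifelse(is.na(plots$water[m]), 0L, plots$water[m])
  obs$A <- plots$intra_high[m]
  obs$S <- plots$S[m]
  obs <- obs[!plots$excluded[m], , drop = FALSE]
  if (nrow(obs) < 10) stop("too few leaves at site ", site)

  xr <- list(intercept = rep(1, nrow(obs)), a_A = obs$S, a_C = obs$A)
  if (has_G) xr$a_G <- obs$W
  xh <- list(intercept = rep(1, nrow(obs)), a_B = obs$S, a_D = obs$A)
  if (has_F) xh$a_F <- obs$W
  xh$a_E <- obs$y_R
  if (interactions) {
    xr$r_WA <- xh$h_WA <- obs$W * obs$A
    xr$r_WS <- xh$h_WS <- obs$W * obs$S
  }
  XR <- do.call(cbind, xr); XH <- do.call(cbind, xh)
  for (X in list(XR, XH)) {
    sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance predictor: ",
           paste(colnames(X)[-1][sds == 0], collapse = ", "))
  }
  yR <- obs$y_R; yH <- obs$y_H
  kR <- ncol(XR); kH <- ncol(XH)
  par_names <- c(paste0("R.", colnames(XR)), "log_sigma_R",
                 paste0("H.", colnames(XH)), "log_sigma_H")
  pR <- kR + 1L; p <- pR + kH + 1L
  ixR <- seq_len(pR); ixH <- (pR + 1L):p

  lp_eq <- function(X, y, th) {
    k <- ncol(X)
    site_loglik(X, y, th[seq_len(k)], th[k + 1L]) +
      sum(stats::dnorm(th[seq_len(k)], 0, 100, log = TRUE)) +
      lp_half_cauchy_log(th[k + 1L])
  }
  log_post <- function(theta, block = NULL) {
    if (is.null(block))
      lp_eq(XR, yR, theta[ixR]) + lp_eq(XH, yH, theta[ixH])
    else if (block == 1L) lp_eq(XR, yR, theta[ixR])
    else lp_eq(XH, yH, theta[ixH])
  }
  log_lik <- function(theta) {
    site_loglik(XR, yR, theta[seq_len(kR)], theta[kR + 1L]) +
      site_loglik(XH, yH, theta[pR + seq_len(kH)], theta[p])
  }
  eR <- ols_start(XR, yR); eH <- ols_start(XH, yH)
  base <- c(eR$coef, eR$log_sd, eH$coef, eH$log_sd)
  prop_sd <- c(eR$se, eR$log_sd_se, eH$se, eH$log_sd_se)
  jit <- pmax(abs(base) * 0.25, 0.25)
  init <- function(chain) base + stats::rnorm(p) * jit

  draws <- run_chains(log_post, init, n_chains = n_chains, n_iter = n_iter,
                      n_burn = n_burn, seed = seed,
                      blocks = list(ixR, ixH), par_names = par_names,
                      proposal_sd = prop_sd)
  rhat <- tryCatch(gelman_rubin(draws), error = function(e) NULL)

  fit <- structure(list(draws = draws, variant = variant, site = site,
                        interactions = interactions,
                        frame = list(obs = obs, XR = XR, XH = XH,
                                     yR = yR, yH = yH),
                        paths = bsem_paths(variant, interactions),
                        log_lik = log_lik, rhat = rhat,
                        call = match.call()),
                   class = "bsem")
  fit$dic <- dic.default(retained_draws(draws), log_lik)
  fit$ppc <- ppc.bsem(fit)
  fit
}

bsem_paths <- function(variant, interactions = FALSE) {
  # path label -> (parameter, predictor column, outcome)
  p <- list(
    A = c(par = "R.a_A", pred = "S", out = "R"),
    C = c(par = "R.a_C", pred = "A", out = "R"),
    B = c(par = "H.a_B", pred = "S", out = "H"),
    D = c(par = "H.a_D", pred = "A", out = "H"),
    E = c(par = "H.a_E", pred = "R", out = "H"))
  if (variant %in% c("I", "II")) p$G <- c(par = "R.a_G", pred = "W", out = "R")
  if (variant %in% c("I", "III")) p$F <- c(par = "H.a_F", pred = "W", out = "H")
  p
}

#' @export
print.bsem <- function(x, ...) {
  cat("Bayesian structural equation model, variant", x$variant,
      "at site", x$site, "\n")
  cat("Active paths:", paste(names(x$paths), collapse = ", "),
      "  n leaves =", nrow(x$frame$obs), "\n")
  cat(sprintf("DIC = %.1f (pD = %.1f), PPC = %.3f\n",
              x$dic$DIC, x$dic$pD, x$ppc["combined"]))
  invisible(x)
}

#' @export
summary.bsem <- function(object, ...) draws_summary(object$draws, object$rhat)

#' @export
coef.bsem <- function(object, ...) {
  m <- retained_draws(object$draws)
  stats::setNames(apply(m, 2, stats::median), colnames(m))
}

#' @export
predict.bsem <- function(object, ...) {
  co <- coef.bsem(object)
  kR <- ncol(object$frame$XR); kH <- ncol(object$frame$XH)
  list(R = as.vector(object$frame$XR %*% co[seq_len(kR)]),
       H = as.vector(object$frame$XH %*% co[(kR + 2L):(kR + 1L + kH)]))
}

#' @export
residuals.bsem <- function(object, ...) {
  pr <- predict.bsem(object)
  list(R = object$frame$yR - pr$R, H = object$frame$yH - pr$H)
}

#' @rdname ppc
#' @export
ppc.bsem <- function(object, max_draws = 500, seed = 1, ...) {
  m <- retained_draws(object$draws)
  keep <- unique(round(seq(1, nrow(m), length.out = min(max_draws, nrow(m)))))
  m <- m[keep, , drop = FALSE]
  kR <- ncol(object$frame$XR); kH <- ncol(object$frame$XH)
  pR <- kR + 1L
  muR <- m[, seq_len(kR), drop = FALSE] %*% t(object$frame$XR)
  muH <- m[, pR + seq_len(kH), drop = FALSE] %*% t(object$frame$XH)
  sR <- exp(m[, pR]); sH <- exp(m[, ncol(m)])
  pr <- ppc_sumsq(object$frame$yR, muR, sR, seed = seed)
  ph <- ppc_sumsq(object$frame$yH, muH, sH, seed = seed + 1L)
  # combined discrepancy: total residual sum of squares over both equations
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed + 2L)
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  n <- length(object$frame$yR)
  tR_obs <- rowSums(sweep(muR, 2, object$frame$yR, function(m_, y) y - m_)^2)
  tH_obs <- rowSums(sweep(muH, 2, object$frame$yH, function(m_, y) y - m_)^2)
  tR_rep <- rowSums((matrix(rnorm(nrow(m) * n), nrow(m), n) * sR)^2)
  tH_rep <- rowSums((matrix(rnorm(nrow(m) * n), nrow(m), n) * sH)^2)
  comb <- mean(((tR_rep + tH_rep) > (tR_obs + tH_obs)) +
                 0.5 * ((tR_rep + tH_rep) == (tR_obs + tH_obs)))
  c(R = pr, H = ph, combined = comb)
}

#' @rdname dic
#' @export
dic.bsem <- function(object, ...) object$dic

#' Standardized path coefficients
#'
#' Scales each raw path coefficient by sd(predictor)/sd(outcome), both
#' computed from the site data (binary treatments use their observed sd),
#' so coefficients are comparable across paths and invariant to affine
#' rescaling of any variable. Standardization is post hoc — raw and
#' standardized summaries come from the same fit.
#'
#' @param object A fitted `bsem`.
#' @return Data.frame with one row per active path: posterior median, mean,
#'   95\% CI and PD of the standardized coefficient. The per-draw
#'   standardized coefficient matrix is attached as attribute `"draws"`.
#' @export
standardized_coefficients <- function(object) {
  stopifnot(inherits(object, "bsem"))
  obs <- object$frame$obs
  vars <- list(S = obs$S, A = obs$A, W = obs$W, R = obs$y_R, H = obs$y_H)
  sds <- vapply(vars, stats::sd, 0)
  if (any(sds[c("R", "H")] == 0)) stop("zero-variance outcome")
  m <- retained_draws(object$draws)
  paths <- object$paths
  std <- sapply(names(paths), function(lbl) {
    p <- paths[[lbl]]
    if (sds[p["pred"]] == 0) stop("zero-variance predictor for path ", lbl)
    m[, p["par"]] * sds[p["pred"]] / sds[p["out"]]
  })
  colnames(std) <- names(paths)
  out <- data.frame(
    path = names(paths),
    predictor = vapply(paths, `[`, "", "pred"),
    outcome = vapply(paths, `[`, "", "out"),
    median = apply(std, 2, stats::median),
    mean = colMeans(std),
    lo95 = apply(std, 2, function(v) credible_interval(v)[1]),
    hi95 = apply(std, 2, function(v) credible_interval(v)[2]),
    pd = apply(std, 2, p_direction),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- std
  out
}

#' Indirect effect along a chain of paths
#'
#' The per-draw product of the standardized coefficients of the given path
#' chain (e.g. `c("A", "E")` for inter-richness -> insect richness ->
#' herbivory), summarized as an effect.
#'
#' @param object A fitted `bsem`.
#' @param chain Character vector of path labels, multiplied in order.
#' @return An `effect_summary` of the indirect effect.
#' @export
indirect_effect <- function(object, chain) {
  stopifnot(inherits(object, "bsem"))
  inactive <- setdiff(chain, names(object$paths))
  if (length(inactive))
    stop("chain references inactive path(s): ",
         paste(inactive, collapse = ", "))
  std <- attr(standardized_coefficients(object), "draws")
  prod_draws <- std[, chain[1]]
  for (lbl in chain[-1]) prod_draws <- prod_draws * std[, lbl]
  effect_summary(prod_draws)
}

#' Compare BSEM variants fitted to identical data
#'
#' Ranks fits by DIC (ascending); fits within 2 DIC units of the best are
#' treated as ties and broken toward the variant with fewer active paths
#' (parsimony). The PPC is reported alongside.
#'
#' @param fits List of `bsem` objects fitted to the same site data.
#' @return Data.frame (variant, n_paths, DIC, pD, PPC, delta_DIC, selected)
#'   ordered by rank; the selected variant name is attached as attribute
#'   `"selected"`.
#' @export
compare_bsem <- function(fits) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, TRUE, "bsem")))
  sig <- vapply(fits, function(f)
    paste(f$site, nrow(f$frame$obs), signif(sum(f$frame$yH), 12),
          signif(sum(f$frame$yR), 12)), "")
  if (length(unique(sig)) != 1) stop("fits were made on differing data")
  tab <- data.frame(
    variant = vapply(fits, function(f) f$variant, ""),
    n_paths = vapply(fits, function(f) length(f$paths), 0L),
    DIC = vapply(fits, function(f) f$dic$DIC, 0),
    pD = vapply(fits, function(f) f$dic$pD, 0),
    PPC = vapply(fits, function(f) unname(f$ppc["combined"]), 0),
    stringsAsFactors = FALSE)
  tab$delta_DIC <- tab$DIC - min(tab$DIC)
  contenders <- which(tab$delta_DIC < 2)
  sel <- contenders[order(tab$n_paths[contenders],
                          tab$DIC[contenders])][1]
  tab$selected <- seq_len(nrow(tab)) == sel
  tab <- tab[order(tab$DIC), ]
  rownames(tab) <- NULL
  attr(tab, "selected") <- tab$variant[tab$selected]
  tab
}
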