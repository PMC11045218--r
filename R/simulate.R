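#' Default site configurations for a five-site *Piper* diversity experiment
#'
#' Returns the site layout emulated by the synthetic-experiment generator:
#' five neotropical sites, 12-plant plots, a water-addition treatment crossed
#' with intra- and interspecific richness at three of the sites, site species
#' pools of differing size, and experiment durations between roughly 1.4 and
#' 2.8 years. Interspecific richness levels are monoculture, two species and
#' the site's maximum pool.
#'
#' @param n_plots_per_cell Replicate plots per treatment combination.
#' @param plants_per_plot Plants per plot (the field design used 12).
#' @param mean_leaves_per_plant Mean of the (zero-truncated Poisson) leaf
#'   count per surviving plant.
#' @param sites Optional character subset of the five default site names.
#' @return A data.frame with one row per site and list-columns
#'   `richness_levels` (planted interspecific richness treatments) and
#'   `taxa` (per-site data.frame of insect taxon labels and specialist flags).
#' @export
piper_sites <- function(n_plots_per_cell = 2L, plants_per_plot = 12L,
                        mean_leaves_per_plant = 6,
                        sites = c("CostaRica", "Ecuador", "Peru",
                                  "Mogi", "Uaimii")) {
  master <- data.frame(
    taxon = c("Eois", "Quadrus", "Marmara", "Tortricidae", "Limacodidae",
              "Geometridae", "Noctuidae", "Pyralidae", "Chrysomelidae",
              "Curculionidae", "Orthoptera", "Saturniidae", "LeafMiner"),
    specialist = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  # per-site taxon pools: 10 taxa at the three wet sites, 9 at Mogi, 8 at
  # Uaimii; specialist-heavy communities at Costa Rica and Ecuador
  pools <- list(
    CostaRica = c(1:6, 7, 9, 10, 11),
    Ecuador   = c(1:6, 7, 8, 9, 11),
    Peru      = c(1, 2, 6, 7:13),
    Mogi      = c(1, 6, 7:13),
    Uaimii    = c(1, 7:13))
  cfg <- data.frame(
    site = c("CostaRica", "Ecuador", "Peru", "Mogi", "Uaimii"),
    pool_size = c(12L, 12L, 6L, 5L, 3L),
    has_water_treatment = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    n_plots_per_cell = n_plots_per_cell,
    plants_per_plot = as.integer(plants_per_plot),
    mean_leaves_per_plant = mean_leaves_per_plant,
    duration_days = c(1022L, 1022L, 511L, 730L, 730L),
    n_blocks = c(0L, 0L, 0L, 3L, 3L),
    stringsAsFactors = FALSE)
  cfg$richness_levels <- lapply(cfg$pool_size, function(p)
    unique(c(1L, 2L, as.integer(p))))
  cfg$taxa <- lapply(cfg$site, function(s) master[pools[[s]], , drop = FALSE])
  cfg <- cfg[cfg$site %in% sites, , drop = FALSE]
  rownames(cfg) <- NULL
  validate_sites(cfg)
  cfg
}

validate_sites <- function(configs) {
  if (nrow(configs) == 0) stop("`configs` must contain at least one site")
  for (i in seq_len(nrow(configs))) {
    rl <- configs$richness_levels[[i]]
    if (any(rl < 1L) || any(rl > configs$pool_size[i]))
      stop("richness level exceeds pool_size at site ", configs$site[i])
    if (configs$plants_per_plot[i] < 1L) stop("plants_per_plot must be >= 1")
    if (configs$duration_days[i] <= 0) stop("duration_days must be positive")
  }
  invisible(configs)
}

#' Ground-truth parameters for the synthetic experiment generator
#'
#' Bundles the true site-hierarchy coefficients for the four modelled
#' responses, the log-hazard parameters of the exponential mortality process,
#' and (for the mechanistic mode) per-taxon incidence and damage parameters.
#' Response coefficients are given as cross-site means `mu` and between-site
#' standard deviations `tau` over `(intercept, W, A, S)`; the generator draws
#' the per-site values from Normal(mu, tau) and records them so that recovery
#' tests can compare posterior estimates against known truth.
#'
#' Defaults emulate the magnitudes observed in multi-site *Piper* plantings:
#' mean leaf herbivory around 20\% with strong site differences, a roughly
#' 4 percentage-point reduction under water addition, about two damage taxa
#' per leaf, and site mortality spanning roughly 25--90\% with water and
#' intraspecific richness reducing the hazard.
#'
#' @param mode `"gaussian"` (responses drawn from the fitted models' truncated
#'   Normal likelihood; used for recovery tests) or `"mechanistic"`
#'   (per-taxon Bernoulli incidence times Gamma damage; used for robustness).
#' @param ... Named overrides merged into the defaults, e.g.
#'   `herbivory = list(mu = c(intercept = 30, W = 0, A = 0, S = 0))`.
#' @return An object of class `piper_truth`.
#' @export
piper_truth <- function(mode = c("gaussian", "mechanistic"), ...) {
  mode <- match.arg(mode)
  coef_block <- function(mu, tau, sigma, mu_WA = 0, mu_WS = 0) {
    list(mu = mu, tau = tau, sigma = sigma,
         interactions = c(WA = mu_WA, WS = mu_WS))
  }
  nm <- c("intercept", "W", "A", "S")
  truth <- list(
    mode = mode,
    herbivory = coef_block(
      mu = stats::setNames(c(20, -4.2, 1.0, 4.0), nm),
      tau = stats::setNames(c(5, 1.0, 1.5, 2.0), nm), sigma = 10),
    insect_richness = coef_block(
      mu = stats::setNames(c(2.0, -0.15, 0.15, 1.0), nm),
      tau = stats::setNames(c(0.4, 0.1, 0.15, 0.3), nm), sigma = 1.1),
    pct_damaged = coef_block(
      mu = stats::setNames(c(65, -3, 2, 6), nm),
      tau = stats::setNames(c(8, 1.5, 2, 3), nm), sigma = 18),
    herb_variance = coef_block(
      mu = stats::setNames(c(140, -15, 5, 20), nm),
      tau = stats::setNames(c(30, 6, 8, 10), nm), sigma = 90),
    survival = list(
      log_lambda0 = log(8e-4), tau_lambda0 = 0.8,
      b_W = -0.45, b_A = -0.40, b_S = -0.10, b_WA = 0),
    taxa = list(
      incidence_logit0 = -1.3, incidence_sd = 0.5,
      g_W = -0.2, g_A = 0.05, g_S = 0.4,
      mean_damage = 7, damage_shape = 1.2))
  overrides <- list(...)
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(truth[[k]])) {
      truth[[k]] <- utils::modifyList(truth[[k]], overrides[[k]])
    } else truth[[k]] <- overrides[[k]]
  }
  validate_truth(truth)
  structure(truth, class = "piper_truth")
}

validate_truth <- function(truth) {
  if (!truth$mode %in% c("gaussian", "mechanistic"))
    stop("unknown generator mode: ", truth$mode)
  for (r in c("herbivory", "insect_richness", "pct_damaged", "herb_variance")) {
    if (truth[[r]]$sigma <= 0) stop("non-positive residual sd for ", r)
    if (any(truth[[r]]$tau < 0)) stop("negative between-site sd for ", r)
  }
  if (truth$taxa$mean_damage <= 0 || truth$taxa$mean_damage > 100)
    stop("mean taxon damage must lie in (0, 100]")
  sv <- truth$survival
  if (!all(is.finite(c(sv$b_W, sv$b_A, sv$b_S, sv$b_WA))))
    stop("non-finite hazard parameter")
  # log_lambda0 = -Inf encodes a zero baseline hazard (no events)
  if (is.nan(sv$log_lambda0) || sv$log_lambda0 == Inf)
    stop("non-finite hazard parameter")
  invisible(truth)
}

rtpois <- function(n, lambda) {
  # Poisson truncated at >= 1 via inverse cdf
  p0 <- stats::dpois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

rtnorm <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm((lo - mean) / sd)
  b <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(a + stats::runif(n) * (b - a))
}

#' Simulate exponential survival times with treatment-dependent hazard
#'
#' Event times are exponential with log-hazard linear in the water,
#' intraspecific and (standardised planted) interspecific treatments; times
#' beyond the site's experiment duration are right-censored there.
#'
#' @param plants Data.frame with columns `W` (0/1), `A` (0/1), `S_planted`
#'   (planted richness / pool size) and `duration_days`.
#' @param truth A `piper_truth` object (its `survival` component is used).
#' @param log_lambda0 Per-plant baseline log hazard (per day); defaults to
#'   the truth's shared baseline for every plant.
#' @return `plants` with columns `time_days` and `event` (1 = died) added.
#' @export
sample_survival_times <- function(plants, truth,
                                  log_lambda0 = truth$survival$log_lambda0) {
  sv <- truth$survival
  eta <- log_lambda0 + sv$b_W * plants$W + sv$b_A * plants$A +
    sv$b_S * plants$S_planted + sv$b_WA * plants$W * plants$A
  # eta = -Inf encodes a zero hazard (no events); anything else non-finite
  # is a specification error
  if (any(is.nan(eta) | eta == Inf)) stop("non-finite hazard")
  lambda <- exp(eta)
  t_raw <- ifelse(lambda > 0, stats::rexp(nrow(plants)) / lambda, Inf)
  plants$event <- as.integer(t_raw <= plants$duration_days)
  plants$time_days <- pmin(t_raw, plants$duration_days)
  plants
}

#' Generate a complete synthetic multi-site experiment
#'
#' Produces the three raw tables the analysis pipeline consumes (plot
#' treatments, long-format per-taxon leaf damage, plant survival records),
#' under a full factorial assignment of water (where available),
#' intraspecific richness (low/high) and planted interspecific richness.
#' Plant mortality is simulated first; realized interspecific richness is
#' recomputed from the surviving plants, and only survivors carry leaves.
#'
#' In `"gaussian"` mode the leaf responses are drawn from the same truncated
#' Normal models the package fits (total herbivory on [0, 100]; damage-taxon
#' richness as a rounded truncated Normal on [0, n taxa]), so fitted models
#' are correctly specified and parameter recovery is testable. In
#' `"mechanistic"` mode each taxon independently attacks a leaf
#' (Bernoulli incidence) and removes a Gamma-distributed leaf fraction.
#'
#' @param configs Site configuration data.frame from [piper_sites()].
#' @param truth A [piper_truth()] object.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return An object of class `piper_experiment`: list with `plots`,
#'   `leaves` (long format), `plants`, the `truth` used, `site_truth`
#'   (realized per-site coefficients, the reference for recovery tests),
#'   `configs` and `seed`.
#' @export
generate_experiment <- function(configs, truth, seed) {
  validate_sites(configs)
  validate_truth(truth)
  if (missing(seed)) stop("a seed must be supplied")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  responses <- c("herbivory", "insect_richness", "pct_damaged", "herb_variance")
  n_site <- nrow(configs)
  site_truth <- list()
  for (r in responses) {
    tb <- truth[[r]]
    m <- matrix(stats::rnorm(n_site * 4, rep(tb$mu, each = n_site),
                             rep(tb$tau, each = n_site)),
                n_site, 4, dimnames = list(configs$site, names(tb$mu)))
    site_truth[[r]] <- m
  }
  site_truth$survival_log_lambda0 <- stats::setNames(
    stats::rnorm(n_site, truth$survival$log_lambda0,
                 truth$survival$tau_lambda0), configs$site)

  plots_list <- list(); plants_list <- list(); leaves_list <- list()

  for (i in seq_len(n_site)) {
    cf <- configs[i, ]
    site <- cf$site
    water_levels <- if (cf$has_water_treatment) c(0L, 1L) else NA_integer_
    cells <- expand.grid(W = water_levels, A = c(0L, 1L),
                         planted = cf$richness_levels[[1]],
                         rep = seq_len(cf$n_plots_per_cell))
    np <- nrow(cells)
    plot_id <- sprintf("%s_p%03d", site, seq_len(np))
    block <- if (cf$n_blocks > 0)
      sprintf("b%d", 1L + (seq_len(np) - 1L) %% cf$n_blocks) else ""
    species_pool <- sprintf("%s_sp%02d", site, seq_len(cf$pool_size))
    taxa <- cf$taxa[[1]]

    plants_site <- vector("list", np)
    for (pp in seq_len(np)) {
      r <- cells$planted[pp]
      sp <- if (r >= cf$pool_size) species_pool else sample(species_pool, r)
      plants_site[[pp]] <- data.frame(
        site = site, plot_id = plot_id[pp],
        plant_id = sprintf("%s_i%02d", plot_id[pp],
                           seq_len(cf$plants_per_plot)),
        species = rep_len(sp, cf$plants_per_plot),
        W = ifelse(is.na(cells$W[pp]), 0L, cells$W[pp]),
        A = cells$A[pp],
        S_planted = r / cf$pool_size,
        duration_days = cf$duration_days,
        stringsAsFactors = FALSE)
    }
    plants_site <- do.call(rbind, plants_site)
    plants_site <- sample_survival_times(
      plants_site, truth, log_lambda0 = site_truth$survival_log_lambda0[site])

    final_rich <- vapply(seq_len(np), function(pp) {
      surv <- plants_site[plants_site$plot_id == plot_id[pp] &
                            plants_site$event == 0L, ]
      length(unique(surv$species))
    }, 0L)

    plots_list[[i]] <- data.frame(
      site = site, plot_id = plot_id, block = block,
      water = cells$W, intra_high = cells$A,
      planted_richness = cells$planted,
      final_richness = final_rich, pool_size = cf$pool_size,
      stringsAsFactors = FALSE)

    survivors <- plants_site[plants_site$event == 0L, ]
    if (nrow(survivors) > 0) {
      S_real <- final_rich[match(survivors$plot_id, plot_id)] / cf$pool_size
      n_leaves <- rtpois(nrow(survivors), cf$mean_leaves_per_plant)
      leaf_plant <- rep(seq_len(nrow(survivors)), n_leaves)
      leaf_seq <- sequence(n_leaves)
      nl <- length(leaf_plant)
      Wv <- survivors$W[leaf_plant]; Av <- survivors$A[leaf_plant]
      Sv <- S_real[leaf_plant]
      leaves_site <- data.frame(
        site = site,
        plot_id = survivors$plot_id[leaf_plant],
        plant_id = survivors$plant_id[leaf_plant],
        leaf_id = sprintf("%s_L%02d", survivors$plant_id[leaf_plant], leaf_seq),
        stringsAsFactors = FALSE)

      if (truth$mode == "gaussian") {
        bH <- site_truth$herbivory[site, ]
        bR <- site_truth$insect_richness[site, ]
        iH <- truth$herbivory$interactions
        iR <- truth$insect_richness$interactions
        etaH <- bH["intercept"] + bH["W"] * Wv + bH["A"] * Av + bH["S"] * Sv +
          iH["WA"] * Wv * Av + iH["WS"] * Wv * Sv
        etaR <- bR["intercept"] + bR["W"] * Wv + bR["A"] * Av + bR["S"] * Sv +
          iR["WA"] * Wv * Av + iR["WS"] * Wv * Sv
        yH <- rtnorm(nl, etaH, truth$herbivory$sigma, 0, 100)
        yR <- round(rtnorm(nl, etaR, truth$insect_richness$sigma,
                           0, nrow(taxa)))
        yR[yH > 0 & yR < 1] <- 1L
        yR[yH == 0] <- 0L
        leaves_list[[length(leaves_list) + 1L]] <-
          split_damage_rows(leaves_site, yH, yR, taxa$taxon)
      } else {
        tx <- truth$taxa
        logit0 <- stats::rnorm(nrow(taxa), tx$incidence_logit0, tx$incidence_sd)
        rows <- vector("list", nrow(taxa))
        hit_any <- rep(FALSE, nl)
        for (tt in seq_len(nrow(taxa))) {
          pr <- stats::plogis(logit0[tt] + tx$g_W * Wv + tx$g_A * Av +
                                tx$g_S * Sv)
          hit <- stats::runif(nl) < pr
          if (!any(hit)) next
          dmg <- stats::rgamma(sum(hit), shape = tx$damage_shape,
                               rate = tx$damage_shape / tx$mean_damage)
          dmg <- pmin(dmg, 100)
          rows[[tt]] <- cbind(leaves_site[hit, , drop = FALSE],
                              taxon = taxa$taxon[tt], damage_pct = dmg)
          hit_any <- hit_any | hit
        }
        undamaged <- leaves_site[!hit_any, , drop = FALSE]
        if (nrow(undamaged) > 0)
          rows[[nrow(taxa) + 1L]] <- cbind(undamaged, taxon = "",
                                           damage_pct = 0)
        leaves_list[[length(leaves_list) + 1L]] <-
          do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      }
    }
    plants_site$duration_days <- NULL
    plants_site$W <- NULL; plants_site$A <- NULL; plants_site$S_planted <- NULL
    plants_list[[i]] <- plants_site
  }

  leaves <- do.call(rbind, leaves_list)
  rownames(leaves) <- NULL
  out <- list(plots = do.call(rbind, plots_list),
              leaves = leaves,
              plants = do.call(rbind, plants_list),
              truth = truth, site_truth = site_truth,
              configs = configs, seed = as.integer(seed))
  rownames(out$plots) <- rownames(out$plants) <- NULL
  class(out) <- "piper_experiment"
  out
}

# distribute gaussian-mode leaf totals over y_R damage taxa so that the
# long-format table reproduces (y_H, y_R) exactly after re-derivation
split_damage_rows <- function(leaves_site, yH, yR, taxon_pool) {
  nl <- nrow(leaves_site)
  rows <- vector("list", nl)
  for (k in seq_len(nl)) {
    if (yR[k] == 0 || yH[k] == 0) {
      rows[[k]] <- cbind(leaves_site[k, , drop = FALSE],
                         taxon = "", damage_pct = 0)
    } else {
      taxa_k <- sample(taxon_pool, yR[k])
      w <- stats::rgamma(yR[k], 1)
      rows[[k]] <- cbind(leaves_site[rep(k, yR[k]), , drop = FALSE],
                         taxon = taxa_k,
                         damage_pct = yH[k] * w / sum(w))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.piper_experiment <- function(x, ...) {
  cat("Synthetic Piper experiment (mode:", x$truth$mode, ", seed:", x$seed,
      ")\n")
  cat(" ", nrow(x$plots), "plots,", nrow(x$plants), "plants,",
      length(unique(x$leaves$leaf_id)), "leaves across",
      length(unique(x$plots$site)), "site(s)\n")
  invisible(x)
}

#' Write a synthetic experiment to CSV files plus a truth sidecar
#'
#' Writes `plots.csv`, `leaves.csv` and `plants.csv` in the schemas read by
#' [read_experiment()], and `truth.json` echoing the generator truth and seed.
#'
#' @param x A `piper_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "piper_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("plots.csv", "leaves.csv", "plants.csv"))
  utils::write.csv(x$plots, paths[1], row.names = FALSE, na = "")
  utils::write.csv(x$leaves, paths[2], row.names = FALSE, na = "")
  utils::write.csv(x$plants, paths[3], row.names = FALSE, na = "")
  truth <- x$truth
  class(truth) <- NULL
  jsonlite::write_json(
    list(seed = x$seed, truth = truth,
         site_truth = lapply(x$site_truth, function(m)
           if (is.matrix(m)) as.data.frame(m) else as.list(m))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "truth.json")))
}
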