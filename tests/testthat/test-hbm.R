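# fast single-site fit used by several tests
fit_small <- function(dat, response = "leaf_herbivory", covariates = c("A", "S"),
                      site = "CostaRica", seed = 1, ...) {
  hbm(dat, response, covariates = covariates, scope = "single_site",
      site = site, n_chains = 2, n_iter = 2500, n_burn = 500, seed = seed, ...)
}

test_that("intercept-only posterior matches the conjugate closed form", {
  tr <- piper_truth(
    herbivory = list(mu = c(intercept = 40, W = 0, A = 0, S = 0),
                     tau = c(intercept = 0, W = 0, A = 0, S = 0), sigma = 12))
  dat <- simulate_experiment(small_site(n_plots_per_cell = 3L), tr, seed = 71)
  f <- hbm(dat, "leaf_herbivory", covariates = character(0),
           scope = "single_site", site = "CostaRica",
           n_chains = 2, n_iter = 4000, n_burn = 800, seed = 2)
  y <- f$frame$y_s[[1]]
  # conjugate posterior for the mean with sigma treated as known (= truth)
  v_post <- 1 / (1 / 100^2 + length(y) / 12^2)
  m_post <- v_post * (sum(y) / 12^2)
  alpha <- retained_draws(f$draws)[, "alpha"]
  expect_lt(abs(mean(alpha) - m_post) / m_post, 0.02)
})

test_that("shifting the response shifts only the intercept", {
  dat <- simulate_experiment(small_site(), piper_truth(), seed = 72)
  f0 <- fit_small(dat, seed = 3)
  dat_shift <- dat
  dat_shift$leaf$y_H <- pmin(dat_shift$leaf$y_H + 10, 110)  # keep exact shift
  f1 <- fit_small(dat_shift, seed = 3)
  c0 <- coef(f0); c1 <- coef(f1)
  expect_lt(abs((c1["alpha"] - c0["alpha"]) - 10), 1.0)
  expect_lt(abs(c1["beta_S"] - c0["beta_S"]), 2.0)
  expect_lt(abs(c1["beta_A"] - c0["beta_A"]), 1.0)
})

test_that("negating a covariate negates its coefficient posterior", {
  dat <- simulate_experiment(small_site(), piper_truth(), seed = 73)
  f0 <- fit_small(dat, seed = 4)
  dat_neg <- dat
  dat_neg$plots$S <- -dat_neg$plots$S
  f1 <- fit_small(dat_neg, seed = 4)
  expect_lt(abs(coef(f1)["beta_S"] + coef(f0)["beta_S"]), 1.5)
})

test_that("effect summaries report the paper-style x +/- y form", {
  es <- summarize_effect(rep(-4.2, 100))
  expect_equal(es$median, -4.2)
  expect_equal(es$half_width, 0)
  es2 <- summarize_effect(rep(0.3, 100), scale = "percent_relative",
                          baseline = 2.0)
  expect_equal(es2$median, 15)
  set.seed(74)
  es3 <- summarize_effect(rnorm(1e5, 1, 1))
  expect_lt(abs(es3$pd - 100 * pnorm(1)), 0.5)
  expect_error(summarize_effect(rnorm(10), scale = "percent_relative",
                                baseline = 0), "baseline")
})

test_that("water-effect models keep only sites with the water treatment", {
  dat <- simulate_experiment(piper_sites(), piper_truth(), seed = 75)
  f <- hbm(dat, "leaf_herbivory", covariates = c("W", "A", "S"),
           n_chains = 2, n_iter = 1500, n_burn = 300, seed = 5)
  expect_setequal(f$frame$sites, c("CostaRica", "Ecuador", "Peru"))
  f_all <- hbm(dat, "leaf_insect_richness", covariates = c("A", "S"),
               n_chains = 2, n_iter = 1500, n_burn = 300, seed = 5)
  expect_setequal(f_all$frame$sites,
                  c("CostaRica", "Ecuador", "Peru", "Mogi", "Uaimii"))
})

test_that("degenerate designs are rejected with informative errors", {
  dat <- simulate_experiment(small_site(), piper_truth(), seed = 76)
  expect_error(hbm(dat, "leaf_herbivory", covariates = c("A", "Z")),
               "unknown covariate")
  expect_error(hbm(dat, "leaf_insect_richness", covariates = c("A", "R")),
               "only defined for leaf_herbivory")
  expect_error(hbm(dat, "leaf_herbivory", covariates = "A",
                   interactions = "W:A"), "require the water covariate")
  expect_error(hbm(dat, "leaf_herbivory", covariates = c("A", "S"),
                   scope = "cross_site"), "at least 2 sites")
  dat_mogi <- simulate_experiment(
    piper_sites(sites = c("Mogi", "Uaimii")), piper_truth(), seed = 77)
  expect_error(hbm(dat_mogi, "leaf_herbivory", covariates = c("W", "A", "S")),
               "water")
  dat_const <- dat
  dat_const$leaf$y_H <- 5
  expect_error(hbm(dat_const, "leaf_herbivory", covariates = c("A", "S"),
                   scope = "single_site", site = "CostaRica"),
               "constant")
})

test_that("interaction contrasts recover a built-in slope difference", {
  # water effect differs by +12pp between intraspecific richness levels
  tr <- piper_truth(
    herbivory = list(mu = c(intercept = 40, W = -6, A = 1, S = 0),
                     tau = c(intercept = 0, W = 0, A = 0, S = 0),
                     sigma = 10, interactions = c(WA = 12, WS = 0)),
    survival = list(log_lambda0 = log(2e-4), tau_lambda0 = 0,
                    b_W = 0, b_A = 0, b_S = 0, b_WA = 0))
  dat <- simulate_experiment(small_site(n_plots_per_cell = 8L), tr, seed = 78)
  f <- hbm(dat, "leaf_herbivory", covariates = c("W", "A", "S"),
           interactions = "W:A", scope = "single_site", site = "CostaRica",
           n_chains = 2, n_iter = 4000, n_burn = 1000, seed = 6)
  ic <- interaction_contrast(f, "A")
  expect_gt(ic$ci95[2], 12 - 6)
  expect_true(ic$ci95[1] <= 12 && 12 <= ic$ci95[2])
  expect_error(interaction_contrast(f, "S"), "does not include")

  # identical water slopes by construction: contrast centred at zero
  tr0 <- piper_truth(
    herbivory = list(mu = c(intercept = 40, W = -6, A = 1, S = 0),
                     tau = c(intercept = 0, W = 0, A = 0, S = 0),
                     sigma = 10),
    survival = list(log_lambda0 = log(2e-4), tau_lambda0 = 0,
                    b_W = 0, b_A = 0, b_S = 0, b_WA = 0))
  dat0 <- simulate_experiment(small_site(n_plots_per_cell = 8L), tr0, seed = 79)
  f0 <- hbm(dat0, "leaf_herbivory", covariates = c("W", "A", "S"),
            interactions = "W:A", scope = "single_site", site = "CostaRica",
            n_chains = 2, n_iter = 4000, n_burn = 1000, seed = 7)
  ic0 <- interaction_contrast(f0, "A")
  expect_true(ic0$ci95[1] <= 0 && 0 <= ic0$ci95[2])
})

test_that("sites with empty water-by-intraspecific cells cannot carry W:A", {
  dat <- simulate_experiment(three_sites(), piper_truth(), seed = 80)
  # empty Peru's watered/high-intra cell, mimicking catastrophic mortality
  kill <- dat$plots$site == "Peru" & dat$plots$water == 1 &
    dat$plots$intra_high == 1
  drop_plots <- dat$plots$plot_id[kill]
  dat$leaf <- dat$leaf[!(dat$leaf$plot_id %in% drop_plots), ]
  expect_warning(
    hbm(dat, "leaf_herbivory", covariates = c("W", "A", "S"),
        interactions = "W:A", n_chains = 2, n_iter = 1200, n_burn = 300,
        seed = 8),
    "Peru")
  expect_error(
    hbm(dat, "leaf_herbivory", covariates = c("W", "A", "S"),
        interactions = "W:A", scope = "single_site", site = "Peru",
        n_chains = 2, n_iter = 1200, n_burn = 300, seed = 8),
    "Peru")
})

test_that("identical site effects pool toward the common mean", {
  tr <- piper_truth(
    herbivory = list(mu = c(intercept = 30, W = 0, A = 2, S = 5),
                     tau = c(intercept = 0, W = 0, A = 0, S = 0), sigma = 10))
  # sparse plots and few leaves: per-site likelihoods are weak, so the
  # hierarchy should visibly shrink site slopes toward the common mean
  cfg <- piper_sites(n_plots_per_cell = 1L, mean_leaves_per_plant = 3,
                     sites = c("CostaRica", "Ecuador", "Peru"))
  dat <- simulate_experiment(cfg, tr, seed = 81)
  f_cross <- hbm(dat, "leaf_herbivory", covariates = c("A", "S"),
                 n_chains = 2, n_iter = 3000, n_burn = 600, seed = 9)
  co <- coef(f_cross)
  pooled <- co[paste0("beta_S[", f_cross$frame$sites, "]")]
  unpooled <- vapply(f_cross$frame$sites, function(s)
    coef(hbm(dat, "leaf_herbivory", covariates = c("A", "S"),
             scope = "single_site", site = s, n_chains = 2,
             n_iter = 2500, n_burn = 500, seed = 9))["beta_S"], 0)
  expect_lt(var(pooled), var(unpooled))
})

test_that("model methods are coherent on a fitted object", {
  dat <- simulate_experiment(small_site(), piper_truth(), seed = 82)
  f <- fit_small(dat, seed = 10)
  expect_output(print(f), "Hierarchical Bayesian model")
  s <- summary(f)
  expect_true(all(c("parameter", "median", "lo95", "hi95", "pd") %in% names(s)))
  expect_true(all(s$lo95 <= s$median & s$median <= s$hi95))
  expect_true(all(s$pd >= 50 & s$pd <= 100))
  fit <- predict(f)
  expect_equal(length(fit), nrow(f$frame$obs))
  expect_equal(residuals(f), f$frame$obs$y - fit)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(f$frame$obs), 3))
  nd <- data.frame(site = "CostaRica", A = c(0, 1), S = c(0.5, 0.5))
  pr <- predict(f, nd)
  expect_equal(pr[2] - pr[1], unname(coef(f)["beta_A"]))
})
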