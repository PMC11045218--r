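test_that("the generator is byte-deterministic under a fixed seed", {
  a <- generate_experiment(three_sites(), piper_truth(), seed = 7)
  b <- generate_experiment(three_sites(), piper_truth(), seed = 7)
  expect_identical(a$plots, b$plots)
  expect_identical(a$leaves, b$leaves)
  expect_identical(a$plants, b$plants)
  d <- generate_experiment(three_sites(), piper_truth(), seed = 8)
  expect_false(identical(a$leaves, d$leaves))
  # byte-identical CSV output too
  t1 <- tempfile(); t2 <- tempfile()
  write_experiment(a, t1); write_experiment(b, t2)
  for (f in c("plots.csv", "leaves.csv", "plants.csv"))
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)))
  unlink(c(t1, t2), recursive = TRUE)
})

null_truth <- function(intercept = 50) {
  zero <- c(intercept = 0, W = 0, A = 0, S = 0)
  piper_truth(
    herbivory = list(mu = c(intercept = intercept, W = 0, A = 0, S = 0),
                     tau = zero, sigma = 10),
    survival = list(b_W = 0, b_A = 0, b_S = 0, b_WA = 0, tau_lambda0 = 0))
}

test_that("null treatment effects give equal group means up to MC error", {
  cfg <- small_site(n_plots_per_cell = 20L)  # 240 plots, one site
  dat <- simulate_experiment(cfg, null_truth(), seed = 31)
  lf <- dat$leaf
  m <- match(lf$plot_id, dat$plots$plot_id)
  w <- dat$plots$water[m]
  diff <- mean(lf$y_H[w == 1]) - mean(lf$y_H[w == 0])
  se <- sqrt(var(lf$y_H[w == 1]) / sum(w == 1) +
               var(lf$y_H[w == 0]) / sum(w == 0))
  expect_lt(abs(diff), 3 * se)
})

test_that("a -5pp water effect appears in raw group means (LLN oracle)", {
  tr <- piper_truth(
    herbivory = list(mu = c(intercept = 50, W = -5, A = 0, S = 0),
                     tau = c(intercept = 0, W = 0, A = 0, S = 0),
                     sigma = 10))
  cfg <- small_site(n_plots_per_cell = 17L)  # ~204 plots
  dat <- simulate_experiment(cfg, tr, seed = 32)
  lf <- dat$leaf
  m <- match(lf$plot_id, dat$plots$plot_id)
  w <- dat$plots$water[m]
  diff <- mean(lf$y_H[w == 1]) - mean(lf$y_H[w == 0])
  se <- sqrt(var(lf$y_H[w == 1]) / sum(w == 1) +
               var(lf$y_H[w == 0]) / sum(w == 0))
  expect_lt(abs(diff - (-5)), 2 * se + 0.2)
})

test_that("leaf totals and richness respect their bounds in both modes", {
  for (mode in c("gaussian", "mechanistic")) {
    dat <- simulate_experiment(piper_sites(), piper_truth(mode), seed = 33)
    expect_true(all(dat$leaf$y_H >= 0 & dat$leaf$y_H <= 100))
    cfg <- piper_sites()
    n_taxa <- setNames(vapply(cfg$taxa, nrow, 0L), cfg$site)
    expect_true(all(dat$leaf$y_R <= n_taxa[dat$leaf$site]))
    expect_true(all(dat$leaf$y_R >= 0))
    expect_true(all((dat$leaf$y_H > 0) == (dat$leaf$y_R > 0)))
  }
})

test_that("gaussian-mode residuals are Normal(0, sigma) at large n", {
  rejections <- 0L
  for (s in 1:3) {
    tr <- piper_truth(
      herbivory = list(mu = c(intercept = 50, W = -4, A = 1, S = 3),
                       tau = c(intercept = 0, W = 0, A = 0, S = 0),
                       sigma = 10),
      survival = list(log_lambda0 = log(2e-4), tau_lambda0 = 0,
                      b_W = 0, b_A = 0, b_S = 0, b_WA = 0))
    cfg <- small_site(n_plots_per_cell = 10L, mean_leaves = 6)
    dat <- simulate_experiment(cfg, tr, seed = 330 + s)
    lf <- dat$leaf
    m <- match(lf$plot_id, dat$plots$plot_id)
    eta <- 50 - 4 * dat$plots$water[m] + 1 * dat$plots$intra_high[m] +
      3 * dat$plots$S[m]
    resid <- lf$y_H - eta
    expect_gt(length(resid), 5000)
    p <- ks.test(resid / 10, "pnorm")$p.value
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 1L)
})

test_that("exponential survival matches its closed form and is monotone", {
  cfg <- small_site(n_plots_per_cell = 30L)
  pl <- data.frame(W = rep(c(0, 1), each = 2000), A = 0, S_planted = 0.5,
                   duration_days = 730)
  lam0 <- 1e-3
  tr <- piper_truth(survival = list(log_lambda0 = log(lam0), tau_lambda0 = 0,
                                    b_W = -0.7, b_A = 0, b_S = 0, b_WA = 0))
  set.seed(41)
  out <- sample_survival_times(pl, tr)
  # control arm: event fraction 1 - exp(-lambda T)
  expected0 <- 1 - exp(-lam0 * 730)
  frac0 <- mean(out$event[out$W == 0])
  expect_lt(abs(frac0 - expected0), 3 * sqrt(expected0 * (1 - expected0) / 2000))
  # watered arm has hazard exp(-0.7) * lam0 -> fewer events
  expected1 <- 1 - exp(-lam0 * exp(-0.7) * 730)
  frac1 <- mean(out$event[out$W == 1])
  expect_lt(abs(frac1 - expected1), 3 * sqrt(expected1 * (1 - expected1) / 2000))
  expect_lt(frac1, frac0)
  # raising the water hazard coefficient raises the watered-arm event rate
  tr_hi <- piper_truth(survival = list(log_lambda0 = log(lam0),
                                       tau_lambda0 = 0, b_W = 0.5,
                                       b_A = 0, b_S = 0, b_WA = 0))
  set.seed(41)
  out_hi <- sample_survival_times(pl, tr_hi)
  expect_gt(mean(out_hi$event[out_hi$W == 1]), frac1)
  # zero hazard: every plant is censored
  tr0 <- piper_truth(survival = list(log_lambda0 = -Inf, tau_lambda0 = 0,
                                     b_W = 0, b_A = 0, b_S = 0, b_WA = 0))
  out0 <- sample_survival_times(pl, tr0)
  expect_true(all(out0$event == 0))
  expect_true(all(out0$time_days == 730))
})

test_that("null water hazard gives indistinguishable KM curves", {
  dat <- simulate_experiment(small_site(n_plots_per_cell = 15L),
                             null_truth(), seed = 43)
  sf <- survival_frame(dat)
  sd_test <- survival::survdiff(
    survival::Surv(time_days, event) ~ W, data = sf)
  p <- 1 - pchisq(sd_test$chisq, 1)
  expect_gt(p, 0.01)
})

test_that("invalid configurations and truths are rejected", {
  cfg <- small_site()
  cfg$richness_levels[[1]] <- c(1L, 20L)
  expect_error(generate_experiment(cfg, piper_truth(), seed = 1),
               "pool_size")
  expect_error(piper_truth(herbivory = list(sigma = -1)), "sigma|non-positive")
  expect_error(piper_truth("banana"))
  tr <- piper_truth()
  tr$mode <- "banana"
  expect_error(generate_experiment(small_site(), tr, seed = 1), "mode")
  expect_error(generate_experiment(small_site(), piper_truth()),
               "seed")
})

test_that("mortality-driven richness loss shows up in realized richness", {
  # very high hazard: most plants die, realized richness falls below planted
  tr <- piper_truth(survival = list(log_lambda0 = log(5e-3), tau_lambda0 = 0,
                                    b_W = 0, b_A = 0, b_S = 0, b_WA = 0))
  dat <- simulate_experiment(small_site(n_plots_per_cell = 5L), tr, seed = 44)
  high <- dat$plots[dat$plots$planted_richness == 12, ]
  expect_true(mean(high$final_richness) < 12)
  expect_true(all(dat$plots$final_richness <= dat$plots$planted_richness |
                    dat$plots$final_richness <= dat$plots$pool_size))
  expect_true(all(dat$plots$S == dat$plots$final_richness / dat$plots$pool_size))
})
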