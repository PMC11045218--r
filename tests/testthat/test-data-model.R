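test_that("per-leaf responses sum, cap and count correctly", {
  dat <- tiny_data()
  lf <- dat$leaf
  l1 <- lf[lf$plant_id == "i1" & lf$leaf_id == "L1", ]
  expect_equal(l1$y_H, 8)   # Geometridae 5 + Chrysomelidae 3
  expect_equal(l1$y_R, 2L)
  l2 <- lf[lf$plant_id == "i1" & lf$leaf_id == "L2", ]
  expect_equal(l2$y_H, 0)   # marker row only
  expect_equal(l2$y_R, 0L)
  l3 <- lf[lf$plant_id == "i3" & lf$leaf_id == "L2", ]
  expect_equal(l3$y_H, 100) # 50 + 54 capped at 100
  expect_equal(l3$y_R, 2L)
})

test_that("per-plant summaries match hand calculations", {
  leaf <- data.frame(site = "s", plot_id = "p",
                     plant_id = c("a", "a", "b", "c", "c", "c"),
                     leaf_id = c("L1", "L2", "L1", "L1", "L2", "L3"),
                     y_H = c(0, 10, 5, 4, 4, 4),
                     y_R = c(0L, 1L, 1L, 1L, 1L, 1L))
  ps <- plant_responses(leaf)
  a <- ps[ps$plant_id == "a", ]
  expect_equal(a$pct_leaves_damaged, 50)
  expect_equal(a$herbivory_variance, 50)  # var({0,10}) with n-1 denominator
  b <- ps[ps$plant_id == "b", ]
  expect_true(is.na(b$herbivory_variance))
  expect_true(b$flagged)
  cc <- ps[ps$plant_id == "c", ]
  expect_equal(cc$pct_leaves_damaged, 100)
  expect_equal(cc$herbivory_variance, 0)
})

test_that("interspecific richness standardizes to the pool proportion", {
  plots <- data.frame(plot_id = c("x", "y", "z"),
                      final_richness = c(6L, 9L, 0L), pool_size = 12L)
  out <- standardize_richness(plots)
  expect_equal(out$S, c(0.5, 0.75, 0))
  expect_equal(out$excluded, c(FALSE, FALSE, TRUE))
  expect_error(standardize_richness(
    data.frame(plot_id = "x", final_richness = 1L, pool_size = 0L)),
    "pool_size")
})

test_that("a well-formed experiment round-trips through CSV with no issues", {
  tt <- tiny_tables()
  dat_mem <- as_piper_data(tt$plots, tt$leaves, tt$plants)
  expect_length(dat_mem$issues, 0)
  dir <- tempfile(); dir.create(dir)
  write.csv(tt$plots, file.path(dir, "plots.csv"), row.names = FALSE, na = "")
  write.csv(tt$leaves, file.path(dir, "leaves.csv"), row.names = FALSE, na = "")
  write.csv(tt$plants, file.path(dir, "plants.csv"), row.names = FALSE, na = "")
  dat <- read_experiment(file.path(dir, "plots.csv"),
                         file.path(dir, "leaves.csv"),
                         file.path(dir, "plants.csv"))
  expect_length(dat$issues, 0)
  expect_equal(dat$leaf$y_H, dat_mem$leaf$y_H)
  expect_equal(dat$plots$S, dat_mem$plots$S)
  unlink(dir, recursive = TRUE)
})

test_that("schema violations are rejected with informative errors", {
  tt <- tiny_tables()
  bad <- tt$leaves
  bad$damage_pct[2] <- 150
  expect_error(as_piper_data(tt$plots, bad, tt$plants), "\\[0, 100\\].*2")
  orphan <- tt$leaves
  orphan$plot_id[1] <- "nope"
  expect_error(as_piper_data(tt$plots, orphan, tt$plants), "orphan leaf")
  orphan_p <- tt$plants
  orphan_p$plot_id[1] <- "nope"
  expect_error(as_piper_data(tt$plots, tt$leaves, orphan_p), "orphan plant")
  dir <- tempfile(); dir.create(dir)
  write.csv(tt$plots[, -3], file.path(dir, "plots.csv"), row.names = FALSE)
  write.csv(tt$leaves, file.path(dir, "leaves.csv"), row.names = FALSE)
  write.csv(tt$plants, file.path(dir, "plants.csv"), row.names = FALSE)
  expect_error(read_experiment(file.path(dir, "plots.csv"),
                               file.path(dir, "leaves.csv"),
                               file.path(dir, "plants.csv")),
               "missing required column.*block")
  unlink(dir, recursive = TRUE)
})

test_that("derived quantities are invariant to row order", {
  dat <- simulate_experiment(small_site(), piper_truth(), seed = 51)
  tt <- list(plots = dat$plots[, !(names(dat$plots) %in% c("S", "excluded"))],
             leaves = dat$leaves, plants = dat$plants)
  set.seed(1)
  perm <- tt
  perm$leaves <- perm$leaves[sample(nrow(perm$leaves)), ]
  perm$plots <- perm$plots[sample(nrow(perm$plots)), ]
  a <- as_piper_data(tt$plots, tt$leaves, tt$plants)
  b <- as_piper_data(perm$plots, perm$leaves, perm$plants)
  key <- function(d) d[order(d$plant_id, d$leaf_id), c("y_H", "y_R")]
  expect_equal(key(a$leaf), key(b$leaf), ignore_attr = TRUE)
  sa <- site_summary(a); sb <- site_summary(b)
  expect_equal(sa, sb)
})

test_that("damage richness responds only to zero/nonzero transitions", {
  tt <- tiny_tables()
  base <- as_piper_data(tt$plots, tt$leaves, tt$plants)$leaf
  within_range <- tt$leaves
  within_range$damage_pct[1] <- 77  # Geometridae 5 -> 77, still > 0
  lf <- as_piper_data(tt$plots, within_range, tt$plants)$leaf
  expect_equal(lf$y_R, base$y_R)
  zeroed <- tt$leaves
  zeroed$damage_pct[1] <- 0
  lf0 <- as_piper_data(tt$plots, zeroed, tt$plants)$leaf
  i <- which(lf0$plant_id == "i1" & lf0$leaf_id == "L1")
  expect_equal(lf0$y_R[i], base$y_R[base$plant_id == "i1" &
                                      base$leaf_id == "L1"] - 1L)
})

test_that("site summaries equal brute-force averages", {
  dat <- simulate_experiment(three_sites(), piper_truth("mechanistic"),
                             seed = 52)
  sm <- site_summary(dat)
  for (s in unique(dat$plots$site)) {
    expect_equal(sm$mean_herbivory[sm$site == s],
                 mean(dat$leaf$y_H[dat$leaf$site == s]))
    expect_equal(sm$mortality_pct[sm$site == s],
                 100 * mean(dat$plants$event[dat$plants$site == s]))
  }
  # hand-built specialist share: 60 of 100 damage units from specialists
  tt <- tiny_tables()
  tt$leaves$damage_pct <- c(25, 15, 0, 30, 0, 20, 10, 0)
  # specialists among taxa present: Eois (rows 4, 6); total = 100, spec = 50
  d2 <- as_piper_data(tt$plots, tt$leaves, tt$plants)
  sm2 <- site_summary(d2, specialists = "Eois")
  expect_equal(sm2$specialist_share, 50)
  # all plants dead -> 100% mortality
  tt$plants$event <- 1L
  tt$plants$time_days <- c(10, 20, 30)
  d3 <- as_piper_data(tt$plots, tt$leaves, tt$plants)
  expect_equal(site_summary(d3)$mortality_pct, 100)
})
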