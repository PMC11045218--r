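# shared fixtures built in code

# single-site configuration kept small for fast model fits
small_site <- function(site = "CostaRica", n_plots_per_cell = 2L,
                       mean_leaves = 4) {
  piper_sites(n_plots_per_cell = n_plots_per_cell,
              mean_leaves_per_plant = mean_leaves, sites = site)
}

three_sites <- function(n_plots_per_cell = 2L) {
  piper_sites(n_plots_per_cell = n_plots_per_cell,
              sites = c("CostaRica", "Ecuador", "Peru"))
}

# generator truth used for recovery/calibration simulations: mortality held
# at a fixed moderate level so the realized design keeps within-site
# variation in every covariate
recovery_truth <- function(...) {
  piper_truth(survival = list(log_lambda0 = log(3e-4), tau_lambda0 = 0.3,
                              b_W = -0.2, b_A = -0.2, b_S = 0, b_WA = 0),
              ...)
}

# a tiny hand-written experiment: 2 plots, 3 plants, 4 leaves; no all-dead
# plots, no single-leaf plants, so validation produces no flags
tiny_tables <- function() {
  plots <- data.frame(
    site = "CostaRica", plot_id = c("p1", "p2"), block = "",
    water = c(0L, 1L), intra_high = c(0L, 1L),
    planted_richness = c(2L, 6L), final_richness = c(2L, 6L),
    pool_size = 12L, stringsAsFactors = FALSE)
  leaves <- data.frame(
    site = "CostaRica",
    plot_id = c("p1", "p1", "p1", "p1", "p1", "p2", "p2", "p2"),
    plant_id = c("i1", "i1", "i1", "i2", "i2", "i3", "i3", "i3"),
    leaf_id = c("L1", "L1", "L2", "L1", "L2", "L1", "L2", "L2"),
    taxon = c("Geometridae", "Chrysomelidae", "", "Eois", "",
              "Eois", "Orthoptera", "Eois"),
    damage_pct = c(5, 3, 0, 9, 0, 60, 50, 54),
    stringsAsFactors = FALSE)
  plants <- data.frame(
    site = "CostaRica", plot_id = c("p1", "p1", "p2"),
    plant_id = c("i1", "i2", "i3"),
    species = c("sp01", "sp02", "sp01"),
    time_days = c(700, 700, 350), event = c(0L, 0L, 1L),
    stringsAsFactors = FALSE)
  list(plots = plots, leaves = leaves, plants = plants)
}

tiny_data <- function() {
  tt <- tiny_tables()
  as_piper_data(tt$plots, tt$leaves, tt$plants)
}
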