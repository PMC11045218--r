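#' Read and validate the three experiment tables
#'
#' Loads the plot-treatment, leaf-damage and plant-survival CSVs, enforces
#' the schemas, checks cross-referential integrity (every leaf and plant must
#' reference a known plot) and derives all modelled responses: per-leaf total
#' herbivory and damage-taxon richness, per-plant summaries, and the
#' standardized interspecific richness covariate.
#'
#' Expected schemas (comma-separated, UTF-8, header required, empty string =
#' missing):
#' \itemize{
#'   \item `plots.csv`: site, plot_id, block, water (0/1/empty for sites
#'     without the treatment), intra_high (0/1), planted_richness,
#'     final_richness, pool_size
#'   \item `leaves.csv`: site, plot_id, plant_id, leaf_id, taxon, damage_pct.
#'     One row per taxon per leaf; an absent taxon row means zero damage.
#'     A leaf with no damage at all appears as one row with an empty taxon
#'     and damage 0 (a leaf-presence marker).
#'   \item `plants.csv`: site, plot_id, plant_id, species, time_days,
#'     event (0 censored / 1 died)
#' }
#'
#' @param plots_path,leaves_path,plants_path CSV file paths.
#' @return An object of class `piper_data` (see [as_piper_data()]).
#' @export
read_experiment <- function(plots_path, leaves_path, plants_path) {
  rd <- function(path, cols) {
    if (!file.exists(path)) stop("file not found: ", path)
    x <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("missing required column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "))
    x
  }
  plots <- rd(plots_path, c("site", "plot_id", "block", "water", "intra_high",
                            "planted_richness", "final_richness", "pool_size"))
  leaves <- rd(leaves_path, c("site", "plot_id", "plant_id", "leaf_id",
                              "taxon", "damage_pct"))
  plants <- rd(plants_path, c("site", "plot_id", "plant_id", "species",
                              "time_days", "event"))
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  plots$water <- as.integer(num(plots$water))
  plots$intra_high <- as.integer(num(plots$intra_high))
  plots$planted_richness <- as.integer(num(plots$planted_richness))
  plots$final_richness <- as.integer(num(plots$final_richness))
  plots$pool_size <- as.integer(num(plots$pool_size))
  leaves$damage_pct <- num(leaves$damage_pct)
  plants$time_days <- num(plants$time_days)
  plants$event <- as.integer(num(plants$event))
  build_piper_data(plots, leaves, plants)
}

#' Assemble a `piper_data` analysis object from in-memory tables
#'
#' Accepts either a [generate_experiment()] result or the three raw tables,
#' validates them and derives every response the models consume.
#'
#' @param x A `piper_experiment`, or a plots data.frame.
#' @param leaves,plants Raw leaf and plant tables when `x` is a data.frame.
#' @return Object of class `piper_data` with components `plots` (including
#'   the standardized richness `S` and an `excluded` flag for plots whose
#'   plants all died), `leaves` (raw long damage rows), `leaf` (one row per
#'   leaf with `y_H`, `y_R`), `plant_summary` (per-plant percent leaves
#'   damaged, within-plant herbivory variance, `flagged` when fewer than two
#'   leaves), `plants` (survival records) and `issues` (validation report).
#' @export
as_piper_data <- function(x, leaves = NULL, plants = NULL) {
  if (inherits(x, "piper_experiment"))
    return(build_piper_data(x$plots, x$leaves, x$plants))
  build_piper_data(x, leaves, plants)
}

build_piper_data <- function(plots, leaves, plants) {
  issues <- character()

  if (anyDuplicated(plots$plot_id))
    stop("duplicate plot_id in plots table")
  bad <- which(!is.na(leaves$damage_pct) &
                 (leaves$damage_pct < 0 | leaves$damage_pct > 100))
  if (length(bad))
    stop("damage_pct outside [0, 100] in leaves row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(is.na(leaves$damage_pct)))
    stop("missing damage_pct in leaves row(s): ",
         paste(utils::head(which(is.na(leaves$damage_pct)), 5), collapse = ", "))
  orphan_leaf <- !(leaves$plot_id %in% plots$plot_id)
  if (any(orphan_leaf))
    stop("orphan leaf record(s): plot_id not found for leaves row(s) ",
         paste(utils::head(which(orphan_leaf), 5), collapse = ", "))
  orphan_plant <- !(plants$plot_id %in% plots$plot_id)
  if (any(orphan_plant))
    stop("orphan plant record(s): plot_id not found for plants row(s) ",
         paste(utils::head(which(orphan_plant), 5), collapse = ", "))
  if (!all(plants$event %in% c(0L, 1L)))
    stop("plants$event must be 0 or 1")
  if (any(plants$time_days <= 0 | is.na(plants$time_days)))
    stop("plants$time_days must be positive")
  if (any(is.na(plots$final_richness) | plots$final_richness < 0 |
            plots$final_richness > plots$pool_size))
    stop("final_richness must lie in [0, pool_size]")

  plots <- standardize_richness(plots)
  if (any(plots$excluded))
    issues <- c(issues, paste0("plot ", plots$plot_id[plots$excluded],
                               ": all plants dead; excluded from herbivory models"))

  leaf <- leaf_responses(leaves)
  plant_summary <- plant_responses(leaf)
  if (any(plant_summary$flagged))
    issues <- c(issues,
                paste0("plant ", plant_summary$plant_id[plant_summary$flagged],
                       ": single leaf; excluded from variance analyses"))

  structure(list(plots = plots, leaves = leaves, leaf = leaf,
                 plant_summary = plant_summary, plants = plants,
                 issues = issues),
            class = "piper_data")
}

#' @export
print.piper_data <- function(x, ...) {
  cat("Piper experiment data:", nrow(x$plots), "plots,",
      nrow(x$plants), "plants,", nrow(x$leaf), "leaves,",
      length(unique(x$plots$site)), "site(s)\n")
  if (length(x$issues)) cat(" ", length(x$issues), "validation flags\n")
  invisible(x)
}

#' Derive per-leaf responses from long-format damage rows
#'
#' Total herbivory `y_H` is the per-leaf sum of taxon damages, capped at 100
#' (taxa can overlap on a leaf); damage richness `y_R` counts taxa with
#' strictly positive damage. Empty-taxon marker rows contribute a leaf with
#' zero damage. Results are independent of row order.
#'
#' @param leaves Long-format leaf table (site, plot_id, plant_id, leaf_id,
#'   taxon, damage_pct).
#' @return One row per leaf with `y_H` and `y_R`.
#' @export
leaf_responses <- function(leaves) {
  key <- paste(leaves$plot_id, leaves$plant_id, leaves$leaf_id, sep = "\r")
  first <- !duplicated(key)
  out <- leaves[first, c("site", "plot_id", "plant_id", "leaf_id")]
  real <- leaves$taxon != "" & leaves$damage_pct > 0
  sums <- rowsum(leaves$damage_pct[real], key[real])
  cnts <- rowsum(rep(1L, sum(real)), key[real])
  ord <- match(key[first], rownames(sums))
  out$y_H <- ifelse(is.na(ord), 0, pmin(100, sums[ord]))
  out$y_R <- ifelse(is.na(ord), 0L, cnts[ord])
  rownames(out) <- NULL
  out
}

#' Derive per-plant herbivory summaries
#'
#' @param leaf Per-leaf table from [leaf_responses()].
#' @return One row per plant: `n_leaves`, `pct_leaves_damaged` (percent of
#'   leaves with any damage) and `herbivory_variance` (sample variance, n-1
#'   denominator, of leaf herbivory within the plant; `NA` and `flagged` for
#'   plants with a single leaf).
#' @export
plant_responses <- function(leaf) {
  key <- paste(leaf$plot_id, leaf$plant_id, sep = "\r")
  first <- !duplicated(key)
  out <- leaf[first, c("site", "plot_id", "plant_id")]
  n <- as.vector(rowsum(rep(1L, nrow(leaf)), key))
  dam <- as.vector(rowsum(as.numeric(leaf$y_H > 0), key))
  sx <- as.vector(rowsum(leaf$y_H, key))
  sxx <- as.vector(rowsum(leaf$y_H^2, key))
  ord <- match(key[first], sort(unique(key)))
  n <- n[ord]; dam <- dam[ord]; sx <- sx[ord]; sxx <- sxx[ord]
  out$n_leaves <- n
  out$pct_leaves_damaged <- 100 * dam / n
  v <- (sxx - sx^2 / n) / (n - 1)
  v[n < 2] <- NA_real_
  out$herbivory_variance <- pmax(v, 0)
  out$flagged <- n < 2
  rownames(out) <- NULL
  out
}

#' Standardize interspecific richness to the proportion of the site pool
#'
#' Adds `S = final_richness / pool_size` (in [0, 1]) and flags plots whose
#' plants all died (`final_richness == 0`) for exclusion from herbivory
#' models; they are retained for survival analysis.
#'
#' @param plots Plot-treatment table.
#' @return `plots` with columns `S` and `excluded` added.
#' @export
standardize_richness <- function(plots) {
  if (any(plots$pool_size <= 0)) stop("pool_size must be positive")
  plots$S <- plots$final_richness / plots$pool_size
  plots$excluded <- plots$final_richness == 0L
  plots
}

#' Per-site descriptive summary
#'
#' @param data A `piper_data` object.
#' @param specialists Character vector of specialist taxon labels used for
#'   the specialist damage share; defaults to the specialist taxa of
#'   [piper_sites()].
#' @return Data.frame with one row per site: mean leaf herbivory (percent),
#'   plant mortality (percent), number of distinct damage taxa, and the
#'   specialist share of total damage (percent; `NA` where no damage).
#' @export
site_summary <- function(data, specialists = NULL) {
  stopifnot(inherits(data, "piper_data"))
  if (is.null(specialists)) {
    cfg <- piper_sites()
    tax <- do.call(rbind, cfg$taxa)
    specialists <- unique(tax$taxon[tax$specialist])
  }
  sites <- sort(unique(data$plots$site))
  res <- lapply(sites, function(s) {
    lf <- data$leaf[data$leaf$site == s, ]
    lv <- data$leaves[data$leaves$site == s & data$leaves$taxon != "" &
                        data$leaves$damage_pct > 0, ]
    pl <- data$plants[data$plants$site == s, ]
    tot <- sum(lv$damage_pct)
    data.frame(
      site = s,
      mean_herbivory = if (nrow(lf)) mean(lf$y_H) else NA_real_,
      mortality_pct = if (nrow(pl)) 100 * mean(pl$event) else NA_real_,
      n_damage_taxa = length(unique(lv$taxon)),
      specialist_share = if (tot > 0)
        100 * sum(lv$damage_pct[lv$taxon %in% specialists]) / tot
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate, assemble and derive in one step
#'
#' Convenience wrapper: [generate_experiment()] followed by
#' [as_piper_data()]. The generator truth is attached as attribute `truth`
#' and the realized per-site coefficients as attribute `site_truth`.
#'
#' @inheritParams generate_experiment
#' @return A `piper_data` object ready for [hbm()], [bsem()] and the
#'   survival functions.
#' @export
simulate_experiment <- function(configs = piper_sites(),
                                truth = piper_truth(), seed) {
  exp <- generate_experiment(configs, truth, seed)
  dat <- as_piper_data(exp)
  attr(dat, "truth") <- exp$truth
  attr(dat, "site_truth") <- exp$site_truth
  attr(dat, "seed") <- exp$seed
  dat
}
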