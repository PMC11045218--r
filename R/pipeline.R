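#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates an end-to-end run: simulate (or ingest) the experiment
#' tables, derive responses, fit the configured hierarchical Bayesian
#' models, BSEM variants and survival models, run convergence and fit
#' diagnostics, and write all summaries plus run metadata to an output
#' directory. Every fitted model's split R-hat is checked against 1.1; a
#' failing model is refit once at doubled iterations (doubling the burn-in
#' too), and an error is raised if it still fails.
#'
#' The configuration is a YAML file or an equivalent named list:
#' \preformatted{
#' seed: 1
#' out: runs/demo
#' simulate:            # exactly one of `simulate` / `input`
#'   sites: [CostaRica, Ecuador, Peru]
#'   mode: gaussian
#'   n_plots_per_cell: 2
#' input:
#'   plots: plots.csv
#'   leaves: leaves.csv
#'   plants: plants.csv
#' mcmc: {chains: 3, iters: 5000, burnin: 500}
#' hbm:
#'   - {response: leaf_herbivory, covariates: [W, A, S]}
#' bsem:
#'   sites: [CostaRica]
#'   variants: [I, II, III]
#' survival:
#'   covariates: [W, A, S_planted]
#'   per_site: true
#' }
#'
#' @param config Path to a YAML file or a named list.
#' @param out Output directory; overrides `config$out`.
#' @return Invisibly, a list with the fitted objects, all summary tables and
#'   the run metadata. Side effect: CSV/JSON outputs in the run directory.
#' @export
run_full_analysis <- function(config, out = NULL) {
  t0 <- Sys.time()
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out <- out %||% config$out %||% stop("no output directory configured")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  mc <- config$mcmc %||% list()
  chains <- as.integer(mc$chains %||% 3L)
  iters <- as.integer(mc$iters %||% 10000L)
  burnin <- as.integer(mc$burnin %||% 1000L)
  log <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    val <- force(expr)
    log[[name]] <<- list(seconds = as.numeric(Sys.time() - st, units = "secs"))
    val
  }

  data <- if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfgs <- piper_sites(
      n_plots_per_cell = as.integer(sc$n_plots_per_cell %||% 2L),
      plants_per_plot = as.integer(sc$plants_per_plot %||% 12L),
      mean_leaves_per_plant = sc$mean_leaves_per_plant %||% 6,
      sites = sc$sites %||% c("CostaRica", "Ecuador", "Peru", "Mogi",
                              "Uaimii"))
    stage("simulate",
          simulate_experiment(cfgs, piper_truth(sc$mode %||% "gaussian"),
                              seed = seed))
  } else {
    stage("ingest", read_experiment(config$input$plots, config$input$leaves,
                                    config$input$plants))
  }
  log$records <- list(plots = nrow(data$plots), plants = nrow(data$plants),
                      leaves = nrow(data$leaf))

  water_sites <- unique(data$plots$site[!is.na(data$plots$water)])
  check_water <- function(sites_requested, what) {
    bad <- setdiff(sites_requested, water_sites)
    if (length(bad))
      stop("config requests water-treatment ", what, " at site(s) without ",
           "the water treatment: ", paste(bad, collapse = ", "))
  }

  fit_with_retry <- function(fit_fun, label) {
    f <- fit_fun(iters, burnin)
    if (!is.null(f$rhat) && max(f$rhat) > 1.1) {
      log[[paste0("retry_", label)]] <<- list(max_rhat = max(f$rhat))
      f <- fit_fun(2L * iters, 2L * burnin)
      if (!is.null(f$rhat) && max(f$rhat) > 1.1)
        stop("model ", label, " failed to converge after a doubled-iteration ",
             "re-run (max R-hat ", sprintf("%.3f", max(f$rhat)), ")")
    }
    f
  }

  hbm_fits <- list(); hbm_rows <- list()
  for (spec in config$hbm %||% list()) {
    cov <- unlist(spec$covariates)
    scope <- spec$scope %||% "cross_site"
    if ("W" %in% cov && !is.null(spec$site)) check_water(spec$site, "models")
    label <- paste0(spec$response, if (!is.null(spec$site))
      paste0("@", spec$site))
    f <- fit_with_retry(function(it, bu)
      hbm(data, spec$response, covariates = cov,
          interactions = unlist(spec$interactions),
          scope = scope, site = spec$site,
          n_chains = chains, n_iter = it, n_burn = bu, seed = seed),
      label)
    hbm_fits[[label]] <- f
    sm <- summary(f)
    sm <- cbind(model = label, sm)
    sm$ppc <- unname(ppc(f))
    hbm_rows[[label]] <- sm
  }
  if (length(hbm_rows))
    utils::write.csv(do.call(rbind, hbm_rows),
                     file.path(out, "hbm_summaries.csv"), row.names = FALSE)

  bsem_fits <- list(); bsem_cmp <- NULL; bsem_paths_rows <- list()
  if (!is.null(config$bsem)) {
    bs <- config$bsem
    variants <- unlist(bs$variants %||% list("I", "II", "III"))
    for (s in unlist(bs$sites)) {
      if (any(variants != "no_water")) check_water(s, "path models")
      fits <- lapply(variants, function(v)
        fit_with_retry(function(it, bu)
          bsem(data, s, variant = v, n_chains = chains, n_iter = it,
               n_burn = bu, seed = seed), paste0("bsem_", v, "@", s)))
      names(fits) <- variants
      bsem_fits[[s]] <- fits
      if (length(fits) >= 2) {
        cmp <- compare_bsem(fits)
        cmp <- cbind(site = s, cmp)
        bsem_cmp <- rbind(bsem_cmp, cmp)
        best <- fits[[attr(compare_bsem(fits), "selected")]]
      } else best <- fits[[1]]
      sc <- standardized_coefficients(best)
      bsem_paths_rows[[s]] <- cbind(site = s, variant = best$variant, sc)
    }
    if (!is.null(bsem_cmp))
      utils::write.csv(bsem_cmp, file.path(out, "bsem_comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(do.call(rbind, bsem_paths_rows),
                     file.path(out, "bsem_paths.csv"), row.names = FALSE)
  }

  cox_rows <- list(); km_all <- NULL
  if (!is.null(config$survival)) {
    sv <- config$survival
    sf <- survival_frame(data)
    per_site <- isTRUE(sv$per_site %||% TRUE)
    groups <- if (per_site) split(sf, sf$site) else list(all = sf)
    for (g in names(groups)) {
      rec <- groups[[g]]
      cov <- unlist(sv$covariates %||% list("A", "S_planted"))
      if ("W" %in% cov && !all(rec$has_water_treatment)) {
        if (per_site) cov <- setdiff(cov, "W") else
          stop("water covariate requested for sites without the treatment")
      }
      cov <- cov[vapply(cov, function(cv)
        length(unique(rec[[cv]])) > 1, TRUE)]
      if (!length(cov) || sum(rec$event) == 0) next
      cf <- fit_cox(rec, cov, interactions = unlist(sv$interactions))
      cox_rows[[g]] <- cbind(site = g, cf$coefficients)
      grp <- intersect(c("W", "A"), cov)
      km <- km_curves(rec, if (length(grp)) grp[1] else NULL)
      km_all <- rbind(km_all, cbind(site = g, km))
    }
    if (length(cox_rows))
      utils::write.csv(do.call(rbind, cox_rows), file.path(out, "cox.csv"),
                       row.names = FALSE)
    if (!is.null(km_all))
      utils::write.csv(km_all, file.path(out, "km.csv"), row.names = FALSE)
  }

  utils::write.csv(site_summary(data), file.path(out, "site_summary.csv"),
                   row.names = FALSE)

  meta <- list(
    seed = seed,
    config_hash = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else
        unname(tools::md5sum(textConnection_hash(config))),
    mcmc = list(chains = chains, iters = iters, burnin = burnin),
    version = as.character(utils::packageVersion("divherb")),
    stages = log,
    total_seconds = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(meta, file.path(out, "run.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(data = data, hbm = hbm_fits, bsem = bsem_fits,
                 bsem_comparison = bsem_cmp, cox = cox_rows, meta = meta))
}

textConnection_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp)
  tmp
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML path")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$input)
  if (has_sim == has_in)
    stop("config must contain exactly one of `simulate` or `input`")
  if (has_in) {
    need <- c("plots", "leaves", "plants")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("config$input lacks: ", paste(miss, collapse = ", "))
  }
  for (spec in config$hbm %||% list()) {
    if (is.null(spec$response)) stop("each hbm entry needs a `response`")
  }
  if (!is.null(config$bsem)) {
    bad <- setdiff(unlist(config$bsem$variants %||% list()),
                   c("I", "II", "III", "no_water"))
    if (length(bad)) stop("unknown BSEM variant(s): ",
                          paste(bad, collapse = ", "))
    if (is.null(config$bsem$sites)) stop("config$bsem needs `sites`")
  }
  invisible(config)
}
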