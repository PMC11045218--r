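#' Plant-level survival model frame
#'
#' Joins the plant survival records with their plot treatments. Survival
#' models use the planted (not realized) interspecific richness, because
#' mortality occurs early and itself drives richness loss.
#'
#' @param data A `piper_data` object.
#' @return Data.frame with columns site, plot_id, plant_id, species,
#'   time_days, event, `W` (0 for sites without the treatment), `A`, and
#'   `S_planted` (planted richness / pool size).
#' @export
survival_frame <- function(data) {
  stopifnot(inherits(data, "piper_data"))
  pl <- data$plants
  m <- match(pl$plot_id, data$plots$plot_id)
  pl$W <- ifelse(is.na(data$plots$water[m]), 0L, data$plots$water[m])
  pl$has_water_treatment <- !is.na(data$plots$water[m])
  pl$A <- data$plots$intra_high[m]
  pl$S_planted <- data$plots$planted_richness[m] / data$plots$pool_size[m]
  pl
}

#' Kaplan-Meier survivorship curves
#'
#' Product-limit estimates by group, via [survival::survfit()].
#'
#' @param records Data.frame with `time_days` and `event` (0 censored /
#'   1 died) — e.g. [survival_frame()] output, optionally subset to a site.
#' @param grouping Name of a grouping column in `records`, a vector of such
#'   names (crossed), or `NULL` for one overall curve.
#' @return Data.frame of class `km_curves`: group, time, survival, at_risk,
#'   events. `S(0) = 1`; the curve is non-increasing within each group.
#' @export
km_curves <- function(records, grouping = NULL) {
  if (any(records$time_days < 0)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1))) stop("event must be coded 0/1")
  g <- if (is.null(grouping)) rep("all", nrow(records))
       else interaction(records[grouping], sep = ":", drop = TRUE)
  fit <- survival::survfit(
    survival::Surv(records$time_days, records$event) ~ g)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time))
         else sub("^g=", "", as.character(sm$strata))
  out <- data.frame(group = grp, time = sm$time, survival = sm$surv,
                    at_risk = sm$n.risk, events = sm$n.event,
                    stringsAsFactors = FALSE)
  class(out) <- c("km_curves", "data.frame")
  out
}

km_at <- function(km, group, t) {
  cur <- km[km$group == group, ]
  if (nrow(cur) == 0) stop("group not found in curves: ", group)
  keep <- cur$time <= t
  if (!any(keep)) return(1)
  cur$survival[max(which(keep))]
}

#' Cox proportional-hazards fit for plant mortality
#'
#' Maximizes the partial likelihood by Newton iteration (through
#' [survival::coxph()]) with the Efron tie correction by default. Species
#' identity, when requested, enters as reference-coded categories.
#'
#' @param records A [survival_frame()] data.frame (subset to one site for
#'   site-level fits).
#' @param covariates Character vector of covariate column names, e.g.
#'   `c("W", "A", "S_planted")` or `"species"`.
#' @param interactions Optional character vector of `"x:y"` interaction
#'   terms, e.g. `"A:W"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: a list with `coefficients`
#'   (data.frame: term, beta, se, z, p), `ties`, `converged`, `n`, `n_event`
#'   and the underlying `coxph` fit.
#' @export
fit_cox <- function(records, covariates, interactions = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1) stop("no events: all subjects are censored")
  for (cv in covariates) {
    if (!cv %in% names(records)) stop("unknown covariate: ", cv)
    if (length(unique(records[[cv]])) < 2)
      stop("covariate is constant across subjects: ", cv,
           " (unidentifiable)")
  }
  rhs <- paste(c(covariates, interactions), collapse = " + ")
  records$species <- if ("species" %in% names(records))
    factor(records$species) else NULL
  fml <- stats::as.formula(paste(
    "survival::Surv(time_days, event) ~", rhs))
  fit <- survival::coxph(fml, data = records, ties = ties)
  if (any(is.na(stats::coef(fit))))
    stop("Cox fit produced undefined coefficients (collinear covariates?)")
  s <- summary(fit)
  co <- data.frame(term = rownames(s$coefficients),
                   beta = s$coefficients[, "coef"],
                   se = s$coefficients[, "se(coef)"],
                   z = s$coefficients[, "z"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE)
  rownames(co) <- NULL
  structure(list(coefficients = co, ties = ties,
                 converged = all(is.finite(co$beta)) && all(co$se > 0),
                 n = s$n, n_event = sum(records$event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), ",
      x$n, " subjects, ", x$n_event, " events\n", sep = "")
  print(transform(x$coefficients,
                  beta = round(beta, 4), se = round(se, 4),
                  z = round(z, 2), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' End-of-study percent survival difference between groups
#'
#' 100 * (S_treat(T) - S_ref(T)) / S_ref(T) evaluated at the last observed
#' time T of the curves. This is a descriptive effect size; inferential
#' weight rests on the Cox z and p values.
#'
#' @param km A `km_curves` object.
#' @param treat,ref Group labels present in `km$group`.
#' @return Scalar percent difference.
#' @export
survival_effect_percent <- function(km, treat, ref) {
  t_end <- max(km$time)
  s_t <- km_at(km, treat, t_end)
  s_r <- km_at(km, ref, t_end)
  if (s_r == 0) stop("reference group survival is zero at end of study")
  100 * (s_t - s_r) / s_r
}
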