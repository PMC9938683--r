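# Estimation stage: nested Cox models for the timing groups, Fine-Gray
# competing-risk regression, and FDR correction. Penalized-spline
# dose-response and standardization live in spline-models.R; interaction and
# subgroup analyses in interaction.R.

#' Covariate sets of the nested adjustment models
#'
#' Model 1: age, sex. Model 2 adds ethnicity, deprivation, region, education,
#' season of wear, diet score, smoking, alcohol. Model 3 adds sleep duration,
#' sleep midpoint, and total weekly MVPA volume. The sets are strictly nested.
#'
#' @param level 1, 2, or 3.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(level = 3) {
  stopifnot(level %in% 1:3)
  m1 <- c("age", "sex")
  m2 <- c(m1, "ethnicity", "deprivation", "region", "education",
          "wear_season", "diet_score", "smoking", "alcohol")
  m3 <- c(m2, "sleep_duration", "sleep_midpoint", "weekly_mvpa")
  switch(level, m1, m2, m3)
}

# event indicator for an outcome; all_cause pools every recorded cause
outcome_status <- function(cohort, outcome) {
  ev <- as.character(cohort$event_cause)
  if (outcome == "all_cause") as.integer(ev != "none")
  else {
    if (!outcome %in% levels(cohort$event_cause)) {
      stop("unknown outcome '", outcome, "'", call. = FALSE)
    }
    as.integer(ev == outcome)
  }
}

cox_formula <- function(covs, exposure = "timing_group") {
  as.formula(paste("survival::Surv(follow_up_years, .status) ~",
                   paste(c(exposure, covs), collapse = " + ")))
}

#' Cox proportional hazards fit for the timing groups
#'
#' Partial-likelihood estimation (Efron ties) of the hazard ratios of the
#' midday-afternoon, evening, and mixed groups versus the reference, under one
#' of the nested adjustment models. Events and person-years are reported per
#' group. A warning is logged when the events-per-parameter rule of thumb
#' (at least 10) is violated.
#'
#' @param cohort Analysis-ready cohort tibble with `timing_group`,
#'   `follow_up_years`, `event_cause`, and the model covariates.
#' @param outcome `"all_cause"` or one of the recorded causes.
#' @param model Adjustment level 1-3 (see [model_covariates()]), or a
#'   character vector of covariate names.
#' @param reference Reference timing group (default morning).
#' @return A tibble of class `timing_fit` with one row per group (the
#'   reference row carries HR 1): `outcome`, `model`, `group`, `events`,
#'   `person_years`, `hr`, `ci_low`, `ci_high`, `p`. The `coxph` fit is
#'   attached as attribute `"fit"`.
#' @export
fit_timing_cox <- function(cohort, outcome, model = 3,
                           reference = "morning") {
  covs <- if (is.character(model)) model else model_covariates(model)
  missing_covs <- setdiff(covs, names(cohort))
  if (length(missing_covs)) {
    stop("cohort lacks covariate(s): ", paste(missing_covs, collapse = ", "),
         call. = FALSE)
  }
  d <- as.data.frame(cohort)
  d$timing_group <- stats::relevel(factor(d$timing_group), ref = reference)
  d$.status <- outcome_status(cohort, outcome)
  fit <- survival::coxph(cox_formula(covs), data = d, ties = "efron")
  if (anyNA(coef(fit))) {
    stop("Cox fit failed to converge; NA coefficients for ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  if (fit$nevent / length(coef(fit)) < 10) {
    warning(sprintf("only %.1f events per parameter (< 10 rule of thumb)",
                    fit$nevent / length(coef(fit))))
  }
  sm <- summary(fit)
  groups <- levels(d$timing_group)
  ev <- tapply(d$.status, d$timing_group, sum)
  py <- tapply(d$follow_up_years, d$timing_group, sum)
  rows <- lapply(groups, function(g) {
    if (g == reference) {
      tibble::tibble(group = g, events = ev[[g]], person_years = py[[g]],
                     hr = 1, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_)
    } else {
      cn <- paste0("timing_group", g)
      tibble::tibble(group = g, events = ev[[g]], person_years = py[[g]],
                     hr = sm$conf.int[cn, "exp(coef)"],
                     ci_low = sm$conf.int[cn, "lower .95"],
                     ci_high = sm$conf.int[cn, "upper .95"],
                     p = sm$coefficients[cn, "Pr(>|z|)"])
    }
  })
  out <- do.call(rbind, rows)
  out <- tibble::tibble(outcome = outcome,
                        model = if (is.character(model)) "custom" else model,
                        out)
  attr(out, "fit") <- fit
  class(out) <- c("timing_fit", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment with monotonicity enforcement, delegated to
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA`s passed through).
#' @return Adjusted p-values of the same length.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Fine-Gray subdistribution hazards for one cause
#'
#' Subdistribution hazard ratios of the timing groups under competing risks,
#' via the weighted estimating equations of `cmprsk::crr()`; deaths from any
#' other cause are the competing event. With no competing events the
#' subdistribution risk sets coincide with the cause-specific ones and the fit
#' reduces to the Cox model (noted in the output).
#'
#' @inheritParams fit_timing_cox
#' @param cause One of the recorded causes (not `"all_cause"`).
#' @return Tibble with one row per non-reference group: `group`, `shr`
#'   (subdistribution HR), `ci_low`, `ci_high`, `p`, plus attribute
#'   `"reduces_to_cox"` and the `crr` fit as attribute `"fit"`.
#' @export
fine_gray <- function(cohort, cause, model = 3, reference = "morning") {
  if (cause == "all_cause") {
    stop("Fine-Gray needs a specific cause with a competing event",
         call. = FALSE)
  }
  covs <- if (is.character(model)) model else model_covariates(model)
  d <- as.data.frame(cohort)
  d$timing_group <- stats::relevel(factor(d$timing_group), ref = reference)
  ev <- as.character(d$event_cause)
  fstatus <- ifelse(ev == "none", 0L, ifelse(ev == cause, 1L, 2L))
  reduces <- !any(fstatus == 2L)
  mm <- stats::model.matrix(
    as.formula(paste("~ timing_group +", paste(covs, collapse = " + "))),
    data = d)[, -1, drop = FALSE]
  fit <- cmprsk::crr(ftime = d$follow_up_years, fstatus = fstatus,
                     cov1 = mm, failcode = 1, cencode = 0, gtol = 1e-10)
  sm <- summary(fit)
  cn <- paste0("timing_group", setdiff(levels(d$timing_group), reference))
  out <- tibble::tibble(
    cause = cause,
    group = sub("^timing_group", "", cn),
    shr = sm$conf.int[cn, "exp(coef)"],
    ci_low = sm$conf.int[cn, "2.5%"],
    ci_high = sm$conf.int[cn, "97.5%"],
    p = sm$coef[cn, "p-value"])
  attr(out, "reduces_to_cox") <- reduces
  attr(out, "fit") <- fit
  out
}
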