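# Multiplicative and additive interaction (RERI / AP / SI with delta-method
# CIs) and subgroup analyses for the dichotomized timing phenotype.

#' Add the binary effect modifiers used in interaction and subgroup analyses
#'
#' Derives `age_high` (age >= 65), `male`, `low_mvpa` (weekly MVPA below the
#' physical-activity guideline threshold, default 150 min/week), and passes
#' through `cvd_history` and `obesity`.
#'
#' @param cohort Cohort tibble.
#' @param who_threshold Guideline MVPA threshold in min/week.
#' @return The cohort with modifier columns added.
#' @export
add_interaction_modifiers <- function(cohort, who_threshold = 150) {
  cohort$age_high <- cohort$age >= 65
  cohort$male <- cohort$sex == "male"
  cohort$low_mvpa <- cohort$weekly_mvpa < who_threshold
  cohort
}

# covariates whose information is carried by a given modifier
modifier_source <- function(modifier) {
  switch(modifier, age_high = "age", male = "sex", low_mvpa = "weekly_mvpa",
         character(0))
}

#' Multiplicative and additive interaction between timing and a modifier
#'
#' The four timing groups are combined into unfavorable (morning/evening,
#' the exposure) versus favorable (midday-afternoon/mixed, the reference). A
#' Cox model with both main effects and their product is fitted under the
#' adjustment model (minus the covariate the modifier is derived from). The
#' multiplicative interaction p-value is the Wald test of the product term.
#' Additive interaction follows the standard relative-excess definitions:
#' RERI = HR11 - HR10 - HR01 + 1, AP = RERI / HR11,
#' SI = (HR11 - 1) / ((HR10 - 1) + (HR01 - 1)), with delta-method confidence
#' intervals (log scale for SI).
#'
#' @inheritParams fit_timing_cox
#' @param modifier Name of a logical column in `cohort` (see
#'   [add_interaction_modifiers()]).
#' @return List of class `interaction_result`: stratum HRs `hr10` (exposure
#'   only), `hr01` (modifier only), `hr11` (both) versus the double reference,
#'   `reri`, `ap`, `si` each with 95% CI, and `p_multiplicative`.
#' @export
interaction_analysis <- function(cohort, outcome, modifier, model = 3) {
  covs <- if (is.character(model)) model else model_covariates(model)
  covs <- setdiff(covs, modifier_source(modifier))
  d <- as.data.frame(cohort)
  d$.status <- outcome_status(cohort, outcome)
  d$.exp <- as.integer(d$timing_group %in% c("morning", "evening"))
  d$.mod <- as.integer(d[[modifier]])
  cells <- table(d$.exp, d$.mod)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty interaction cell: exposure=%s, modifier=%s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]),
         call. = FALSE)
  }
  f <- as.formula(paste("survival::Surv(follow_up_years, .status) ~",
                        paste(c(".exp * .mod", covs), collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = "efron")
  b <- coef(fit)[c(".exp", ".mod", ".exp:.mod")]
  V <- vcov(fit)[c(".exp", ".mod", ".exp:.mod"),
                 c(".exp", ".mod", ".exp:.mod")]
  h10 <- exp(b[1]); h01 <- exp(b[2]); h11 <- exp(sum(b))
  delta_ci <- function(fun, log_scale = FALSE) {
    val <- unname(fun(b))
    eps <- 1e-6
    g <- vapply(1:3, function(i) {
      bp <- b; bm <- b
      bp[i] <- bp[i] + eps; bm[i] <- bm[i] - eps
      (fun(bp) - fun(bm)) / (2 * eps)
    }, numeric(1))
    se <- sqrt(drop(t(g) %*% V %*% g))
    if (log_scale) {
      # SI is only interpretable on the positive half-line
      if (!is.finite(val) || val <= 0) return(c(val, NA_real_, NA_real_))
      c(val, exp(log(val) + c(-1.96, 1.96) * se / val))
    } else {
      c(val, val + c(-1.96, 1.96) * se)
    }
  }
  reri_f <- function(bb) exp(sum(bb)) - exp(bb[1]) - exp(bb[2]) + 1
  ap_f <- function(bb) reri_f(bb) / exp(sum(bb))
  si_f <- function(bb) (exp(sum(bb)) - 1) /
    ((exp(bb[1]) - 1) + (exp(bb[2]) - 1))
  reri <- delta_ci(reri_f)
  ap <- delta_ci(ap_f)
  si_den <- (h10 - 1) + (h01 - 1)
  si <- if (abs(si_den) < 1e-10) c(NA_real_, NA_real_, NA_real_)
        else delta_ci(si_f, log_scale = TRUE)
  p_mult <- summary(fit)$coefficients[".exp:.mod", "Pr(>|z|)"]
  structure(
    list(outcome = outcome, modifier = modifier,
         hr10 = unname(h10), hr01 = unname(h01), hr11 = unname(h11),
         reri = reri[1], reri_ci = reri[2:3],
         ap = ap[1], ap_ci = ap[2:3],
         si = si[1], si_ci = si[2:3],
         p_multiplicative = p_mult),
    class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<interaction_result> %s x %s: HR10=%.2f HR01=%.2f HR11=%.2f\n",
    "  RERI %.2f (%.2f, %.2f); AP %.2f; SI %s; multiplicative p = %.3g\n"),
    x$outcome, x$modifier, x$hr10, x$hr01, x$hr11,
    x$reri, x$reri_ci[1], x$reri_ci[2], x$ap,
    if (is.na(x$si)) "undefined" else sprintf("%.2f", x$si),
    x$p_multiplicative))
  invisible(x)
}

#' Subgroup analysis of the favorable-timing contrast
#'
#' Within each stratum of the stratifier, fits the fully adjusted Cox model of
#' favorable (midday-afternoon/mixed) versus unfavorable (morning/evening)
#' timing; strata with fewer than 10 events per parameter are flagged.
#'
#' @inheritParams interaction_analysis
#' @param stratifier Name of a factor/logical column defining the strata.
#' @return Tibble with one row per stratum: `stratum`, `n`, `events`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `low_events`.
#' @export
subgroup_analysis <- function(cohort, outcome, stratifier, model = 3) {
  covs <- if (is.character(model)) model else model_covariates(model)
  covs <- setdiff(covs, modifier_source(stratifier))
  d <- as.data.frame(cohort)
  d$.status <- outcome_status(cohort, outcome)
  d$.fav <- as.integer(d$timing_group %in% c("midday_afternoon", "mixed"))
  strata <- if (is.logical(d[[stratifier]])) c(FALSE, TRUE)
            else levels(factor(d[[stratifier]]))
  rows <- lapply(strata, function(s) {
    ds <- d[d[[stratifier]] == s, , drop = FALSE]
    f <- as.formula(paste("survival::Surv(follow_up_years, .status) ~ .fav +",
                          paste(covs, collapse = " + ")))
    fit <- survival::coxph(f, data = ds, ties = "efron")
    sm <- summary(fit)
    low <- fit$nevent / length(coef(fit)) < 10
    if (low) warning(sprintf("stratum %s=%s: %.1f events per parameter",
                             stratifier, s, fit$nevent / length(coef(fit))))
    tibble::tibble(stratum = as.character(s), n = nrow(ds),
                   events = fit$nevent,
                   hr = sm$conf.int[".fav", "exp(coef)"],
                   ci_low = sm$conf.int[".fav", "lower .95"],
                   ci_high = sm$conf.int[".fav", "upper .95"],
                   p = sm$coefficients[".fav", "Pr(>|z|)"],
                   low_events = low)
  })
  out <- do.call(rbind, rows)
  tibble::tibble(outcome = outcome, stratifier = stratifier, out)
}
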