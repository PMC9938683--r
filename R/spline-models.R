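# Penalized-spline dose-response inside the Cox model, and G-computation
# standardized cumulative risk curves.

#' Penalized cubic spline dose-response in a Cox model
#'
#' Fits the exposure through [survival::pspline()] inside the adjusted Cox
#' model. `p_overall` is the likelihood-ratio test of all spline terms against
#' the covariates-only model; `p_nonlinear` the LRT of the spline against a
#' linear exposure, each on the spline's effective degrees of freedom. The HR
#' curve is the spline term centered at the reference exposure (HR = 1 there),
#' with the term's pointwise standard errors.
#'
#' @inheritParams fit_timing_cox
#' @param exposure Name of the continuous exposure column.
#' @param df Target effective degrees of freedom of the penalized spline.
#' @param upper Winsorization bound on the exposure (default 750, the plotted
#'   range of weekly MVPA); `Inf` disables.
#' @param ref Reference exposure value (default: median of the winsorized
#'   exposure).
#' @param grid_n Number of grid points for the curve.
#' @param extra_covariates Covariates added on top of the model set (used for
#'   mutual adjustment of window volumes).
#' @param drop_covariates Covariates removed from the model set.
#' @return A list of class `spline_result`: `exposure`, `grid`, `hr`,
#'   `ci_low`, `ci_high`, `p_overall`, `p_nonlinear`, `edf`, `ref`.
#' @export
dose_response_spline <- function(cohort, exposure, outcome, model = 3,
                                 df = 4, upper = 750, ref = NULL,
                                 grid_n = 60, extra_covariates = character(0),
                                 drop_covariates = character(0)) {
  covs <- if (is.character(model)) model else model_covariates(model)
  covs <- setdiff(unique(c(covs, extra_covariates)),
                  c(exposure, drop_covariates))
  d <- as.data.frame(cohort)
  d$.status <- outcome_status(cohort, outcome)
  d$.x <- pmin(d[[exposure]], upper)
  if (sd(d$.x) == 0) {
    stop("degenerate exposure '", exposure, "': no variation", call. = FALSE)
  }
  base_rhs <- paste(covs, collapse = " + ")
  f0 <- as.formula(paste("survival::Surv(follow_up_years, .status) ~",
                         base_rhs))
  f1 <- as.formula(paste("survival::Surv(follow_up_years, .status) ~ .x +",
                         base_rhs))
  f2 <- as.formula(paste(
    "survival::Surv(follow_up_years, .status) ~ survival::pspline(.x, df =",
    df, ") +", base_rhs))
  fit0 <- survival::coxph(f0, data = d, ties = "efron")
  fit1 <- survival::coxph(f1, data = d, ties = "efron")
  fit2 <- survival::coxph(f2, data = d, ties = "efron")
  edf <- sum(fit2$df) - length(coef(fit0))
  lrt <- function(big, small, dof) {
    stat <- 2 * (big$loglik[2] - small$loglik[2])
    pchisq(max(stat, 0), df = max(dof, 1e-8), lower.tail = FALSE)
  }
  p_overall <- lrt(fit2, fit0, edf)
  p_nonlinear <- lrt(fit2, fit1, edf - 1)
  if (is.null(ref)) ref <- median(d$.x)
  grid <- unique(sort(c(ref, seq(min(d$.x), max(d$.x), length.out = grid_n))))
  nd <- d[rep(1L, length(grid)), c(".x", covs), drop = FALSE]
  nd$.x <- grid
  nd$.status <- 1L
  nd$follow_up_years <- median(d$follow_up_years)
  pt <- predict(fit2, newdata = nd, type = "terms", se.fit = TRUE)
  term_col <- grep("pspline", colnames(pt$fit))
  term <- unname(pt$fit[, term_col])
  se <- unname(pt$se.fit[, term_col])
  loghr <- term - term[grid == ref]
  out <- list(exposure = exposure, grid = grid, hr = exp(loghr),
              ci_low = exp(loghr - 1.96 * se), ci_high = exp(loghr + 1.96 * se),
              p_overall = p_overall, p_nonlinear = p_nonlinear,
              edf = edf, ref = ref)
  attr(out, "fit") <- fit2
  class(out) <- "spline_result"
  out
}

#' @export
print.spline_result <- function(x, ...) {
  cat(sprintf(
    "<spline_result> %s: P_overall = %.3g, P_nonlinear = %.3g (edf %.2f)\n",
    x$exposure, x$p_overall, x$p_nonlinear, x$edf))
  invisible(x)
}

#' Dose-response of MVPA accumulated within one timing window
#'
#' Spline for the chosen window's MVPA minutes with the other two windows'
#' volumes as covariates (mutual adjustment) on top of the fully adjusted
#' model without total MVPA volume. Logs a collinearity note when window
#' volumes correlate above 0.95.
#'
#' @inheritParams dose_response_spline
#' @param window `"morning"`, `"midday_afternoon"`, or `"evening"`.
#' @return A `spline_result`.
#' @export
window_mvpa_model <- function(cohort, window, outcome, model = 3, df = 4,
                              upper = 750) {
  wins <- c("morning", "midday_afternoon", "evening")
  stopifnot(window %in% wins)
  cols <- paste0("mvpa_", wins)
  cc <- stats::cor(as.data.frame(cohort)[cols])
  if (any(cc[upper.tri(cc)] > 0.95)) {
    warning("window MVPA volumes correlate > 0.95; mutual adjustment unstable")
  }
  dose_response_spline(
    cohort, exposure = paste0("mvpa_", window), outcome = outcome,
    model = model, df = df, upper = upper,
    extra_covariates = paste0("mvpa_", setdiff(wins, window)),
    drop_covariates = "weekly_mvpa")
}

#' Dose-response of the MVPA fraction within one timing window
#'
#' Spline for the window's MVPA fraction (0-1) adjusted for total MVPA volume
#' and the fully adjusted covariate set — the continuous view of the timing
#' effect.
#'
#' @inheritParams window_mvpa_model
#' @return A `spline_result`.
#' @export
fraction_dose_response <- function(cohort, window, outcome, model = 3,
                                   df = 4) {
  stopifnot(window %in% c("morning", "midday_afternoon", "evening"))
  dose_response_spline(
    cohort, exposure = paste0("fraction_", window), outcome = outcome,
    model = model, df = df, upper = Inf)
}

#' Standardized cumulative risk curves by timing group
#'
#' G-computation standardization: the fully adjusted Cox model is fitted once;
#' then for each timing group every participant's cumulative incidence is
#' predicted with their own covariates but the group set to that level, and
#' averaged over the whole cohort. Curves therefore differ only through the
#' group coefficients.
#'
#' @inheritParams fit_timing_cox
#' @param times Evaluation times (years); default 50 points to the follow-up
#'   maximum.
#' @return Tibble with `group`, `time`, `risk` (standardized cumulative
#'   incidence).
#' @export
standardized_risk_curves <- function(cohort, outcome, model = 3,
                                     times = NULL) {
  covs <- if (is.character(model)) model else model_covariates(model)
  d <- as.data.frame(cohort)
  d$timing_group <- factor(d$timing_group)
  d$.status <- outcome_status(cohort, outcome)
  fit <- survival::coxph(cox_formula(covs), data = d, ties = "efron",
                         x = TRUE, model = TRUE)
  bh <- survival::basehaz(fit, centered = FALSE)
  if (is.null(times)) {
    times <- seq(0, max(d$follow_up_years), length.out = 50)
  }
  H0 <- stats::approx(bh$time, bh$hazard, xout = times, method = "constant",
                      f = 0, yleft = 0, rule = 2)$y
  groups <- levels(d$timing_group)
  rows <- lapply(groups, function(g) {
    dg <- d
    dg$timing_group <- factor(g, levels = groups)
    lp <- predict(fit, newdata = dg, type = "lp", reference = "zero")
    risk <- vapply(H0, function(h) mean(1 - exp(-h * exp(lp))), numeric(1))
    tibble::tibble(group = g, time = times, risk = risk)
  })
  do.call(rbind, rows)
}
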