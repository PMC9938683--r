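# Cohort assembly: the healthy diet score, ordered exclusion criteria with a
# conservation-checked ledger, and simplified (single, seeded) covariate
# imputation with a complete-case mode.

#' Healthy diet score (0-5)
#'
#' One point per satisfied criterion: vegetables at least four tablespoons a
#' day, fruit at least three pieces a day, fish at least twice a week,
#' unprocessed red meat at most twice a week, processed meat at most twice a
#' week. A missing criterion makes the score missing (imputed downstream).
#'
#' @param vegetable,fruit,fish,red_meat,processed_meat Logical vectors (may
#'   contain `NA`).
#' @return Integer scores in 0-5 (or `NA`).
#' @export
healthy_diet_score <- function(vegetable, fruit, fish, red_meat,
                               processed_meat) {
  m <- cbind(vegetable, fruit, fish, red_meat, processed_meat)
  if (!is.logical(m)) stop("diet criteria must be logical", call. = FALSE)
  as.integer(rowSums(m))
}

#' Apply the exclusion criteria in their frozen order
#'
#' Sequential exclusions: (1) withdrawal, (2) incomplete 1-h clock coverage,
#' (3) high nocturnal activity, (4) unreliable/invalid accelerometry
#' (including under 72 h of wear). Each participant is counted once, at the
#' first criterion that removes them, and the ledger counts sum exactly to
#' initial minus final n.
#'
#' Recognised flag columns (absent columns mean "not excluded"): `withdrawn`,
#' `hour_coverage_ok`, `nocturnal_excluded`, `accel_valid`.
#'
#' @param cohort Cohort tibble carrying the flag columns.
#' @return List with `cohort` (retained rows) and `ledger` (tibble
#'   `criterion`, `removed`, with attributes `initial_n` and `final_n`).
#' @export
apply_exclusions <- function(cohort) {
  n0 <- nrow(cohort)
  get_flag <- function(col, default) {
    v <- if (col %in% names(cohort)) cohort[[col]] else rep(default, n0)
    v[is.na(v)] <- default
    v
  }
  steps <- list(
    withdrawal = get_flag("withdrawn", FALSE),
    hour_coverage = !get_flag("hour_coverage_ok", TRUE),
    nocturnal_activity = get_flag("nocturnal_excluded", FALSE),
    invalid_accelerometry = !get_flag("accel_valid", TRUE))
  keep <- rep(TRUE, n0)
  removed <- integer(length(steps))
  for (i in seq_along(steps)) {
    hit <- keep & steps[[i]]
    removed[i] <- sum(hit)
    keep <- keep & !hit
  }
  if (!any(keep)) warning("all participants excluded")
  ledger <- tibble::tibble(criterion = names(steps), removed = removed)
  attr(ledger, "initial_n") <- n0
  attr(ledger, "final_n") <- sum(keep)
  list(cohort = cohort[keep, , drop = FALSE], ledger = ledger)
}

#' Single seeded covariate imputation
#'
#' Simplified stand-in for chained-equations multiple imputation: one
#' stochastic imputation, deterministic under the seed. Categorical values
#' (factors, logicals, integer-coded scores) are drawn from the observed
#' class frequencies; continuous values are
#' predicted by linear regression on the complete covariates plus Gaussian
#' noise at the residual scale. `method = "complete_case"` instead drops rows
#' with any missing covariate (the no-imputation sensitivity dataset).
#'
#' @param cohort Cohort tibble.
#' @param seed Integer seed.
#' @param method `"stochastic"` (default) or `"complete_case"`.
#' @param exclude Columns never treated as covariates (identifiers and
#'   outcome columns by default).
#' @return The imputed (or filtered) cohort.
#' @export
impute_covariates <- function(cohort, seed = 1L,
                              method = c("stochastic", "complete_case"),
                              exclude = c("participant_id",
                                          "follow_up_years", "event_cause")) {
  method <- match.arg(method)
  covar_cols <- setdiff(names(cohort), exclude)
  if (method == "complete_case") {
    return(cohort[complete.cases(cohort[covar_cols]), , drop = FALSE])
  }
  na_frac <- vapply(cohort[covar_cols], function(x) mean(is.na(x)),
                    numeric(1))
  if (any(na_frac == 1)) {
    stop("cannot impute all-missing column(s): ",
         paste(covar_cols[na_frac == 1], collapse = ", "), call. = FALSE)
  }
  if (any(na_frac >= 0.5)) {
    warning("column(s) with >= 50% missing: ",
            paste(covar_cols[na_frac >= 0.5], collapse = ", "))
  }
  set.seed(seed)
  out <- cohort
  complete_preds <- covar_cols[na_frac == 0]
  for (col in covar_cols[na_frac > 0]) {
    x <- out[[col]]
    miss <- is.na(x)
    if (is.numeric(x) && !is.integer(x)) {
      preds <- complete_preds[vapply(out[complete_preds], is.numeric,
                                     logical(1))]
      if (length(preds)) {
        fit <- lm(as.formula(paste(col, "~", paste(preds, collapse = "+"))),
                  data = out[!miss, , drop = FALSE])
        mu <- predict(fit, newdata = out[miss, , drop = FALSE])
        sigma <- sd(residuals(fit))
      } else {
        mu <- mean(x[!miss])
        sigma <- sd(x[!miss])
      }
      x[miss] <- mu + rnorm(sum(miss), 0, sigma)
    } else {
      # categorical (factor/logical/integer-coded): draw from observed
      # class frequencies
      obs <- x[!miss]
      x[miss] <- sample(obs, sum(miss), replace = TRUE)
    }
    out[[col]] <- x
  }
  out
}
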