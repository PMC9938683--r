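# Outcome-based discovery of the diurnal window boundaries: 2-h timing groups
# (3-h for 21:00-24:00), per-window hazards versus the mixed reference, and
# change points where the elevated flag flips.

#' The exploratory small-window grid
#'
#' Nine windows partitioning 05:00-24:00: 2-h intervals from 05:00 to 21:00
#' and a final 3-h 21:00-24:00 window.
#'
#' @return List with `boundaries` (hours 5, 7, ..., 21, 24) and `labels`.
#' @export
small_window_grid <- function() {
  boundaries <- c(seq(5, 21, by = 2), 24)
  labels <- paste0(sprintf("%02d", head(boundaries, -1L)), "-",
                   sprintf("%02d", tail(boundaries, -1L)))
  list(boundaries = boundaries, labels = labels)
}

#' Assign timing groups on the small-window grid
#'
#' A participant belongs to a small window when strictly more than 50% of
#' their 05:00-24:00 MVPA falls in it; otherwise to the mixed group.
#'
#' @param hourly A length-24 MVPA histogram, or a matrix/data frame with 24
#'   columns (one row per participant).
#' @param grid A [small_window_grid()].
#' @return Factor of group labels (levels: mixed then the window labels).
#' @export
assign_small_window_groups <- function(hourly, grid = small_window_grid()) {
  m <- if (is.null(dim(hourly))) matrix(hourly, nrow = 1L)
       else as.matrix(hourly)
  stopifnot(ncol(m) == 24L)
  b <- grid$boundaries
  denom <- rowSums(m[, 6:24, drop = FALSE])
  frac <- vapply(seq_along(grid$labels), function(i) {
    rowSums(m[, (b[i] + 1L):b[i + 1L], drop = FALSE]) / denom
  }, numeric(nrow(m)))
  frac <- matrix(frac, nrow = nrow(m))
  top <- apply(frac, 1L, which.max)
  topf <- frac[cbind(seq_len(nrow(m)), top)]
  lab <- ifelse(is.finite(topf) & topf > 0.5, grid$labels[top], "mixed")
  lab[denom <= 0] <- NA
  factor(lab, levels = c("mixed", grid$labels))
}

#' Hazard scan over the small-window grid
#'
#' One Cox fit per small-window group against the mixed reference under the
#' requested adjustment model. Groups with zero events are flagged unstable
#' and excluded from change-point logic.
#'
#' @param cohort Cohort tibble with a `small_window_group` column (see
#'   [assign_small_window_groups()]), survival columns, and the model
#'   covariates.
#' @param outcome Outcome label as in [fit_timing_cox()].
#' @param model Adjustment level or covariate names; covariates absent from
#'   the cohort are dropped.
#' @param grid A [small_window_grid()].
#' @return Tibble of class `window_scan`: `window`, `n`, `events`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `elevated`, `unstable`.
#' @export
scan_windows <- function(cohort, outcome = "all_cause", model = 1,
                         grid = small_window_grid()) {
  covs <- if (is.character(model)) model else model_covariates(model)
  covs <- intersect(covs, names(cohort))
  d <- as.data.frame(cohort)
  d$.status <- outcome_status(cohort, outcome)
  rows <- lapply(grid$labels, function(w) {
    ds <- d[d$small_window_group %in% c(w, "mixed"), , drop = FALSE]
    ds$.w <- as.integer(ds$small_window_group == w)
    ev_w <- sum(ds$.status[ds$.w == 1L])
    if (ev_w == 0 || sum(ds$.w) == 0) {
      return(tibble::tibble(window = w, n = sum(ds$.w), events = ev_w,
                            hr = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p = NA_real_,
                            elevated = NA, unstable = TRUE))
    }
    rhs <- paste(c(".w", covs), collapse = " + ")
    fit <- survival::coxph(
      as.formula(paste("survival::Surv(follow_up_years, .status) ~", rhs)),
      data = ds, ties = "efron")
    sm <- summary(fit)
    tibble::tibble(window = w, n = sum(ds$.w), events = ev_w,
                   hr = sm$conf.int[".w", "exp(coef)"],
                   ci_low = sm$conf.int[".w", "lower .95"],
                   ci_high = sm$conf.int[".w", "upper .95"],
                   p = sm$coefficients[".w", "Pr(>|z|)"],
                   elevated = sm$conf.int[".w", "exp(coef)"] > 1,
                   unstable = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "outcome") <- outcome
  class(out) <- c("window_scan", class(out))
  out
}

#' Change points of the elevated-hazard pattern
#'
#' A window is elevated when its point hazard ratio versus mixed exceeds 1
#' (or, with `ci_based = TRUE`, when its lower confidence limit does). Change
#' points are the grid boundaries at which the elevated flag flips between
#' consecutive usable windows. To intersect across outcomes, pass several
#' scans: only boundaries detected in all of them are returned.
#'
#' @param scan A `window_scan`, or a list of them (consistency intersection).
#' @param ci_based Flag windows on the lower confidence limit instead of the
#'   point estimate.
#' @return Sorted numeric vector of boundary hours (possibly empty).
#' @export
identify_change_points <- function(scan, ci_based = FALSE) {
  if (is.list(scan) && !inherits(scan, "window_scan")) {
    cps <- lapply(scan, identify_change_points, ci_based = ci_based)
    return(sort(Reduce(intersect, cps)))
  }
  grid <- attr(scan, "grid")
  use <- !scan$unstable
  flags <- if (ci_based) scan$ci_low > 1 else scan$elevated
  flags <- flags[use]
  starts <- head(grid$boundaries, -1L)[use]
  if (length(flags) < 2L) return(numeric(0))
  flips <- which(flags[-1L] != flags[-length(flags)])
  sort(starts[flips + 1L])
}
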