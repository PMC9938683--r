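# Two-tier synthetic cohort generator. Tier 1 emulates 7-day 5-s epoch wrist
# traces (diurnal structure, timing-archetype MVPA placement, non-wear
# episodes, nocturnal outliers) for phenotyping tests at small n. Tier 2 draws
# the phenotype directly (timing group, window fractions, weekly MVPA,
# covariates) and plants cause-specific exponential hazards for survival-scale
# experiments, so every planted hazard ratio is known ground truth.

#' Planted log hazard ratios used by default
#'
#' Group-specific log hazards versus the morning reference, by cause:
#' CVD 0.72 / 0.87 / 0.74, cancer 0.97 / 1.07 / 0.96 (midday-afternoon /
#' evening / mixed), other-cause null. These are the fully adjusted estimates
#' the package's recovery experiments treat as simulation truth.
#'
#' @return Named list (by cause) of named numeric vectors (by timing group).
#' @export
default_planted_log_hr <- function() {
  list(
    cvd = c(midday_afternoon = log(0.72), evening = log(0.87),
            mixed = log(0.74)),
    cancer = c(midday_afternoon = log(0.97), evening = log(1.07),
               mixed = log(0.96)),
    other = c(midday_afternoon = 0, evening = 0, mixed = 0))
}

#' Default baseline hazards (events/person-year by cause)
#'
#' Calibrated so a 7-year exponentially censored follow-up yields roughly
#' 1.17% CVD, 2.03% cancer, and 0.15% other-cause deaths in the reference
#' group (about 3.3% all-cause overall).
#'
#' @return Named numeric vector of per-year rates.
#' @export
default_baseline_hazard <- function() {
  c(cvd = -log(1 - 0.0117) / 7,
    cancer = -log(1 - 0.0203) / 7,
    other = -log(1 - 0.0015) / 7)
}

# Baseline covariate distributions of the emulated cohort (marginals of the
# real accelerometer sub-cohort's baseline table).
default_covariate_params <- function() {
  list(
    age_mean = 62.38, age_sd = 7.84,
    male_p = 40094 / 92139,
    white_p = 0.9694,
    deprivation_mean = -2.45, deprivation_sd = 3.63 / 1.349,
    region_p = c(england = 0.8977, wales = 0.0374, scotland = 0.0648),
    education_p = c(degree = 0.4379, other_qualification = 0.4788,
                    no_qualification = 0.0833),
    season_p = c(spring = 0.2257, summer = 0.2612, autumn = 0.2994,
                 winter = 0.2138),
    smoking_p = c(never = 0.5747, previous = 0.3623, current = 0.0630),
    alcohol_p = c(not_current = 0.0597, two_or_less = 0.4628,
                  three_or_more = 0.4775),
    diet_item_p = 2.69 / 5,
    sleep_duration_p = c(lt7 = 0.3446, h7to8 = 0.4581, gt8 = 0.1973),
    sleep_midpoint_p = c(before_0230 = 0.2586, b0230_0330 = 0.4670,
                         after_0330 = 0.2745),
    obesity_p = 0.1946, diabetes_p = 0.0463, longstanding_p = 0.2940,
    depression_p = 0.0887, cvd_history_p = 0.2459, cancer_history_p = 0.1457)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic generator. The defaults encode the
#' study conditions of the emulated cohort: archetype mix proportional to the
#' observed timing-group sizes (15,865 / 41,125 / 8,307 / 26,842 of 92,139),
#' weekly MVPA log-normal with median 113.83 min/week and IQR 158.67 (sdlog
#' 0.9655), 7-year administrative censoring, and planted hazards from
#' [default_planted_log_hr()].
#'
#' @param n_participants Cohort size for phenotype-level generation.
#' @param archetype_mix Probabilities over morning / midday_afternoon /
#'   evening / mixed; must sum to 1.
#' @param concentration Fraction of MVPA placed in the archetype window for
#'   epoch-level generation (0-1).
#' @param weekly_mvpa_meanlog,weekly_mvpa_sdlog Log-normal parameters of
#'   weekly MVPA (min/week).
#' @param nonwear_rate Expected non-wear episodes per participant (Poisson).
#' @param nocturnal_outlier_rate Probability a participant carries planted
#'   high nocturnal activity.
#' @param planted_log_hr Named list (cause -> named vector over non-reference
#'   timing groups) of log hazard ratios versus morning.
#' @param mvpa_log_hr_per_unit Log HR per min/week of weekly MVPA (default 0).
#' @param covariate_log_hr Named numeric of log HRs per unit of numeric
#'   covariate columns (default none; covariate effects isolate timing-group
#'   recovery when zero).
#' @param baseline_hazard Named numeric of events/person-year per cause.
#' @param followup_years Administrative censoring horizon.
#' @param covariate_params Distributional parameters for covariates.
#' @param seed Integer seed; identical seeds reproduce output exactly.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 1000L,
                              archetype_mix = c(morning = 15865,
                                                midday_afternoon = 41125,
                                                evening = 8307,
                                                mixed = 26842) / 92139,
                              concentration = 0.8,
                              weekly_mvpa_meanlog = log(113.83),
                              weekly_mvpa_sdlog = 0.9655,
                              nonwear_rate = 1,
                              nocturnal_outlier_rate = 0.02,
                              planted_log_hr = default_planted_log_hr(),
                              mvpa_log_hr_per_unit = 0,
                              covariate_log_hr = numeric(0),
                              baseline_hazard = default_baseline_hazard(),
                              followup_years = 7,
                              covariate_params = default_covariate_params(),
                              seed = 1L) {
  if (abs(sum(archetype_mix) - 1) > 1e-8 || any(archetype_mix < 0)) {
    stop("archetype_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (!all(names(archetype_mix) == TIMING_GROUPS)) {
    stop("archetype_mix must be named morning, midday_afternoon, evening, ",
         "mixed (in order)", call. = FALSE)
  }
  if (concentration < 0 || concentration > 1) {
    stop("concentration must lie in [0, 1]", call. = FALSE)
  }
  if (any(baseline_hazard <= 0)) {
    stop("baseline hazards must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(
    list(n_participants = as.integer(n_participants),
         archetype_mix = archetype_mix, concentration = concentration,
         weekly_mvpa_meanlog = weekly_mvpa_meanlog,
         weekly_mvpa_sdlog = weekly_mvpa_sdlog,
         nonwear_rate = nonwear_rate,
         nocturnal_outlier_rate = nocturnal_outlier_rate,
         planted_log_hr = planted_log_hr,
         mvpa_log_hr_per_unit = mvpa_log_hr_per_unit,
         covariate_log_hr = covariate_log_hr,
         baseline_hazard = baseline_hazard,
         followup_years = followup_years,
         covariate_params = covariate_params,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> n=%d, mix=(%s), concentration=%.2f, seed=%d\n"),
    x$n_participants,
    paste(sprintf("%.3f", x$archetype_mix), collapse = ", "),
    x$concentration, x$seed))
  invisible(x)
}

# ---- tier 1: epoch-level generation ---------------------------------------

# clock-block ranges (0-based 5-min blocks since midnight) per timing window
WINDOW_BLOCKS <- list(morning = 60:131, midday_afternoon = 132:203,
                      evening = 204:287)

# one participant's 7-day trace; returns list(series, truth row fields)
generate_one_epoch_series <- function(id, archetype, weekly_mvpa,
                                      nocturnal_outlier, n_nonwear,
                                      concentration) {
  n_days <- 7L
  n <- n_days * EPOCHS_PER_DAY
  clock <- (seq_len(n) - 1L) %% EPOCHS_PER_DAY * EPOCH_SECONDS
  hr <- clock %/% 3600L
  asleep <- hr >= 23L | hr < 6L

  # wake baseline: mostly sedentary with movement bursts; sleep: near-rest
  # with sparse posture shifts. Both keep hourly dispersion above the
  # stationarity threshold so worn time is never mistaken for non-wear.
  vm <- rlnorm(n, log(10), 0.35)
  burst <- runif(n) < 0.10 & !asleep
  vm[burst] <- runif(sum(burst), 60, 250)
  vm[asleep] <- rlnorm(sum(asleep), log(3), 0.4)
  turn <- runif(n) < 0.06 & asleep
  vm[turn] <- runif(sum(turn), 60, 180)

  # moderate sessions (5-min clock-aligned blocks) + standalone vigorous epochs
  n_sess <- max(0L, as.integer(round(weekly_mvpa * 0.95 / 5)))
  n_vig <- as.integer(round(weekly_mvpa * 0.05 * 12))
  sess_window <- draw_windows(n_sess, archetype, concentration)
  sess_day <- sample.int(n_days, n_sess, replace = TRUE)
  placed_w <- character(0)
  session_blocks <- integer(0) # global block ids, 0-based over the week
  for (d in seq_len(n_days)) {
    for (w in names(WINDOW_BLOCKS)) {
      k <- sum(sess_day == d & sess_window == w)
      if (!k) next
      pool <- WINDOW_BLOCKS[[w]]
      take <- sample(pool, min(k, length(pool)))
      session_blocks <- c(session_blocks, (d - 1L) * 288L + take)
      placed_w <- c(placed_w, rep(w, length(take)))
    }
  }
  for (b in session_blocks) {
    i0 <- b * 60L
    lo <- sample.int(60L, 5L) # a few below-range epochs: 55/60 in range
    vm[i0 + seq_len(60L)] <- runif(60, 110, 390)
    vm[i0 + lo] <- runif(5, 30, 90)
  }
  vig_window <- draw_windows(n_vig, archetype, concentration)
  vig_idx <- integer(0)
  vig_w <- character(0)
  if (n_vig > 0L) {
    for (w in names(WINDOW_BLOCKS)) {
      k <- sum(vig_window == w)
      if (!k) next
      blocks <- WINDOW_BLOCKS[[w]]
      pool <- (rep(blocks, n_days) +
                 rep(288L * (seq_len(n_days) - 1L),
                     each = length(blocks))) * 60L
      k <- min(k, length(pool))
      cand <- sample(pool, k) + sample.int(60L, k, replace = TRUE)
      keep <- !((cand - 1L) %/% 60L %in% session_blocks)
      vig_idx <- c(vig_idx, cand[keep])
      vig_w <- c(vig_w, rep(w, sum(keep)))
    }
    vm[vig_idx] <- runif(length(vig_idx), 420, 900)
  }

  if (nocturnal_outlier) {
    # sustained 01:30-02:30 activity every night: non-diurnal lifestyle
    noct <- clock >= 5400L & clock < 9000L
    vm[noct] <- runif(sum(noct), 110, 300)
  }

  for (e in seq_len(n_nonwear)) {
    # daytime device-off episode: >=1.2 h of near-constant low signal
    d <- sample.int(n_days, 1L)
    start_sec <- runif(1, 8, 19) * 3600
    len <- as.integer(runif(1, 1.2, 3) * EPOCHS_PER_HOUR)
    i0 <- (d - 1L) * EPOCHS_PER_DAY + as.integer(start_sec / EPOCH_SECONDS)
    idx <- i0 + seq_len(len)
    idx <- idx[idx <= n]
    vm[idx] <- pmax(0, runif(1, 2, 8) + rnorm(length(idx), 0, 0.3))
  }

  mins <- c(morning = 0, midday_afternoon = 0, evening = 0)
  for (w in names(mins)) {
    mins[w] <- 5 * sum(placed_w == w) + sum(vig_w == w) / 12
  }
  frac <- if (sum(mins) > 0) mins / sum(mins) else rep(NA_real_, 3)
  list(series = epoch_series(id, as.POSIXct("2015-06-01 00:00:00",
                                            tz = "UTC"), vm),
       true_fractions = frac)
}

# window labels for MVPA placement under an archetype
draw_windows <- function(k, archetype, concentration) {
  wins <- names(WINDOW_BLOCKS)
  if (k == 0L) return(character(0))
  if (archetype == "mixed") {
    # cycle the three windows so no window ever dominates
    rep_len(sample(wins), k)
  } else {
    others <- setdiff(wins, archetype)
    ifelse(runif(k) < concentration, archetype,
           sample(others, k, replace = TRUE))
  }
}

#' Generate an epoch-level cohort (tier 1)
#'
#' Simulates `n_small` participants' 7-day 5-s traces with archetype-driven
#' MVPA placement, returning the traces alongside ground truth. Intended for
#' phenotyping-chain tests; survival-scale cohorts use
#' [generate_phenotype_cohort()].
#'
#' @param config A [simulation_config()].
#' @param n_small Number of participants (at most 10,000).
#' @return List with `series` (list of [epoch_series()]) and `truth` (tibble
#'   with archetype labels, true window fractions, planted weekly MVPA,
#'   nocturnal-outlier flags, and non-wear episode counts).
#' @export
generate_epoch_cohort <- function(config, n_small = config$n_participants) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_small > 10000L) {
    stop("epoch-level generation is capped at 10,000 participants; ",
         "use generate_phenotype_cohort() for survival-scale cohorts",
         call. = FALSE)
  }
  set.seed(config$seed)
  archetype <- sample(TIMING_GROUPS, n_small, replace = TRUE,
                      prob = config$archetype_mix)
  weekly <- rlnorm(n_small, config$weekly_mvpa_meanlog,
                   config$weekly_mvpa_sdlog)
  noct <- runif(n_small) < config$nocturnal_outlier_rate
  n_nw <- rpois(n_small, config$nonwear_rate)
  series <- vector("list", n_small)
  fr <- matrix(NA_real_, n_small, 3,
               dimnames = list(NULL, names(WINDOW_BLOCKS)))
  ids <- sprintf("P%05d", seq_len(n_small))
  for (i in seq_len(n_small)) {
    g <- generate_one_epoch_series(ids[i], archetype[i], weekly[i],
                                   noct[i], n_nw[i], config$concentration)
    series[[i]] <- g$series
    fr[i, ] <- g$true_fractions
  }
  truth <- tibble::tibble(
    participant_id = ids, archetype = archetype,
    true_fraction_morning = fr[, "morning"],
    true_fraction_midday_afternoon = fr[, "midday_afternoon"],
    true_fraction_evening = fr[, "evening"],
    weekly_mvpa_true = weekly,
    nocturnal_outlier = noct, n_nonwear = n_nw)
  attr(truth, "planted") <- config
  list(series = series, truth = truth)
}

# ---- tier 2: phenotype-level generation -----------------------------------

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# window fractions consistent with a timing group at the 0.5 cutoff
draw_group_fractions <- function(group) {
  n <- length(group)
  fr <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(WINDOW_BLOCKS)))
  mixed <- group == "mixed"
  if (any(mixed)) {
    m <- sum(mixed)
    f <- rdirichlet(m, c(5, 5, 5))
    bad <- apply(f, 1, max) >= 0.5
    while (any(bad)) {
      f[bad, ] <- rdirichlet(sum(bad), c(5, 5, 5))
      bad <- apply(f, 1, max) >= 0.5
    }
    fr[mixed, ] <- f
  }
  for (w in names(WINDOW_BLOCKS)) {
    sel <- group == w
    if (!any(sel)) next
    k <- sum(sel)
    dom <- runif(k, 0.5, 0.95)
    split <- runif(k)
    rest <- 1 - dom
    f <- cbind(dom, rest * split, rest * (1 - split))
    ord <- match(names(WINDOW_BLOCKS), c(w, setdiff(names(WINDOW_BLOCKS), w)))
    fr[sel, ] <- f[, ord, drop = FALSE]
  }
  fr
}

#' Generate a phenotype-level cohort (tier 2)
#'
#' Draws the analysis-ready phenotype directly — timing group, window
#' fractions consistent with the group at the 0.5 cutoff, weekly MVPA, and the
#' full covariate set — skipping epoch simulation so survival-scale cohorts
#' (tens of thousands of rows) generate in well under a second.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (tibble, one row per participant) and `truth`
#'   (archetype labels plus the planted parameters as an attribute).
#' @export
generate_phenotype_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_participants
  p <- config$covariate_params
  group <- sample(TIMING_GROUPS, n, replace = TRUE,
                  prob = config$archetype_mix)
  fr <- draw_group_fractions(group)
  weekly <- rlnorm(n, config$weekly_mvpa_meanlog, config$weekly_mvpa_sdlog)
  rcat <- function(probs) {
    factor(sample(names(probs), n, replace = TRUE, prob = probs),
           levels = names(probs))
  }
  cohort <- tibble::tibble(
    participant_id = sprintf("S%06d", seq_len(n)),
    timing_group = factor(group, levels = TIMING_GROUPS),
    fraction_morning = fr[, "morning"],
    fraction_midday_afternoon = fr[, "midday_afternoon"],
    fraction_evening = fr[, "evening"],
    weekly_mvpa = weekly,
    mvpa_morning = weekly * fr[, "morning"],
    mvpa_midday_afternoon = weekly * fr[, "midday_afternoon"],
    mvpa_evening = weekly * fr[, "evening"],
    age = rnorm(n, p$age_mean, p$age_sd),
    sex = factor(ifelse(runif(n) < p$male_p, "male", "female"),
                 levels = c("female", "male")),
    ethnicity = factor(ifelse(runif(n) < p$white_p, "white", "other"),
                       levels = c("white", "other")),
    deprivation = rnorm(n, p$deprivation_mean, p$deprivation_sd),
    region = rcat(p$region_p),
    education = rcat(p$education_p),
    wear_season = rcat(p$season_p),
    smoking = rcat(p$smoking_p),
    alcohol = rcat(p$alcohol_p),
    diet_score = rbinom(n, 5L, p$diet_item_p),
    sleep_duration = rcat(p$sleep_duration_p),
    sleep_midpoint = rcat(p$sleep_midpoint_p),
    obesity = runif(n) < p$obesity_p,
    diabetes = runif(n) < p$diabetes_p,
    longstanding_illness = runif(n) < p$longstanding_p,
    depression = runif(n) < p$depression_p,
    cvd_history = runif(n) < p$cvd_history_p,
    cancer_history = runif(n) < p$cancer_history_p)
  truth <- tibble::tibble(participant_id = cohort$participant_id,
                          archetype = group)
  attr(truth, "planted") <- config
  list(cohort = cohort, truth = truth)
}

#' Plant cause-specific survival outcomes
#'
#' Draws exponential event times per cause with hazard
#' `baseline_hazard[cause] * exp(planted_log_hr[cause][group] + covariate
#' effects)`; the observed follow-up is the earliest cause or the
#' administrative censoring horizon. Proportional hazards hold exactly by
#' construction.
#'
#' @param cohort Phenotype-level cohort tibble with `timing_group`.
#' @param config A [simulation_config()].
#' @return The cohort with `follow_up_years` and `event_cause` columns added.
#' @export
generate_survival <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"),
            "timing_group" %in% names(cohort))
  set.seed(config$seed + 1L)
  n <- nrow(cohort)
  causes <- names(config$baseline_hazard)
  grp <- as.character(cohort$timing_group)
  non_ref <- setdiff(TIMING_GROUPS, "morning")
  tmat <- matrix(Inf, n, length(causes), dimnames = list(NULL, causes))
  extra_lp <- config$mvpa_log_hr_per_unit * cohort$weekly_mvpa
  for (v in names(config$covariate_log_hr)) {
    extra_lp <- extra_lp + config$covariate_log_hr[[v]] * cohort[[v]]
  }
  for (cz in causes) {
    lhr <- config$planted_log_hr[[cz]]
    if (is.null(lhr) || !all(non_ref %in% names(lhr))) {
      stop("missing planted log HR for cause '", cz, "'", call. = FALSE)
    }
    lp <- ifelse(grp == "morning", 0, lhr[grp]) + extra_lp
    tmat[, cz] <- rexp(n, rate = config$baseline_hazard[[cz]] * exp(lp))
  }
  tmin <- apply(tmat, 1L, min)
  cause_min <- causes[apply(tmat, 1L, which.min)]
  event <- ifelse(tmin <= config$followup_years, cause_min, "none")
  cohort$follow_up_years <- pmin(tmin, config$followup_years)
  cohort$event_cause <- factor(event, levels = c("none", causes))
  cohort
}

#' Simulate a cohort labelled on the exploratory 2-h window grid
#'
#' Supports the window-discovery experiments: participants are assigned a 2-h
#' small-window timing group (3-h for 21:00-24:00) or mixed, and survival is
#' planted versus the mixed reference with every small window inside the
#' morning (05-11) and evening (17-24) spans elevated and the midday windows
#' decisively non-elevated.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param elevated_log_hr Planted log HR vs mixed for 2-h groups inside
#'   05:00-11:00 and 17:00-24:00 (default log 1.35, the magnitude of the
#'   morning-vs-mixed CVD contrast).
#' @param midday_log_hr Planted log HR vs mixed for windows inside 11:00-17:00
#'   (default log 0.85).
#' @param baseline_hazard Events/person-year in the mixed reference.
#' @param followup_years Administrative censoring horizon.
#' @param mixed_share Probability of the mixed group; the remainder is spread
#'   evenly over the nine small windows.
#' @return List with `cohort` (tibble: `small_window_group`, `age`, `sex`,
#'   `follow_up_years`, `event_cause`) and `truth` (planted log HRs by group).
#' @export
generate_window_scan_cohort <- function(n = 50000L, seed = 1L,
                                        elevated_log_hr = log(1.35),
                                        midday_log_hr = log(0.85),
                                        baseline_hazard = 0.0088,
                                        followup_years = 7,
                                        mixed_share = 0.28) {
  set.seed(seed)
  grid <- small_window_grid()
  labels <- grid$labels
  probs <- c(rep((1 - mixed_share) / length(labels), length(labels)),
             mixed_share)
  group <- sample(c(labels, "mixed"), n, replace = TRUE, prob = probs)
  starts <- head(grid$boundaries, -1L)
  planted <- ifelse(starts < 11 | starts >= 17, elevated_log_hr,
                    midday_log_hr)
  names(planted) <- labels
  lp <- ifelse(group == "mixed", 0, planted[group])
  t_ev <- rexp(n, rate = baseline_hazard * exp(lp))
  cohort <- tibble::tibble(
    participant_id = sprintf("W%06d", seq_len(n)),
    small_window_group = factor(group, levels = c("mixed", labels)),
    age = rnorm(n, 62.38, 7.84),
    sex = factor(sample(c("female", "male"), n, replace = TRUE,
                        prob = c(0.565, 0.435)), levels = c("female", "male")),
    follow_up_years = pmin(t_ev, followup_years),
    event_cause = factor(ifelse(t_ev <= followup_years, "all_cause", "none"),
                         levels = c("none", "all_cause")))
  list(cohort = cohort,
       truth = tibble::tibble(window = labels, planted_log_hr = planted))
}

#' Configuration for all-cause-only planted simulations
#'
#' Convenience wrapper: a [simulation_config()] whose single cause is
#' all-cause mortality with planted fully adjusted HRs 0.89 / 0.98 / 0.89
#' (midday-afternoon / evening / mixed vs morning) and a baseline hazard
#' giving about 3.3% events over 7 years in the reference group.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
all_cause_config <- function(...) {
  simulation_config(
    planted_log_hr = list(all_cause = c(midday_afternoon = log(0.89),
                                        evening = log(0.98),
                                        mixed = log(0.89))),
    baseline_hazard = c(all_cause = -log(1 - 0.0335) / 7),
    ...)
}
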