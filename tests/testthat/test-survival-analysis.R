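# shared fixtures: one null cohort and one cohort with planted group effects
null_cfg <- simulation_config(
  n_participants = 20000, seed = 51,
  planted_log_hr = list(cvd = c(midday_afternoon = 0, evening = 0, mixed = 0),
                        other = c(midday_afternoon = 0, evening = 0,
                                  mixed = 0)),
  baseline_hazard = c(cvd = 0.004, other = 0.002))
null_cohort <- generate_survival(generate_phenotype_cohort(null_cfg)$cohort,
                                 null_cfg)

planted_cfg <- simulation_config(
  n_participants = 30000, seed = 52,
  planted_log_hr = list(cvd = c(midday_afternoon = log(0.6), evening = 0,
                                mixed = log(0.75)),
                        other = c(midday_afternoon = 0, evening = 0,
                                  mixed = 0)),
  baseline_hazard = c(cvd = 0.005, other = 1e-9))
planted_cohort <- generate_survival(
  generate_phenotype_cohort(planted_cfg)$cohort, planted_cfg)

test_that("the null cohort recovers hazard ratios near one", {
  ft <- fit_timing_cox(null_cohort, "cvd", model = 1)
  non_ref <- ft[ft$group != "morning", ]
  expect_true(all(abs(log(non_ref$hr)) <
                    3 * (log(non_ref$ci_high) - log(non_ref$ci_low)) / 3.92))
  expect_equal(sum(ft$events), sum(null_cohort$event_cause == "cvd"))
  expect_equal(sum(ft$person_years), sum(null_cohort$follow_up_years))
})

test_that("planted group effects are recovered within their confidence intervals", {
  ft <- suppressWarnings(fit_timing_cox(planted_cohort, "cvd", model = 3))
  mid <- ft[ft$group == "midday_afternoon", ]
  mix <- ft[ft$group == "mixed", ]
  expect_gt(0.6, mid$ci_low); expect_lt(0.6, mid$ci_high)
  expect_gt(0.75, mix$ci_low); expect_lt(0.75, mix$ci_high)
})

test_that("Cox estimates are invariant to monotone time transforms", {
  ft <- fit_timing_cox(null_cohort, "cvd", model = 1)
  doubled <- null_cohort
  doubled$follow_up_years <- doubled$follow_up_years * 2
  ft2 <- fit_timing_cox(doubled, "cvd", model = 1)
  expect_equal(ft2$hr, ft$hr, tolerance = 1e-8)
})

test_that("model log-likelihood is non-decreasing along the nested ladder", {
  f1 <- fit_timing_cox(null_cohort, "cvd", model = 1)
  f3 <- fit_timing_cox(null_cohort, "cvd", model = 3)
  expect_gte(attr(f3, "fit")$loglik[2], attr(f1, "fit")$loglik[2])
  expect_true(all(model_covariates(1) %in% model_covariates(2)))
  expect_true(all(model_covariates(2) %in% model_covariates(3)))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fine-Gray reduces to Cox without competing events", {
  cfg <- simulation_config(
    n_participants = 6000, seed = 53,
    planted_log_hr = list(cvd = c(midday_afternoon = log(0.7), evening = 0,
                                  mixed = log(0.8)),
                          other = c(midday_afternoon = 0, evening = 0,
                                    mixed = 0)),
    baseline_hazard = c(cvd = 0.006, other = 1e-9))
  co <- generate_survival(generate_phenotype_cohort(cfg)$cohort, cfg)
  expect_equal(sum(co$event_cause == "other"), 0)
  fg <- fine_gray(co, "cvd", model = 1)
  cx <- fit_timing_cox(co, "cvd", model = 1)
  expect_true(attr(fg, "reduces_to_cox"))
  expect_lt(max(abs(log(fg$shr) - log(cx$hr[cx$group != "morning"]))), 1e-6)
})

test_that("a strong competing risk attenuates the subdistribution HR", {
  # cause of interest null everywhere; competing cause strongly elevated for
  # the midday group, which should pull its subdistribution HR below the
  # cause-specific one
  cfg <- simulation_config(
    n_participants = 20000, seed = 54,
    planted_log_hr = list(cvd = c(midday_afternoon = 0, evening = 0,
                                  mixed = 0),
                          other = c(midday_afternoon = log(3), evening = 0,
                                    mixed = 0)),
    baseline_hazard = c(cvd = 0.008, other = 0.02))
  co <- generate_survival(generate_phenotype_cohort(cfg)$cohort, cfg)
  fg <- fine_gray(co, "cvd", model = 1)
  cx <- fit_timing_cox(co, "cvd", model = 1)
  shr_mid <- fg$shr[fg$group == "midday_afternoon"]
  hr_mid <- cx$hr[cx$group == "midday_afternoon"]
  expect_lt(shr_mid, hr_mid)
})

test_that("spline dose-response recovers linear and plateau truths", {
  # linear log-hazard in weekly MVPA
  lin_cfg <- simulation_config(
    n_participants = 20000, seed = 55,
    planted_log_hr = list(all = c(midday_afternoon = 0, evening = 0,
                                  mixed = 0)),
    mvpa_log_hr_per_unit = -0.003,
    baseline_hazard = c(all = 0.02))
  co <- generate_survival(generate_phenotype_cohort(lin_cfg)$cohort, lin_cfg)
  sp <- dose_response_spline(co, "weekly_mvpa", "all_cause", model = 1)
  expect_lt(sp$p_overall, 1e-6)
  expect_gt(sp$p_nonlinear, 0.001)
  expect_equal(sp$hr[sp$grid == sp$ref], 1)
  expect_gt(sp$hr[1], tail(sp$hr, 1)) # decreasing in exposure

  # plateau: effect only below 150 min/week
  plat_cfg <- lin_cfg
  plat_cfg$seed <- 56
  plat_cfg$mvpa_log_hr_per_unit <- 0
  plat_cfg$covariate_log_hr <- c(mvpa_capped = -0.008)
  co2 <- generate_phenotype_cohort(plat_cfg)$cohort
  co2$mvpa_capped <- pmin(co2$weekly_mvpa, 150)
  co2 <- generate_survival(co2, plat_cfg)
  sp2 <- dose_response_spline(co2, "weekly_mvpa", "all_cause", model = 1)
  expect_lt(sp2$p_overall, 1e-6)
  expect_lt(sp2$p_nonlinear, 0.01)

  expect_error(dose_response_spline(
    transform(co, weekly_mvpa = 1), "weekly_mvpa", "all_cause", model = 1),
    "degenerate")
})

test_that("window-volume and fraction splines run with mutual adjustment", {
  sp <- window_mvpa_model(planted_cohort, "midday_afternoon", "cvd",
                          model = 1)
  expect_s3_class(sp, "spline_result")
  expect_true(is.finite(sp$p_overall))
  spf <- fraction_dose_response(planted_cohort, "midday_afternoon", "cvd",
                                model = 1)
  expect_equal(spf$hr[spf$grid == spf$ref], 1)
  # planted protective midday effect shows as HR < 1 at high fractions
  expect_lt(tail(spf$hr, 1), 1)
})

test_that("standardized risk curves are proper and ordered by planted risk", {
  src <- standardized_risk_curves(planted_cohort, "cvd", model = 1)
  for (g in unique(src$group)) {
    r <- src$risk[src$group == g]
    expect_equal(r[1], 0)
    expect_false(is.unsorted(r))
    expect_true(all(r >= 0 & r <= 1))
  }
  at_end <- tapply(src$risk[src$time == max(src$time)],
                   src$group[src$time == max(src$time)], identity)
  expect_lt(at_end[["midday_afternoon"]], at_end[["morning"]])

  # null cohort: curves overlap closely
  src0 <- standardized_risk_curves(null_cohort, "cvd", model = 1)
  end0 <- src0$risk[src0$time == max(src0$time)]
  expect_lt(max(end0) - min(end0), 0.2 * mean(end0) + 0.005)
})

test_that("interaction identities hold exactly and nulls give RERI near zero", {
  co <- add_interaction_modifiers(null_cohort)
  ia <- suppressWarnings(interaction_analysis(co, "cvd", "age_high",
                                              model = 1))
  expect_equal(ia$reri, ia$hr11 - ia$hr10 - ia$hr01 + 1)
  expect_equal(ia$ap, ia$reri / ia$hr11)
  expect_equal(ia$si, (ia$hr11 - 1) / ((ia$hr10 - 1) + (ia$hr01 - 1)))
  # RERI consistent with zero at 3.5 delta-method SEs (false-alarm ~5e-4)
  reri_se <- diff(ia$reri_ci) / 3.92
  expect_lt(abs(ia$reri), 3.5 * reri_se)
  expect_gt(ia$p_multiplicative, 1e-4)

  # empty cell is a named error
  co2 <- co
  co2$age_high <- co2$timing_group %in% c("morning", "evening")
  expect_error(interaction_analysis(co2, "cvd", "age_high", model = 1),
               "empty interaction cell")
})

test_that("subgroup estimates bracket the pooled favorable-timing contrast", {
  co <- add_interaction_modifiers(planted_cohort)
  sg <- suppressWarnings(subgroup_analysis(co, "cvd", "male", model = 1))
  expect_equal(nrow(sg), 2)
  expect_true(all(is.finite(sg$hr)))
  d <- as.data.frame(co)
  d$.status <- as.integer(d$event_cause == "cvd")
  d$.fav <- as.integer(d$timing_group %in% c("midday_afternoon", "mixed"))
  pooled <- survival::coxph(
    survival::Surv(follow_up_years, .status) ~ .fav + age + sex, data = d)
  lp <- unname(coef(pooled)[".fav"])
  # approximate collapsibility on the log scale
  expect_gt(lp, min(log(sg$hr)) - 0.15)
  expect_lt(lp, max(log(sg$hr)) + 0.15)
})
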