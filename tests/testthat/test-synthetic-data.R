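test_that("configuration invariants are enforced", {
  expect_error(simulation_config(archetype_mix = c(morning = 0.5,
                                                   midday_afternoon = 0.4,
                                                   evening = 0.2,
                                                   mixed = 0.1)), "sum to 1")
  expect_error(simulation_config(concentration = 1.2), "concentration")
  expect_error(simulation_config(baseline_hazard = c(cvd = -1)), "positive")
})

test_that("identical seeds reproduce epoch output exactly", {
  cfg <- simulation_config(n_participants = 2, seed = 1)
  a <- generate_epoch_cohort(cfg, 2)
  b <- generate_epoch_cohort(cfg, 2)
  expect_identical(a$series[[1]]$vm, b$series[[1]]$vm)
  expect_identical(a$series[[2]]$vm, b$series[[2]]$vm)
  expect_identical(a$truth, b$truth)

  cfg2 <- simulation_config(n_participants = 500, seed = 3)
  c1 <- generate_phenotype_cohort(cfg2)
  c2 <- generate_phenotype_cohort(cfg2)
  expect_identical(c1$cohort, c2$cohort)
  s1 <- generate_survival(c1$cohort, cfg2)
  s2 <- generate_survival(c2$cohort, cfg2)
  expect_identical(s1, s2)
})

test_that("degenerate concentration puts all MVPA in the archetype window", {
  cfg <- simulation_config(n_participants = 4, concentration = 1,
                           archetype_mix = c(morning = 1, midday_afternoon = 0,
                                             evening = 0, mixed = 0),
                           nonwear_rate = 0, nocturnal_outlier_rate = 0,
                           seed = 2)
  ep <- generate_epoch_cohort(cfg, 4)
  expect_true(all(ep$truth$true_fraction_morning == 1))
  for (tr in ep$series) {
    h <- hourly_histogram(detect_moderate_sessions(tr),
                          detect_vigorous_epochs(tr), tr)
    expect_equal(sum(h[6:11]), sum(h)) # all MVPA between 05:00 and 11:00
  }
})

test_that("mixed archetypes never cross the 50% dominance rule", {
  cfg <- simulation_config(n_participants = 8,
                           archetype_mix = c(morning = 0, midday_afternoon = 0,
                                             evening = 0, mixed = 1),
                           nonwear_rate = 0, nocturnal_outlier_rate = 0,
                           seed = 4)
  ep <- generate_epoch_cohort(cfg, 8)
  fr <- as.matrix(ep$truth[, c("true_fraction_morning",
                               "true_fraction_midday_afternoon",
                               "true_fraction_evening")])
  expect_true(all(apply(fr, 1, max) < 0.5))
})

test_that("phenotype cohorts respect the archetype mix and fraction rules", {
  cfg <- simulation_config(
    n_participants = 20000,
    archetype_mix = c(morning = 15865, midday_afternoon = 41125,
                      evening = 8307, mixed = 26842) / 92139, seed = 6)
  co <- generate_phenotype_cohort(cfg)$cohort
  counts <- table(co$timing_group)
  for (g in names(cfg$archetype_mix)) {
    p <- cfg$archetype_mix[[g]]
    # realized counts within 99.9% binomial bounds
    expect_lt(abs(counts[[g]] - 20000 * p), 3.3 * sqrt(20000 * p * (1 - p)))
  }
  fr <- co$fraction_morning + co$fraction_midday_afternoon +
    co$fraction_evening
  expect_equal(fr, rep(1, nrow(co)), tolerance = 1e-12)
  # fractions consistent with the assigned group at the 0.5 cutoff
  fmat <- cbind(co$fraction_morning, co$fraction_midday_afternoon,
                co$fraction_evening)
  pure <- co$timing_group != "mixed"
  dom <- fmat[cbind(which(pure), as.integer(co$timing_group[pure]))]
  expect_true(all(dom >= 0.5))
  expect_true(all(apply(fmat[!pure, ], 1, max) < 0.5))

  # degenerate mix: everyone morning
  cfg2 <- simulation_config(n_participants = 200,
                            archetype_mix = c(morning = 1, midday_afternoon = 0,
                                              evening = 0, mixed = 0), seed = 7)
  expect_true(all(generate_phenotype_cohort(cfg2)$cohort$timing_group ==
                    "morning"))
})

test_that("generated weekly MVPA matches the configured distribution", {
  cfg <- simulation_config(n_participants = 5000, seed = 8)
  co <- generate_phenotype_cohort(cfg)$cohort
  expect_lt(abs(median(co$weekly_mvpa) - 113.83) / 113.83, 0.10)
})

test_that("planted survival behaves like the exponential model it is", {
  # null planting: event proportions equal across groups within sampling error
  null_cfg <- simulation_config(
    n_participants = 20000, seed = 9,
    planted_log_hr = list(all = c(midday_afternoon = 0, evening = 0,
                                  mixed = 0)),
    baseline_hazard = c(all = 0.005))
  co <- generate_survival(generate_phenotype_cohort(null_cfg)$cohort, null_cfg)
  p_by_group <- tapply(co$event_cause != "none", co$timing_group, mean)
  expect_lt(max(p_by_group) - min(p_by_group), 0.012)

  # doubling the baseline hazard doubles expected events in the rare limit
  cfg_a <- simulation_config(n_participants = 20000, seed = 10,
                             planted_log_hr = list(all = c(
                               midday_afternoon = 0, evening = 0, mixed = 0)),
                             baseline_hazard = c(all = 0.001))
  cfg_b <- cfg_a
  cfg_b$baseline_hazard <- c(all = 0.002)
  coh <- generate_phenotype_cohort(cfg_a)$cohort
  ev_a <- sum(generate_survival(coh, cfg_a)$event_cause != "none")
  ev_b <- sum(generate_survival(coh, cfg_b)$event_cause != "none")
  # closed form: E[events] = n (1 - exp(-lambda T))
  expect_lt(abs(ev_a - 20000 * (1 - exp(-0.001 * 7))), 4 * sqrt(140))
  expect_lt(abs(ev_b - 20000 * (1 - exp(-0.002 * 7))), 4 * sqrt(280))

  # planted HR 0.5: crude rate ratio approaches 0.5 in the rare-event limit
  cfg_hr <- simulation_config(
    n_participants = 40000, seed = 11,
    archetype_mix = c(morning = 0.5, midday_afternoon = 0.5, evening = 0,
                      mixed = 0),
    planted_log_hr = list(all = c(midday_afternoon = log(0.5), evening = 0,
                                  mixed = 0)),
    baseline_hazard = c(all = 0.004))
  co2 <- generate_survival(generate_phenotype_cohort(cfg_hr)$cohort, cfg_hr)
  rate <- tapply(co2$event_cause != "none", co2$timing_group, sum) /
    tapply(co2$follow_up_years, co2$timing_group, sum)
  expect_equal(unname(rate[["midday_afternoon"]] / rate[["morning"]]), 0.5,
               tolerance = 0.15)

  # missing planted parameter is a configuration error
  bad <- simulation_config(planted_log_hr = list(cvd = c(evening = 0)),
                           baseline_hazard = c(cvd = 0.001), seed = 1)
  expect_error(generate_survival(generate_phenotype_cohort(bad)$cohort, bad),
               "missing planted log HR")
})

test_that("epoch-level generation is capped at desk scale", {
  cfg <- simulation_config(seed = 1)
  expect_error(generate_epoch_cohort(cfg, 10001), "capped")
})
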