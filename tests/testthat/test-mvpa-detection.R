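# one-day trace with no accidental MVPA: everything below 100 mg
quiet_day <- function() runif(17280, 10, 60)

# overwrite a clock-aligned 5-min block (0-based id) with n_in in-range epochs
set_block <- function(vm, block, n_in, in_val = 200, out_val = 50) {
  idx <- block * 60L + seq_len(60L)
  vm[idx] <- out_val
  vm[idx[seq_len(n_in)]] <- in_val
  vm
}

test_that("the session rule is strictly more than 80% of epochs in range", {
  set.seed(1)
  vm <- quiet_day()
  vm <- set_block(vm, 100, 49) # 49/60 = 81.7%
  vm <- set_block(vm, 120, 48) # 48/60 = 80.0% exactly
  s <- detect_moderate_sessions(make_trace(vm))
  expect_equal(s$epoch_start, 100 * 60 + 1)
  expect_equal(s$n_in_range, 49)

  # boundary values: 100 and 400 are moderate (closed range)
  vm2 <- quiet_day()
  idx <- 90 * 60 + seq_len(60)
  vm2[idx] <- rep(c(100, 400), 30)
  expect_equal(detect_moderate_sessions(make_trace(vm2))$epoch_start,
               90 * 60 + 1)

  # all epochs at 500 mg: vigorous, not moderate
  expect_equal(nrow(detect_moderate_sessions(make_trace(rep(500, 17280)))), 0)
})

test_that("vigorous epochs use a strict 400 mg threshold", {
  vm <- c(400, 400.1, 399.9, 1000, 0)
  expect_equal(detect_vigorous_epochs(make_trace(vm)), c(2L, 4L))
})

test_that("session detection matches the brute-force 80%-rule oracle", {
  set.seed(33)
  for (rep in 1:3) {
    vm <- quiet_day()
    # random blocks at varying in-range counts straddling the threshold
    for (b in sample(0:287, 12)) {
      vm <- set_block(vm, b, sample(44:60, 1))
    }
    tr <- make_trace(vm)
    expect_identical(detect_moderate_sessions(tr)$epoch_start,
                     oracle_sessions(tr))
  }
})

test_that("adding an in-range epoch never destroys a session", {
  set.seed(9)
  vm <- quiet_day()
  vm <- set_block(vm, 50, 49)
  tr <- make_trace(vm)
  before <- detect_moderate_sessions(tr)$epoch_start
  vm[50 * 60 + 60] <- 250 # one more epoch into range
  after <- detect_moderate_sessions(make_trace(vm))$epoch_start
  expect_true(all(before %in% after))
})

test_that("daily minutes follow the 05:00-24:00 summation rule", {
  set.seed(2)
  vm <- quiet_day()
  # 3 sessions in daytime
  for (b in c(80, 150, 220)) vm <- set_block(vm, b, 55)
  # 24 standalone vigorous epochs at 10:00
  vm[10 * 720 + seq_len(24)] <- 600
  tr <- make_trace(vm)
  s <- detect_moderate_sessions(tr)
  v <- detect_vigorous_epochs(tr)
  expect_equal(daily_mvpa_minutes(s, v, 1, tr), 3 * 5 + 24 * 5 / 60)

  # vigorous epochs only between 02:00 and 03:00 contribute nothing
  vm2 <- quiet_day()
  vm2[2 * 720 + seq_len(100)] <- 700
  tr2 <- make_trace(vm2)
  expect_equal(daily_mvpa_minutes(detect_moderate_sessions(tr2),
                                  detect_vigorous_epochs(tr2), 1, tr2), 0)

  # no MVPA at all
  tr3 <- make_trace(quiet_day())
  expect_equal(daily_mvpa_minutes(detect_moderate_sessions(tr3),
                                  detect_vigorous_epochs(tr3), 1, tr3), 0)
})

test_that("vigorous epochs inside a session are not double counted", {
  set.seed(3)
  vm <- quiet_day()
  vm <- set_block(vm, 100, 55)
  vm[100 * 60 + 57:59] <- 500 # vigorous epochs inside the session block
  tr <- make_trace(vm)
  s <- detect_moderate_sessions(tr)
  v <- detect_vigorous_epochs(tr)
  expect_equal(nrow(s), 1)
  expect_equal(daily_mvpa_minutes(s, v, 1, tr), 5)
})

test_that("weekly MVPA extrapolates over valid days", {
  expect_equal(weekly_mvpa(c(20, 10, 25, 5), 4), 105)
  expect_equal(weekly_mvpa(rep(10, 7), 7), 70)
  expect_error(weekly_mvpa(numeric(0), 0), "no valid days")
})

test_that("hourly histogram attributes minutes by their midpoints", {
  # a hand-made 10:57-11:02 session: 3 minutes to hour 10, 2 to hour 11
  fake_session <- data.frame(epoch_start = 1L, day = 1L,
                             clock_sec = 10L * 3600L + 57L * 60L,
                             n_in_range = 60L)
  tr <- make_trace(quiet_day())
  h <- hourly_histogram(fake_session, integer(0), tr)
  expect_equal(h[11], 3)
  expect_equal(h[12], 2)
  expect_equal(sum(h), 5)

  # all activity in one hour: single nonzero bin
  set.seed(4)
  vm <- quiet_day()
  vm <- set_block(vm, 6 * 12 + 2, 55) # 06:10
  tr2 <- make_trace(vm)
  h2 <- hourly_histogram(detect_moderate_sessions(tr2),
                         detect_vigorous_epochs(tr2), tr2)
  expect_equal(which(h2 > 0), 7L)
})

test_that("histogram totals are conserved against daily sums plus nocturnal", {
  cfg <- simulation_config(n_participants = 3, nonwear_rate = 0, seed = 14)
  ep <- generate_epoch_cohort(cfg, 3)
  for (tr in ep$series) {
    s <- detect_moderate_sessions(tr)
    v <- detect_vigorous_epochs(tr)
    h <- hourly_histogram(s, v, tr)
    daily <- vapply(1:7, function(d) daily_mvpa_minutes(s, v, d, tr),
                    numeric(1))
    # 05:00-24:00 histogram mass equals the summed daily minutes
    expect_equal(sum(h[6:24]), sum(daily), tolerance = 1e-10)
    # and the full histogram matches the independent oracle
    expect_equal(h, oracle_histogram(tr), tolerance = 1e-10)
  }
})
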