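# Brute-force reference implementations and small fixture builders. The
# oracles recompute each rule directly from its definition, independently of
# the package's vectorized code paths.

midnight <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC")

# a series starting at local midnight with the given vm values
make_trace <- function(vm, id = "T1", start = midnight) {
  epoch_series(id, start, vm)
}

# direct scan: an epoch is non-wear iff it lies in some length-k window whose
# sample sd of vm is below the threshold
oracle_nonwear <- function(series, sd_threshold = 13, min_hours = 1) {
  x <- series$vm
  n <- length(x)
  k <- as.integer(min_hours * 3600 / series$epoch_seconds)
  wear <- rep(TRUE, n)
  if (n < k) return(wear)
  for (i in seq_len(n - k + 1L)) {
    if (sd(x[i:(i + k - 1L)]) < sd_threshold) {
      wear[i:(i + k - 1L)] <- FALSE
    }
  }
  wear
}

# direct 80%-rule over every clock-aligned 5-min block
oracle_sessions <- function(series) {
  vm <- series$vm
  off <- series$start_offset
  starts <- integer(0)
  abs_start <- off
  first_block <- ceiling(abs_start / 300)
  total_sec <- off + length(vm) * 5L
  blocks <- seq(first_block, total_sec %/% 300L - 1L)
  for (b in blocks) {
    i0 <- (b * 300L - off) %/% 5L + 1L
    idx <- i0:(i0 + 59L)
    if (max(idx) > length(vm) || min(idx) < 1L) next
    n_in <- sum(vm[idx] >= 100 & vm[idx] <= 400)
    if (n_in / 60 > 0.8) starts <- c(starts, i0)
  }
  starts
}

# direct hour-of-day MVPA histogram (minutes), mirroring the attribution rule
oracle_histogram <- function(series) {
  vm <- series$vm
  sess <- oracle_sessions(series)
  hist <- numeric(24)
  in_session <- rep(FALSE, length(vm))
  for (s in sess) in_session[s:(s + 59L)] <- TRUE
  for (s in sess) {
    start_clock <- (series$start_offset + (s - 1L) * 5L) %% 86400L
    for (m in 0:4) {
      h <- ((start_clock + m * 60 + 30) %% 86400) %/% 3600
      hist[h + 1] <- hist[h + 1] + 1
    }
  }
  vig <- which(vm > 400 & !in_session)
  for (i in vig) {
    mid <- (series$start_offset + (i - 1L) * 5L + 2.5) %% 86400
    h <- floor(mid / 3600)
    hist[h + 1] <- hist[h + 1] + 5 / 60
  }
  hist
}

# direct window fractions over 05-24 from an hourly histogram
oracle_fractions <- function(hist) {
  denom <- sum(hist[6:24])
  if (denom <= 0) return(rep(NA_real_, 3))
  c(sum(hist[6:11]), sum(hist[12:17]), sum(hist[18:24])) / denom
}

# a trace with a given total-hours length of mixed active/sedentary signal;
# dispersion far above the stationarity threshold
active_trace <- function(hours, seed = 1) {
  set.seed(seed)
  n <- hours * 720
  vm <- rlnorm(n, log(15), 0.4)
  burst <- runif(n) < 0.15
  vm[burst] <- runif(sum(burst), 80, 300)
  vm
}
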