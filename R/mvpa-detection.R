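# MVPA quantification on wear-complete epoch traces: moderate sessions
# (5-min blocks with >80% of epochs at 100-400 mg), vigorous epochs (>400 mg),
# daily 05:00-24:00 minutes, weekly extrapolation, hour-of-day histogram.

MODERATE_LO <- 100
MODERATE_HI <- 400
VIGOROUS_THRESHOLD <- 400
SESSION_EPOCHS <- 60L      # 5 min of 5-s epochs
SESSION_MIN_IN_RANGE <- 49L # strictly more than 80% of 60

#' Detect moderate-intensity sessions
#'
#' A moderate session is a clock-aligned, disjoint 5-min block in which
#' strictly more than 80% of the sixty 5-s epochs have a mean acceleration in
#' the closed range 100-400 mg. Partial blocks at the edges of the recording
#' are never sessions.
#'
#' @param series A wear-complete (imputed) [epoch_series()].
#' @return A data frame with one row per session: `epoch_start` (index of the
#'   first epoch), `day` (recording day), `clock_sec` (seconds after local
#'   midnight of the block start), and `n_in_range`.
#' @export
detect_moderate_sessions <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  vm <- series$vm
  n <- length(vm)
  abs_sec <- series$start_offset + (seq_len(n) - 1L) * series$epoch_seconds
  block <- abs_sec %/% 300L
  in_range <- as.integer(vm >= MODERATE_LO & vm <= MODERATE_HI)
  counts <- rowsum(in_range, block)
  sizes <- rowsum(rep(1L, n), block)
  ok <- which(sizes[, 1L] == SESSION_EPOCHS &
                counts[, 1L] >= SESSION_MIN_IN_RANGE)
  blk <- as.integer(rownames(counts))[ok]
  epoch_start <- match(blk, block)
  data.frame(
    epoch_start = epoch_start,
    day = (blk * 300L) %/% 86400L + 1L,
    clock_sec = (blk * 300L) %% 86400L,
    n_in_range = counts[ok, 1L])
}

#' Detect vigorous-intensity epochs
#'
#' @param series A wear-complete [epoch_series()].
#' @return Integer indices of epochs with vector magnitude strictly above
#'   400 mg.
#' @export
detect_vigorous_epochs <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  which(series$vm > VIGOROUS_THRESHOLD)
}

# indices of vigorous epochs lying inside any detected session block
vigorous_in_sessions <- function(vigorous, sessions) {
  if (!nrow(sessions) || !length(vigorous)) return(integer(0))
  inside <- logical(length(vigorous))
  for (s in sessions$epoch_start) {
    inside <- inside | (vigorous >= s & vigorous < s + SESSION_EPOCHS)
  }
  vigorous[inside]
}

#' Daily MVPA minutes in the 05:00-24:00 window
#'
#' Minutes are 5 x (number of moderate sessions starting between 05:00 and
#' 24:00) plus 5/60 min per standalone vigorous epoch (vigorous epochs inside a
#' detected session are not double counted). Activity between 00:00 and 05:00
#' contributes nothing.
#'
#' @param sessions Data frame from [detect_moderate_sessions()].
#' @param vigorous Indices from [detect_vigorous_epochs()].
#' @param day Recording day (1-based).
#' @param series The underlying `epoch_series`.
#' @return MVPA minutes for that day.
#' @export
daily_mvpa_minutes <- function(sessions, vigorous, day, series) {
  s_day <- sessions[sessions$day == day & sessions$clock_sec >= 5L * 3600L, ,
                    drop = FALSE]
  standalone <- setdiff(vigorous, vigorous_in_sessions(vigorous, sessions))
  if (length(standalone)) {
    cs <- epoch_clock_seconds(series)[standalone]
    dd <- epoch_day_index(series)[standalone]
    standalone <- standalone[dd == day & cs >= 5L * 3600L]
  }
  5 * nrow(s_day) + length(standalone) * series$epoch_seconds / 60
}

#' Weekly MVPA by extrapolation over valid days
#'
#' @param daily_minutes Numeric vector of daily MVPA minutes.
#' @param valid_days Number of valid wear days contributing.
#' @return Extrapolated min/week: `sum(daily) / valid_days * 7` (the plain sum
#'   when all 7 days are valid).
#' @export
weekly_mvpa <- function(daily_minutes, valid_days) {
  if (valid_days == 0) stop("no valid days; weekly MVPA undefined",
                            call. = FALSE)
  sum(daily_minutes) / valid_days * 7
}

#' Hour-of-day MVPA histogram
#'
#' Attributes each MVPA minute to the clock hour containing its midpoint:
#' session minutes as five consecutive 1-min intervals from the session start,
#' standalone vigorous epochs as 5/60 min at the epoch midpoint. All 24 clock
#' hours are kept (hours 0-4 feed the nocturnal filter, not the daily totals).
#'
#' @inheritParams daily_mvpa_minutes
#' @return Numeric vector of length 24 (MVPA minutes per clock hour, summed
#'   over days).
#' @export
hourly_histogram <- function(sessions, vigorous, series) {
  hist <- numeric(24)
  if (nrow(sessions)) {
    for (m in 0:4) {
      mid <- (sessions$clock_sec + m * 60L + 30L) %% 86400L
      h <- mid %/% 3600L
      for (hh in h) hist[hh + 1L] <- hist[hh + 1L] + 1
    }
  }
  standalone <- setdiff(vigorous, vigorous_in_sessions(vigorous, sessions))
  if (length(standalone)) {
    mid <- (epoch_clock_seconds(series)[standalone] +
              series$epoch_seconds / 2) %% 86400
    h <- floor(mid / 3600)
    tab <- table(h)
    hist[as.integer(names(tab)) + 1L] <- hist[as.integer(names(tab)) + 1L] +
      as.numeric(tab) * series$epoch_seconds / 60
  }
  hist
}

#' Weekly activity profile of one participant
#'
#' Runs the full MVPA quantification on a wear-complete series and returns the
#' per-participant summary used by the timing phenotype: daily 05:00-24:00
#' MVPA minutes, the 24-h MVPA histogram, extrapolated weekly MVPA, the
#' acceleration-weighted nocturnal activity fraction (share of summed vector
#' magnitude accumulated 01:00-04:00), and the number of valid days.
#'
#' A day counts as valid when it carries at least `min_day_wear_hours` of wear.
#'
#' @param series A wear-complete [epoch_series()].
#' @param min_day_wear_hours Wear hours required for a day to count as valid.
#' @return A list of class `activity_profile`.
#' @export
activity_profile <- function(series, min_day_wear_hours = 16) {
  sessions <- detect_moderate_sessions(series)
  vigorous <- detect_vigorous_epochs(series)
  days <- sort(unique(epoch_day_index(series)))
  daily <- vapply(days, function(d) daily_mvpa_minutes(sessions, vigorous, d,
                                                       series), numeric(1))
  wear_by_day <- rowsum(as.numeric(series$wear), epoch_day_index(series))[, 1L]
  valid_days <- sum(wear_by_day * series$epoch_seconds / 3600 >=
                      min_day_wear_hours)
  hourly <- hourly_histogram(sessions, vigorous, series)
  hrs <- epoch_clock_hours(series)
  vm_by_hour <- numeric(24)
  tv <- rowsum(series$vm, hrs)
  vm_by_hour[as.integer(rownames(tv)) + 1L] <- tv[, 1L]
  total_vm <- sum(vm_by_hour)
  noct <- if (total_vm > 0) sum(vm_by_hour[2:4]) / total_vm else NA_real_
  structure(
    list(participant_id = series$participant_id,
         daily_mvpa = stats::setNames(daily, paste0("day", days)),
         hourly_mvpa = hourly,
         hourly_vm = vm_by_hour,
         total_weekly_mvpa = weekly_mvpa(daily, max(valid_days, 1L)),
         nocturnal_activity_fraction = noct,
         valid_days = valid_days),
    class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf(
    "<activity_profile> %s: %.1f min/week MVPA, %d valid days, nocturnal %.3f\n",
    x$participant_id, x$total_weekly_mvpa, x$valid_days,
    x$nocturnal_activity_fraction))
  invisible(x)
}
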