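# The full per-participant phenotyping chain, epoch trace -> cohort row.

#' Phenotype a batch of epoch series
#'
#' Runs the complete chain on each trace: non-wear detection,
#' similar-time-of-day imputation, wear-time QC, MVPA quantification, and
#' timing assignment. One row per participant is returned regardless of QC
#' outcome; downstream exclusion is the assembly stage's job.
#'
#' @param series_list List of [epoch_series()].
#' @param cutoff Timing-group fraction cutoff.
#' @param windows A [timing_windows()].
#' @param nocturnal_threshold Threshold of [nocturnal_filter()].
#' @param sd_threshold,min_hours Non-wear detection parameters.
#' @return Tibble with participant id, QC fields (`wear_hours`,
#'   `hour_coverage_ok`, `accel_valid`), weekly MVPA, hourly MVPA columns
#'   `hourly_mvpa_00` ... `hourly_mvpa_23`, window fractions, `timing_group`,
#'   `nocturnal_excluded`, and `valid_days`.
#' @export
phenotype_epoch_cohort <- function(series_list, cutoff = 0.50,
                                   windows = timing_windows(),
                                   nocturnal_threshold = 0.10,
                                   sd_threshold = 13.0, min_hours = 1) {
  rows <- lapply(series_list, function(s) {
    mask <- detect_nonwear(s, sd_threshold, min_hours)
    s2 <- impute_nonwear(s, mask)
    qc <- qc_validity(s2)
    prof <- activity_profile(s2)
    asg <- timing_assignment(prof, windows, cutoff, nocturnal_threshold)
    hm <- as.list(setNames(prof$hourly_mvpa,
                           sprintf("hourly_mvpa_%02d", 0:23)))
    tibble::tibble(
      participant_id = s$participant_id,
      wear_hours = qc$wear_hours,
      hour_coverage_ok = qc$hour_bins_covered == 24L,
      accel_valid = qc$wear_hours >= 72,
      valid_days = prof$valid_days,
      weekly_mvpa = prof$total_weekly_mvpa,
      !!!hm,
      fraction_morning = asg$fractions[["morning"]],
      fraction_midday_afternoon = asg$fractions[["midday_afternoon"]],
      fraction_evening = asg$fractions[["evening"]],
      timing_group = asg$group,
      nocturnal_excluded = asg$excluded_nocturnal)
  })
  do.call(rbind, rows)
}
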