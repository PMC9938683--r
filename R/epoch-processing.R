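# Quality control and cleaning of 5-s epoch traces: non-wear detection from
# prolonged stationarity, similar-time-of-day imputation, and wear-time
# validity checks.

#' Detect non-wear from prolonged stationarity
#'
#' Flags device-off periods as stationary episodes of at least `min_hours`
#' whose dispersion falls below `sd_threshold` (13.0 mg by default).
#' Operationally, a sliding window of `min_hours` is moved over the trace one
#' epoch at a time; every epoch covered by at least one window whose sample
#' standard deviation of vector magnitude is below the threshold is marked
#' non-wear. The union of flagged windows yields maximal stationary runs of at
#' least `min_hours` by construction.
#'
#' @param series An [epoch_series()].
#' @param sd_threshold Stationarity threshold on the windowed standard
#'   deviation, in milligravity.
#' @param min_hours Minimum duration of a stationary episode, in hours.
#' @return Logical wear mask (`TRUE` = worn) aligned with the series.
#' @export
detect_nonwear <- function(series, sd_threshold = 13.0, min_hours = 1) {
  stopifnot(inherits(series, "epoch_series"))
  x <- series$vm
  n <- length(x)
  k <- as.integer(round(min_hours * 3600 / series$epoch_seconds))
  if (n < k) {
    warning("series shorter than the minimum stationary episode; all wear")
    return(rep(TRUE, n))
  }
  rsd <- rolling_sd(x, k)
  starts <- which(rsd < sd_threshold)
  wear <- rep(TRUE, n)
  if (length(starts)) {
    # union of flagged length-k windows via a difference array
    delta <- integer(n + 1L)
    delta[starts] <- delta[starts] + 1L
    delta[starts + k] <- delta[starts + k] - 1L
    wear[cumsum(delta[seq_len(n)]) > 0L] <- FALSE
  }
  wear
}

# sample sd over every length-k window, via rolling sums
rolling_sd <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n - k + 1L)
  s <- cs[i + k] - cs[i]
  s2 <- cs2[i + k] - cs2[i]
  v <- (s2 - s^2 / k) / (k - 1)
  sqrt(pmax(v, 0))
}

#' Impute non-wear epochs from similar clock times on other days
#'
#' Each non-wear epoch's vector magnitude is replaced by the mean of wear-epoch
#' values observed at the identical 5-s clock slot on the other recorded days
#' (`slot` resolution), or within the same clock hour (`hour` resolution).
#' Wear epochs are untouched.
#'
#' @param series An [epoch_series()].
#' @param mask Logical wear mask from [detect_nonwear()].
#' @param resolution `"slot"` (identical 5-s clock slot, default) or `"hour"`
#'   (pool all wear epochs in the same clock hour).
#' @return A new `epoch_series` with imputed `vm` and the mask stored in
#'   `wear`.
#' @export
impute_nonwear <- function(series, mask, resolution = c("slot", "hour")) {
  stopifnot(inherits(series, "epoch_series"),
            is.logical(mask), length(mask) == length(series$vm))
  resolution <- match.arg(resolution)
  vm <- series$vm
  if (all(mask)) {
    out <- series
    out$wear <- mask
    return(out)
  }
  key <- if (resolution == "slot") epoch_clock_slot(series)
         else epoch_clock_hours(series) + 1L
  nkey <- if (resolution == "slot") EPOCHS_PER_DAY else 24L
  sums <- numeric(nkey)
  cnts <- numeric(nkey)
  tw <- rowsum(vm[mask], key[mask])
  idx <- as.integer(rownames(tw))
  sums[idx] <- tw[, 1L]
  cnts[idx] <- rowsum(rep(1, sum(mask)), key[mask])[, 1L]
  miss_key <- key[!mask]
  if (any(cnts[miss_key] == 0)) {
    bad <- unique(miss_key[cnts[miss_key] == 0])
    sec <- (bad[1L] - 1L) * (if (resolution == "slot") EPOCH_SECONDS else 3600L)
    stop(sprintf(
      "imputation impossible: clock slot %02d:%02d:%02d is non-wear on every day",
      sec %/% 3600L, (sec %% 3600L) %/% 60L, sec %% 60L), call. = FALSE)
  }
  vm[!mask] <- (sums / cnts)[miss_key]
  out <- series
  out$vm <- vm
  out$wear <- mask
  out
}

#' Wear-time validity report
#'
#' A trace is analysis-valid when it carries at least 72 h of wear and every
#' 1-h clock bin of the 24-h cycle is covered by wear on at least one day.
#'
#' @param series An `epoch_series` whose `wear` mask reflects non-wear
#'   detection.
#' @return A list of class `qc_report` with `wear_hours`,
#'   `hour_bins_covered`, `valid`, and `reasons`.
#' @export
qc_validity <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  wear_hours <- sum(series$wear) * series$epoch_seconds / 3600
  bins <- length(unique(epoch_clock_hours(series)[series$wear]))
  reasons <- character(0)
  if (wear_hours < 72) reasons <- c(reasons, "wear < 72 h")
  if (bins < 24L) reasons <- c(reasons, "hour bin uncovered")
  structure(list(wear_hours = wear_hours, hour_bins_covered = bins,
                 valid = length(reasons) == 0L, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %.1f h wear, %d/24 hour bins, %s\n",
              x$wear_hours, x$hour_bins_covered,
              if (x$valid) "valid" else paste("invalid:",
                                              paste(x$reasons, collapse = "; "))))
  invisible(x)
}
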