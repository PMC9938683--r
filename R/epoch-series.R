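#' @importFrom stats coef median pchisq pnorm qnorm quantile rbinom rexp rlnorm
#'   rmultinom rnorm rpois runif sd setNames vcov complete.cases lm predict
#'   p.adjust residuals as.formula aggregate rgamma
#' @importFrom utils head tail write.csv read.csv
NULL

EPOCH_SECONDS <- 5L
EPOCHS_PER_HOUR <- 3600L %/% EPOCH_SECONDS # 720
EPOCHS_PER_DAY <- 86400L %/% EPOCH_SECONDS # 17280

#' Per-participant 5-second epoch acceleration series
#'
#' Container for one participant's wrist-accelerometer trace: average vector
#' magnitude (milligravity) per 5-s epoch, uniformly spaced with no gaps.
#' Device-off periods are represented through the `wear` mask, never as
#' missing rows.
#'
#' @param participant_id Scalar identifier.
#' @param start `POSIXct` timestamp of the first epoch (local clock time).
#' @param vm Numeric vector of non-negative vector-magnitude values (mg).
#' @param wear Optional logical vector of the same length; `TRUE` marks epochs
#'   judged to be worn. Defaults to all-wear.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, start, vm, wear = NULL) {
  stopifnot(length(participant_id) == 1L, inherits(start, "POSIXct"),
            is.numeric(vm), length(vm) > 0L)
  if (anyNA(vm) || any(vm < 0)) {
    stop("vm values must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(wear)) wear <- rep(TRUE, length(vm))
  stopifnot(is.logical(wear), length(wear) == length(vm))
  lt <- as.POSIXlt(start)
  start_offset <- lt$hour * 3600L + lt$min * 60L + as.integer(lt$sec)
  structure(
    list(participant_id = as.character(participant_id),
         start = start,
         start_offset = start_offset, # seconds after local midnight
         epoch_seconds = EPOCH_SECONDS,
         vm = as.numeric(vm),
         wear = wear),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  hrs <- length(x$vm) * x$epoch_seconds / 3600
  cat(sprintf(
    "<epoch_series> participant %s: %d epochs (%.1f h), %.1f h wear\n",
    x$participant_id, length(x$vm), hrs,
    sum(x$wear) * x$epoch_seconds / 3600))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$vm)

# seconds after local midnight for each epoch start
epoch_clock_seconds <- function(series) {
  (series$start_offset + (seq_along(series$vm) - 1L) * series$epoch_seconds) %%
    86400L
}

# clock hour (0-23) containing each epoch
epoch_clock_hours <- function(series) {
  epoch_clock_seconds(series) %/% 3600L
}

# recording day index (1-based, day boundary at local midnight)
epoch_day_index <- function(series) {
  abs_sec <- series$start_offset +
    (seq_along(series$vm) - 1L) * series$epoch_seconds
  abs_sec %/% 86400L + 1L
}

# clock slot within the day (1..17280), used for similar-time-of-day imputation
epoch_clock_slot <- function(series) {
  epoch_clock_seconds(series) %/% series$epoch_seconds + 1L
}

#' Write / read epoch series as delimited text
#'
#' Plain-text interchange format: one row per epoch with columns
#' `participant_id`, `timestamp` (ISO-8601 local), `vm_mg`, and `wear`.
#'
#' @param series An `epoch_series`.
#' @param path Output file.
#' @return `write_epoch_series` returns `path` invisibly; `read_epoch_series`
#'   returns an `epoch_series`.
#' @export
write_epoch_series <- function(series, path) {
  stamps <- series$start + (seq_along(series$vm) - 1L) * series$epoch_seconds
  df <- data.frame(
    participant_id = series$participant_id,
    timestamp = format(stamps, "%Y-%m-%dT%H:%M:%S"),
    vm_mg = series$vm,
    wear = series$wear)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epoch_series
#' @export
read_epoch_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "timestamp", "vm_mg")
  if (!all(need %in% names(df))) {
    stop("corrupt epoch file '", path, "': missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  stamps <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(stamps)) {
    stop("corrupt epoch file '", path, "': unparseable timestamp at line ",
         which(is.na(stamps))[1L] + 1L, call. = FALSE)
  }
  wear <- if ("wear" %in% names(df)) as.logical(df$wear) else NULL
  epoch_series(df$participant_id[1L], stamps[1L], df$vm_mg, wear)
}
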