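#' RR-interval series
#'
#' Constructs and validates a beat-to-beat interval record for one subject.
#' Beat times are the cumulative sum of the intervals, in seconds from
#' `start_time`; each interval is attributed to the beat that closes it.
#'
#' @param subject_id subject identifier.
#' @param start_time recording start (ISO 8601 local clock time).
#' @param intervals RR intervals in milliseconds, all positive.
#' @param beat_times optional beat times in seconds from start; defaults to
#'   `cumsum(intervals) / 1000`. Must be strictly increasing.
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(subject_id, start_time, intervals, beat_times = NULL) {
  intervals <- as.numeric(intervals)
  if (!length(intervals)) stopf("empty RR series")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stopf("non-positive or non-finite RR interval")
  if (is.null(beat_times)) beat_times <- cumsum(intervals) / 1000
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) != length(intervals))
    stopf("beat_times and intervals lengths differ")
  if (any(diff(beat_times) <= 0)) stopf("beat_times must be strictly increasing")
  if (max(beat_times) - min(beat_times) > 26 * 3600)
    stopf("RR recording spans more than 26 h")
  structure(list(subject_id = as.character(subject_id),
                 start_time = parse_time(start_time),
                 intervals = intervals,
                 beat_times = beat_times),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s: %d beats, %.2f h from %s; mean RR %.1f ms\n",
              x$subject_id, length(x$intervals),
              diff(range(x$beat_times)) / 3600, format_time(x$start_time),
              mean(x$intervals)))
  invisible(x)
}

#' Read an RR-interval file
#'
#' Three Holter export dialects are supported; the dialect is an explicit
#' argument and never sniffed, because a silent misparse would corrupt all
#' downstream HRV values.
#'
#' * `"interval_list"`: one RR interval (ms) per line;
#' * `"cumulative_ms"`: one cumulative elapsed time (ms) per line, one row
#'   per beat; intervals are successive differences;
#' * `"timestamps"`: CSV with header `time_s,rr_ms` (beat time in seconds
#'   from the recording start, interval in ms).
#'
#' Non-numeric rows are rejected and counted (see attribute
#' `"rejected_rows"`); accepted + rejected always equals the number of
#' input rows.
#'
#' @param path file to read.
#' @param dialect one of `"interval_list"`, `"cumulative_ms"`, `"timestamps"`.
#' @param subject_id,start_time metadata for the resulting series.
#' @return an [rr_series()] with attribute `rejected_rows`.
#' @export
read_rr <- function(path, dialect = c("interval_list", "cumulative_ms", "timestamps"),
                    subject_id = "unknown", start_time = "1970-01-01 00:00:00") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "timestamps") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("time_s", "rr_ms") %in% names(df)))
      stopf("timestamps dialect needs columns time_s,rr_ms")
    ok <- is.finite(suppressWarnings(as.numeric(df$time_s))) &
          is.finite(suppressWarnings(as.numeric(df$rr_ms)))
    rejected <- sum(!ok)
    df <- df[ok, , drop = FALSE]
    if (!nrow(df)) stopf("empty RR file: %s", path)
    out <- rr_series(subject_id, start_time,
                     as.numeric(df$rr_ms), as.numeric(df$time_s))
  } else {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw)) stopf("empty RR file: %s", path)
    vals <- suppressWarnings(as.numeric(raw))
    rejected <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stopf("no numeric rows in %s", path)
    if (dialect == "cumulative_ms") {
      if (any(diff(vals) <= 0)) stopf("cumulative_ms values must increase")
      beat_times <- vals[-1] / 1000
      vals <- diff(vals)
      out <- rr_series(subject_id, start_time, vals, beat_times)
    } else {
      out <- rr_series(subject_id, start_time, vals)
    }
  }
  if (rejected > 0)
    message(sprintf("read_rr: rejected %d non-numeric row(s) of %d",
                    rejected, rejected + length(out$intervals)))
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write an RR series
#'
#' @param x an [rr_series()].
#' @param path output file.
#' @param dialect output format; see [read_rr()].
#' @return `path`, invisibly.
#' @export
write_rr <- function(x, path, dialect = c("interval_list", "cumulative_ms", "timestamps")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "rr_series"))
  if (dialect == "interval_list") {
    writeLines(sprintf("%.15g", x$intervals), path)
  } else if (dialect == "cumulative_ms") {
    start_ms <- (x$beat_times[1] * 1000) - x$intervals[1]
    writeLines(sprintf("%.15g", c(start_ms, x$beat_times * 1000)), path)
  } else {
    df <- data.frame(time_s = sprintf("%.15g", x$beat_times),
                     rr_ms = sprintf("%.15g", x$intervals))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Distal skin temperature series
#'
#' @param subject_id subject identifier.
#' @param time sample timestamps (strictly increasing).
#' @param temp_c temperatures in degrees Celsius; values outside 20--42 are
#'   rejected as logger-detachment artifacts.
#' @return object of class `temperature_series` (a data frame).
#' @export
temperature_series <- function(subject_id, time, temp_c) {
  time <- parse_time(time)
  temp_c <- as.numeric(temp_c)
  if (length(time) != length(temp_c)) stopf("time and temp_c lengths differ")
  if (!length(time)) stopf("empty temperature series")
  if (any(diff(as.numeric(time)) <= 0)) stopf("timestamps must be strictly increasing")
  if (any(!is.finite(temp_c)) || any(temp_c < 20 | temp_c > 42))
    stopf("temperature outside the plausible 20-42 degC window")
  structure(data.frame(time = time, temp_c = temp_c),
            subject_id = as.character(subject_id),
            class = c("temperature_series", "data.frame"))
}

#' Read / write a temperature CSV (`timestamp,temp_c`)
#' @param path file path.
#' @param subject_id subject identifier for the series.
#' @return [temperature_series()]
#' @export
read_temperature <- function(path, subject_id = "unknown") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df)))
    stopf("temperature CSV needs columns timestamp,temp_c")
  temperature_series(subject_id, df$timestamp, df$temp_c)
}

#' @rdname read_temperature
#' @param x a `temperature_series`.
#' @export
write_temperature <- function(x, path) {
  write.csv(data.frame(timestamp = format_time(x$time), temp_c = x$temp_c),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wrist-actigraphy epoch series
#'
#' @param subject_id subject identifier.
#' @param time epoch start timestamps at constant spacing.
#' @param counts non-negative integer activity counts per epoch.
#' @param epoch_length epoch length in seconds; must match the timestamp
#'   spacing.
#' @return object of class `activity_series` (a data frame).
#' @export
activity_series <- function(subject_id, time, counts, epoch_length = 60) {
  time <- parse_time(time)
  counts <- as.numeric(counts)
  if (length(time) != length(counts)) stopf("time and counts lengths differ")
  if (length(time) < 2) stopf("activity series needs at least 2 epochs")
  sp <- diff(as.numeric(time))
  if (any(abs(sp - epoch_length) > 1e-6))
    stopf("epoch spacing is not a constant %g s", epoch_length)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  structure(data.frame(time = time, counts = counts),
            subject_id = as.character(subject_id),
            epoch_length = epoch_length,
            class = c("activity_series", "data.frame"))
}

#' Read / write an activity CSV (`timestamp,counts`)
#' @param path file path.
#' @param subject_id subject identifier.
#' @param epoch_length epoch length in seconds.
#' @return [activity_series()]
#' @export
read_activity <- function(path, subject_id = "unknown", epoch_length = 60) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "counts") %in% names(df)))
    stopf("activity CSV needs columns timestamp,counts")
  activity_series(subject_id, df$timestamp, df$counts, epoch_length)
}

#' @rdname read_activity
#' @param x an `activity_series`.
#' @export
write_activity <- function(x, path) {
  write.csv(data.frame(timestamp = format_time(x$time), counts = x$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

COHORT_GROUPS <- c("CS", "O-LOAD")
COHORT_SEXES <- c("F", "M")

#' Cohort table
#'
#' Per-subject group labels, demographics and cognitive/clinical scores.
#' Downstream modules append derived physiology columns keyed on `id`.
#'
#' @param df data frame with at least `id`, `group` (`"CS"`/`"O-LOAD"`),
#'   `sex` (`"F"`/`"M"`) and `age`; score columns are free-form numeric.
#' @return validated `cohort_table` (a data frame).
#' @export
cohort_table <- function(df) {
  need <- c("id", "group", "sex", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("cohort table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stopf("duplicate subject id(s)")
  if (!all(df$group %in% COHORT_GROUPS))
    stopf("unknown group label(s): %s",
          paste(unique(setdiff(df$group, COHORT_GROUPS)), collapse = ", "))
  if (!all(df$sex %in% COHORT_SEXES))
    stopf("unknown sex label(s): %s",
          paste(unique(setdiff(df$sex, COHORT_SEXES)), collapse = ", "))
  df$id <- as.character(df$id)
  structure(as.data.frame(df), class = c("cohort_table", "data.frame"))
}

#' Read / write a cohort CSV (`id,group,sex,age,...scores`)
#' @param path file path.
#' @return [cohort_table()]
#' @export
read_cohort <- function(path) {
  cohort_table(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname read_cohort
#' @param x a `cohort_table`.
#' @export
write_cohort <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
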