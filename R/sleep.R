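#' Sleep diary intervals
#'
#' Resolves diary rows (`date`, `bed_time`, `rise_time` as clock times)
#' into absolute in-bed intervals. A bed time before noon is taken to fall
#' after midnight (i.e., on the calendar day following `date`); rise time
#' always falls on the day after `date`.
#'
#' @param date night dates (`YYYY-MM-DD`), one per night.
#' @param bed_time,rise_time clock times `"HH:MM"`.
#' @return data frame with POSIXct `bed` and `rise`.
#' @export
sleep_diary <- function(date, bed_time, rise_time) {
  if (!length(date)) stopf("empty diary")
  d0 <- parse_time(date)
  bed <- parse_time(paste(date, bed_time))
  bed_h <- clock_hour(bed)
  bed[bed_h < 12] <- bed[bed_h < 12] + 86400
  rise <- parse_time(paste(date, rise_time)) + 86400
  if (any(rise <= bed)) stopf("rise time not after bed time (check diary dates)")
  if (any(difftime(rise, bed, units = "hours") > 16))
    stopf("in-bed interval longer than 16 h (check diary times)")
  data.frame(date = d0, bed = bed, rise = rise)
}

#' @rdname sleep_diary
#' @param path CSV with columns `date,bed_time,rise_time`.
#' @export
read_diary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "bed_time", "rise_time")
  if (!all(need %in% names(df)))
    stopf("diary CSV needs columns %s", paste(need, collapse = ","))
  sleep_diary(df$date, df$bed_time, df$rise_time)
}

# Cole-Kripke weighted activity score per epoch (window -4..+2 around
# each minute); out-of-range neighbours contribute zero activity.
ck_score <- function(counts, weights) {
  n <- length(counts)
  s <- numeric(n)
  for (j in -4:2) {
    w <- weights[j + 5]
    idx <- seq_len(n) + j
    ok <- idx >= 1 & idx <= n
    s[ok] <- s[ok] + w * counts[idx[ok]]
  }
  s
}

# Webster-style rescoring: after a sustained wake run, the first minutes
# of the following sleep bout are rescored as wake.
rescore_webster <- function(asleep) {
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] || k == length(r$lengths)) next
    wake_len <- r$lengths[k]
    strip <- if (wake_len >= 15) 4 else if (wake_len >= 10) 3 else if (wake_len >= 4) 1 else 0
    if (strip > 0) {
      i0 <- ends[k] + 1
      i1 <- min(ends[k] + strip, ends[k + 1])
      asleep[i0:i1] <- FALSE
    }
  }
  asleep
}

#' Score sleep/wake from actigraphy
#'
#' Each epoch receives a linear weighted-window activity score
#' (Cole-Kripke weights over minutes -4..+2) and is scored asleep when the
#' score falls below the threshold, optionally followed by Webster-style
#' rescoring of sleep immediately after sustained wake. Within each diary
#' in-bed interval, sleep onset is the start of the first run of at least
#' `cfg$onset_run_min` consecutive sleep epochs and sleep offset is the
#' end of the last such run; nights with no qualifying run are flagged.
#' Scored-sleep runs of at least `cfg$nap_min` minutes outside every
#' in-bed interval are recorded as naps.
#'
#' @param activity an [activity_series()] covering the diary interval(s).
#' @param diary a [sleep_diary()] data frame.
#' @param cfg a [run_config()].
#' @return object of class `sleep_intervals`: list with `nights` (bed,
#'   rise, onset, offset, flagged), `naps` (start, end), `epochs`
#'   (time, counts, score, state in wake/sleep/nap) and `epoch_length`.
#' @export
score_epochs <- function(activity, diary, cfg = run_config()) {
  stopifnot(inherits(activity, "activity_series"))
  if (!nrow(diary)) stopf("empty diary")
  ep <- attr(activity, "epoch_length")
  t0 <- activity$time
  t1 <- t0 + ep
  if (any(diary$bed < min(t0) - ep | diary$rise > max(t1) + ep))
    stopf("diary interval outside the activity recording")
  s <- ck_score(activity$counts, cfg$ck_weights)
  asleep <- s < cfg$ck_threshold
  if (cfg$rescore) asleep <- rescore_webster(asleep)

  in_bed <- rep(FALSE, length(t0))
  for (i in seq_len(nrow(diary)))
    in_bed <- in_bed | (t0 >= diary$bed[i] & t0 < diary$rise[i])

  nights <- diary
  nights$onset <- as.POSIXct(rep(NA_real_, nrow(diary)), origin = "1970-01-01", tz = "UTC")
  nights$offset <- nights$onset
  nights$flagged <- FALSE
  for (i in seq_len(nrow(diary))) {
    idx <- which(t0 >= diary$bed[i] & t0 < diary$rise[i])
    runs <- run_bounds(asleep[idx], cfg$onset_run_min)
    if (!nrow(runs)) {
      nights$flagged[i] <- TRUE
      next
    }
    nights$onset[i] <- t0[idx[runs$start[1]]]
    nights$offset[i] <- t0[idx[runs$end[nrow(runs)]]] + ep
  }

  state <- ifelse(asleep & in_bed, "sleep", "wake")
  naps <- data.frame(start = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                     end = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))
  out_runs <- run_bounds(asleep & !in_bed, ceiling(cfg$nap_min * 60 / ep))
  for (k in seq_len(nrow(out_runs))) {
    i0 <- out_runs$start[k]; i1 <- out_runs$end[k]
    state[i0:i1] <- "nap"
    naps <- rbind(naps, data.frame(start = t0[i0], end = t0[i1] + ep))
  }

  structure(list(nights = nights, naps = naps,
                 epochs = data.frame(time = t0, counts = activity$counts,
                                     score = s, state = state),
                 epoch_length = ep),
            class = "sleep_intervals")
}

# start/end indices of TRUE runs of length >= min_len
run_bounds <- function(x, min_len) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.sleep_intervals <- function(x, ...) {
  cat(sprintf("<sleep_intervals> %d night(s) (%d flagged), %d nap(s), %d epochs\n",
              nrow(x$nights), sum(x$nights$flagged), nrow(x$naps),
              nrow(x$epochs)))
  invisible(x)
}

#' Sleep parameters from scored nights
#'
#' Per night: minutes asleep inside the in-bed window, time awake (their
#' complement) and efficiency = 100 * asleep / time in bed; onset and
#' offset clock times. Multi-night recordings are averaged per subject,
#' clock times by circular (vector) mean. Flagged nights are skipped.
#'
#' @param si a `sleep_intervals` from [score_epochs()].
#' @return one-row data frame: `start_time` and `end_time` (decimal clock
#'   hours), `duration_asleep` and `time_awake` (min), `efficiency` (%),
#'   `n_nights`, `n_flagged`.
#' @export
sleep_params <- function(si) {
  stopifnot(inherits(si, "sleep_intervals"))
  nights <- si$nights[!si$nights$flagged, , drop = FALSE]
  if (!nrow(nights)) stopf("no scorable night present")
  ep <- si$epoch_length
  t0 <- si$epochs$time
  asleep <- si$epochs$state == "sleep"
  per <- lapply(seq_len(nrow(nights)), function(i) {
    inb <- t0 >= nights$bed[i] & t0 < nights$rise[i]
    in_bed_min <- as.numeric(difftime(nights$rise[i], nights$bed[i], units = "mins"))
    asleep_min <- sum(asleep & inb) * ep / 60
    data.frame(onset_h = clock_hour(nights$onset[i]),
               offset_h = clock_hour(nights$offset[i]),
               duration_asleep = asleep_min,
               time_awake = in_bed_min - asleep_min,
               efficiency = 100 * asleep_min / in_bed_min)
  })
  per <- do.call(rbind, per)
  data.frame(start_time = circ_mean_clock(per$onset_h),
             end_time = circ_mean_clock(per$offset_h),
             duration_asleep = mean(per$duration_asleep),
             time_awake = mean(per$time_awake),
             efficiency = mean(per$efficiency),
             n_nights = nrow(per),
             n_flagged = sum(si$nights$flagged))
}
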