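#' Cut an RR recording into fixed-length fragments
#'
#' Consecutive half-open windows `[k*f, (k+1)*f)` minutes from the
#' recording start; a beat exactly on a boundary belongs to the next
#' fragment; the trailing partial fragment is dropped.
#'
#' @param rr an [rr_series()].
#' @param fragment_min fragment length in minutes.
#' @return list of `rr_series` fragments; each carries attributes
#'   `offset_s` (window start relative to the recording start) and
#'   `window_s` (length). Empty fragments are kept as `NULL` entries so
#'   indexing stays aligned with the time axis.
#' @export
segment_rr <- function(rr, fragment_min = 30) {
  stopifnot(inherits(rr, "rr_series"))
  if (!length(rr$intervals)) stopf("empty recording")
  f <- fragment_min * 60
  span <- max(rr$beat_times)
  nfrag <- floor(span / f)
  if (nfrag < 2) stopf("recording shorter than 2 fragments")
  lapply(seq_len(nfrag) - 1L, function(k) {
    sel <- rr$beat_times >= k * f & rr$beat_times < (k + 1) * f
    if (!any(sel)) return(NULL)
    out <- rr_series(rr$subject_id, rr$start_time,
                     rr$intervals[sel], rr$beat_times[sel])
    attr(out, "offset_s") <- k * f
    attr(out, "window_s") <- f
    out
  })
}

#' Assign sleep/wake/nap state to RR fragments
#'
#' A fragment takes the `sleep` state when at least `cfg$state_overlap`
#' of its span lies within a scored nocturnal sleep interval
#' (onset--offset), `nap` when that fraction lies within a scored nap,
#' and `wake` otherwise. Naps are excluded from both state averages
#' downstream.
#'
#' @param fragments output of [segment_rr()].
#' @param si a `sleep_intervals` from [score_epochs()].
#' @param rr_start recording start time (POSIXct); defaults to the
#'   `start_time` of the first non-empty fragment.
#' @param cfg a [run_config()].
#' @return character vector of states, one per fragment.
#' @export
assign_states <- function(fragments, si, rr_start = NULL, cfg = run_config()) {
  stopifnot(inherits(si, "sleep_intervals"))
  if (is.null(rr_start)) {
    first <- Filter(Negate(is.null), fragments)[[1]]
    rr_start <- first$start_time
  }
  nights <- si$nights[!si$nights$flagged, , drop = FALSE]
  sleep_iv <- cbind(as.numeric(nights$onset), as.numeric(nights$offset))
  nap_iv <- cbind(as.numeric(si$naps$start), as.numeric(si$naps$end))
  t0 <- as.numeric(rr_start)
  states <- character(length(fragments))
  any_overlap <- FALSE
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    off <- if (is.null(fr)) (i - 1) * 1800 else attr(fr, "offset_s")
    win <- if (is.null(fr)) 1800 else attr(fr, "window_s")
    a <- t0 + off
    b <- a + win
    fs <- overlap_frac(a, b, sleep_iv)
    fn <- overlap_frac(a, b, nap_iv)
    if (fs > 0 || fn > 0) any_overlap <- TRUE
    states[i] <- if (fs >= cfg$state_overlap) "sleep"
                 else if (fn >= cfg$state_overlap) "nap"
                 else "wake"
  }
  if (!any_overlap && nrow(nights))
    stopf("actigraphy sleep intervals do not overlap the RR recording")
  states
}

# fraction of [a,b) covered by union of rows of iv (assumed disjoint)
overlap_frac <- function(a, b, iv) {
  if (!nrow(iv)) return(0)
  ov <- pmin(b, iv[, 2]) - pmax(a, iv[, 1])
  sum(pmax(0, ov)) / (b - a)
}

#' Average per-fragment HRV metrics by sleep/wake state
#'
#' Unweighted mean of every metric over the fragments assigned to each
#' state, plus the sleep-minus-wake difference of every field. Nap
#' fragments enter neither average. Note the ratio convention: `lh_ratio`
#' is averaged across fragments, not recomputed from averaged powers.
#'
#' @param metrics data frame of per-fragment metrics ([hrv_metrics()]
#'   rows; `NA`-row or dropped fragments allowed via `NULL`-padding with
#'   [rbind_metrics()]).
#' @param states character vector of fragment states, same length as
#'   `nrow(metrics)`.
#' @return object of class `state_summary`: data frame with rows `wake`,
#'   `sleep`, `diff`; attributes `n_wake`, `n_sleep`, `n_nap`, `valid`.
#' @export
summarize_states <- function(metrics, states) {
  if (nrow(metrics) != length(states))
    stopf("metrics rows and states length differ")
  usable <- stats::complete.cases(metrics)
  wake <- metrics[states == "wake" & usable, , drop = FALSE]
  sleep <- metrics[states == "sleep" & usable, , drop = FALSE]
  valid <- nrow(wake) >= 1 && nrow(sleep) >= 1
  mw <- colMeans(wake)
  ms <- colMeans(sleep)
  out <- as.data.frame(rbind(wake = mw, sleep = ms, diff = ms - mw))
  structure(out, n_wake = nrow(wake), n_sleep = nrow(sleep),
            n_nap = sum(states == "nap"), valid = valid,
            class = c("state_summary", "data.frame"))
}

#' Bind per-fragment metric rows, padding dropped fragments with NA
#'
#' @param rows list of one-row data frames or `NULL`s (unusable fragments).
#' @return data frame with one row per fragment.
#' @export
rbind_metrics <- function(rows) {
  proto <- Filter(Negate(is.null), rows)
  if (!length(proto)) stopf("no usable fragments")
  nm <- names(proto[[1]])
  filled <- lapply(rows, function(r) {
    if (is.null(r)) as.data.frame(as.list(stats::setNames(rep(NA_real_, length(nm)), nm)))
    else r
  })
  do.call(rbind, filled)
}
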