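#' Full analysis pipeline for one subject
#'
#' Runs the complete chain on one subject's raw recordings: actigraphy
#' sleep scoring and sleep parameters, cosinor fit of the temperature
#' rhythm, RR cleaning, 30-min segmentation, per-fragment HRV, state
#' assignment from the scored sleep intervals, and the wake/sleep/
#' difference summary.
#'
#' @param rr an [rr_series()] (about 24 h).
#' @param activity an [activity_series()] covering the diary.
#' @param temperature a [temperature_series()] (about 7 days).
#' @param diary a [sleep_diary()].
#' @param cfg a [run_config()].
#' @return list with `sleep` ([sleep_params()] row), `cosinor`
#'   ([fit_cosinor()]), `states` (per-fragment labels), `summary`
#'   ([summarize_states()]) and `row` (one flat row of derived
#'   physiology, see [analyze_cohort()]).
#' @export
subject_pipeline <- function(rr, activity, temperature, diary, cfg = run_config()) {
  si <- score_epochs(activity, diary, cfg)
  sp <- sleep_params(si)
  fit <- fit_cosinor(temperature, cfg$harmonics)
  frags <- segment_rr(rr, cfg$fragment_min)
  states <- assign_states(frags, si, rr$start_time, cfg)
  mets <- rbind_metrics(lapply(frags, function(fr) {
    if (is.null(fr)) NULL else hrv_metrics(fr, cfg)
  }))
  summ <- summarize_states(mets, states)
  row <- data.frame(
    id = rr$subject_id,
    pct_rhythm = fit$pct_rhythm, mesor = fit$mesor,
    amplitude = fit$amplitude, acrophase = fit$acrophase,
    start_time = sp$start_time, end_time = sp$end_time,
    duration_asleep = sp$duration_asleep, time_awake = sp$time_awake,
    efficiency = sp$efficiency,
    hrv_valid = isTRUE(attr(summ, "valid")))
  for (st in rownames(summ)) {
    block <- summ[st, , drop = FALSE]
    names(block) <- paste0(st, "_", names(block))
    row <- cbind(row, block, row.names = NULL)
  }
  list(sleep = sp, cosinor = fit, states = states, summary = summ, row = row)
}

#' Run the pipeline over a cohort of raw series
#'
#' @param series named list (one entry per subject) of lists with
#'   elements `rr`, `activity`, `temperature`, `diary`, as produced by
#'   [gen_cohort()].
#' @param cfg a [run_config()].
#' @return data frame with one row per subject: cosinor parameters, sleep
#'   parameters, and `wake_*`, `sleep_*`, `diff_*` HRV summary columns.
#' @export
analyze_cohort <- function(series, cfg = run_config()) {
  rows <- lapply(series, function(s) {
    subject_pipeline(s$rr, s$activity, s$temperature, s$diary, cfg)$row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
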