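#' Synthetic subject specification
#'
#' Ground-truth generative parameters for one subject: a 24-h cosine
#' temperature rhythm, a state-modulated RR tachogram with LF and HF
#' tones, a sleep schedule driving both the RR state and the actigraphy
#' trace, and cognitive score distributions with an optional correlation
#' injected between realized nighttime sympathovagal balance and a named
#' score.
#'
#' @param group `"CS"` or `"O-LOAD"`.
#' @param mesor,amplitude,acrophase,temp_noise_sd temperature rhythm:
#'   rhythm-adjusted mean (degC), half-range above the MESOR (degC), clock
#'   hour of the maximum in `[0, 24)`, Gaussian sample noise SD (degC).
#' @param rr_wake_ms,rr_sleep_ms mean RR interval by behavioural state (ms).
#' @param lf_hz,lf_depth_ms,hf_hz,hf_depth_ms frequencies (Hz, in
#'   `(0, 1.2)`) and additive modulation depths (ms) of the LF and HF
#'   tones on the tachogram.
#' @param jitter_sd_ms beat-to-beat Gaussian jitter SD (ms).
#' @param bed_time,rise_time clock times `"HH:MM"`; a bed time before
#'   noon is interpreted as after midnight.
#' @param latency_min minutes between bed time and sleep onset.
#' @param naps data frame with `start_h` (clock hour) and `dur_min`, or
#'   `NULL`.
#' @param wake_lambda,sleep_move_prob,sleep_burst_lambda actigraphy count
#'   model: Poisson mean while awake; probability and Poisson mean of
#'   isolated movement bursts while asleep.
#' @param activity_noise `FALSE` generates deterministic counts
#'   (`wake_lambda` awake, 0 asleep) for degenerate checks.
#' @param score_means,score_sds named numeric vectors of cognitive /
#'   clinical score distributions.
#' @param age_mean,age_sd,p_female demographics.
#' @param inject_r,inject_score,inject_state correlation injected between
#'   the realized state L/H (`inject_state` in `"sleep"`, `"wake"`,
#'   `"diff"`) and `inject_score`; `inject_r = 0` disables injection.
#' @return object of class `subject_spec` (a validated list).
#' @export
subject_spec <- function(group = "CS",
                         mesor = 33, amplitude = 1, acrophase = 3,
                         temp_noise_sd = 0.3,
                         rr_wake_ms = 800, rr_sleep_ms = 920,
                         lf_hz = 0.1, lf_depth_ms = 15,
                         hf_hz = 0.25, hf_depth_ms = 30,
                         jitter_sd_ms = 10,
                         bed_time = "00:00", rise_time = "08:00",
                         latency_min = 10, naps = NULL,
                         wake_lambda = 200, sleep_move_prob = 0.015,
                         sleep_burst_lambda = 120, activity_noise = TRUE,
                         score_means = NULL, score_sds = NULL,
                         age_mean = 54, age_sd = 9, p_female = 0.72,
                         inject_r = 0, inject_score = NA_character_,
                         inject_state = "sleep") {
  if (!group %in% COHORT_GROUPS) stopf("unknown group label: %s", group)
  vals <- c(mesor, amplitude, acrophase, temp_noise_sd, rr_wake_ms,
            rr_sleep_ms, lf_hz, lf_depth_ms, hf_hz, hf_depth_ms, jitter_sd_ms)
  if (any(!is.finite(vals))) stopf("non-finite subject specification value")
  if (acrophase < 0 || acrophase >= 24) stopf("acrophase must lie in [0, 24)")
  if (lf_hz <= 0 || lf_hz >= 1.2 || hf_hz <= 0 || hf_hz >= 1.2)
    stopf("tone frequencies must lie in (0, 1.2) Hz")
  if (lf_depth_ms < 0 || hf_depth_ms < 0) stopf("tone depths must be >= 0")
  if (abs(inject_r) >= 1) stopf("|inject_r| must be < 1")
  if (!is.null(naps)) {
    if (!all(c("start_h", "dur_min") %in% names(naps)))
      stopf("naps needs columns start_h,dur_min")
  }
  structure(list(group = group, mesor = mesor, amplitude = amplitude,
                 acrophase = acrophase, temp_noise_sd = temp_noise_sd,
                 rr_wake_ms = rr_wake_ms, rr_sleep_ms = rr_sleep_ms,
                 lf_hz = lf_hz, lf_depth_ms = lf_depth_ms,
                 hf_hz = hf_hz, hf_depth_ms = hf_depth_ms,
                 jitter_sd_ms = jitter_sd_ms,
                 bed_time = bed_time, rise_time = rise_time,
                 latency_min = latency_min, naps = naps,
                 wake_lambda = wake_lambda, sleep_move_prob = sleep_move_prob,
                 sleep_burst_lambda = sleep_burst_lambda,
                 activity_noise = isTRUE(activity_noise),
                 score_means = score_means, score_sds = score_sds,
                 age_mean = age_mean, age_sd = age_sd, p_female = p_female,
                 inject_r = inject_r, inject_score = inject_score,
                 inject_state = inject_state),
            class = "subject_spec")
}

#' Default group-level subject specifications
#'
#' The defaults encode the study conditions the generator emulates: a
#' control group (CS) with temperature MESOR 33.03 degC, amplitude
#' 0.99 degC and acrophase 2.56 h, and an at-risk group (O-LOAD) with
#' MESOR 32.16, amplitude 0.96 and a phase-delayed acrophase of 3.80 h;
#' wake/sleep mean RR of 778.5/902.9 ms (CS) and 794.7/926.3 ms (O-LOAD),
#' i.e. a programmed sleep-minus-wake difference of about +130 ms; and
#' cognitive score means/SDs on the scale of the emulated cohort. The
#' O-LOAD default injects a correlation of -0.744 between realized sleep
#' L/H and the verbal-memory score (RAVLT).
#'
#' @param group `"CS"` or `"O-LOAD"`.
#' @return a [subject_spec()].
#' @export
default_subject_spec <- function(group = c("CS", "O-LOAD")) {
  group <- match.arg(group)
  if (group == "CS") {
    subject_spec(
      group = "CS", mesor = 33.03, amplitude = 0.99, acrophase = 2.56,
      temp_noise_sd = 0.3, rr_wake_ms = 778.49, rr_sleep_ms = 902.90,
      bed_time = "00:33", rise_time = "07:55", latency_min = 10,
      score_means = c(Education = 17.1, CRQ = 17.2, Hachinski = 1.1,
                      BDI = 9.1, HDRS = 7.9, PSQI = 5.7, ESS = 8.9,
                      MMSE = 29.3, Clock = 5.9, Vocabulary = 51.4,
                      SemanticFluency = 21.4, RAVLT = 45.6, RAVLT_D = 10.6),
      score_sds = c(Education = 5.23, CRQ = 3.05, Hachinski = 1.31,
                    BDI = 8.28, HDRS = 5.67, PSQI = 3.92, ESS = 4.36,
                    MMSE = 0.87, Clock = 1.31, Vocabulary = 5.67,
                    SemanticFluency = 5.67, RAVLT = 9.59, RAVLT_D = 1.74),
      age_mean = 54.2, age_sd = 9.59, p_female = 0.737,
      inject_r = 0)
  } else {
    subject_spec(
      group = "O-LOAD", mesor = 32.16, amplitude = 0.96, acrophase = 3.80,
      temp_noise_sd = 0.3, rr_wake_ms = 794.71, rr_sleep_ms = 926.33,
      bed_time = "23:50", rise_time = "07:55", latency_min = 10,
      score_means = c(Education = 16.3, CRQ = 15.3, Hachinski = 1.2,
                      BDI = 8.8, HDRS = 8.8, PSQI = 6.3, ESS = 9.3,
                      MMSE = 28.9, Clock = 6.0, Vocabulary = 44.3,
                      SemanticFluency = 20.7, RAVLT = 42.9, RAVLT_D = 8.6),
      score_sds = c(Education = 2.23, CRQ = 3.90, Hachinski = 1.11,
                    BDI = 6.68, HDRS = 7.24, PSQI = 3.90, ESS = 4.45,
                    MMSE = 1.11, Clock = 1.11, Vocabulary = 8.35,
                    SemanticFluency = 3.90, RAVLT = 7.24, RAVLT_D = 3.34),
      age_mean = 53.8, age_sd = 8.91, p_female = 0.71,
      inject_r = -0.744, inject_score = "RAVLT", inject_state = "sleep")
  }
}

# asleep clock-hour intervals (rows lo, hi on [0,24), wrap split) from a spec
asleep_clock_intervals <- function(spec, include_latency = FALSE, include_naps = TRUE) {
  bed <- clock_to_hours(spec$bed_time)
  rise <- clock_to_hours(spec$rise_time)
  onset <- if (include_latency) bed else (bed + spec$latency_min / 60) %% 24
  iv <- split_wrap(onset, rise)
  if (include_naps && !is.null(spec$naps)) {
    for (i in seq_len(nrow(spec$naps))) {
      iv <- rbind(iv, split_wrap(spec$naps$start_h[i],
                                 (spec$naps$start_h[i] + spec$naps$dur_min[i] / 60) %% 24))
    }
  }
  iv
}

clock_to_hours <- function(hhmm) {
  p <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] + p[2] / 60
}

split_wrap <- function(lo, hi) {
  if (lo < hi) matrix(c(lo, hi), 1) else matrix(c(lo, 24, 0, hi), 2, byrow = TRUE)
}

in_intervals <- function(h, iv) {
  for (r in seq_len(nrow(iv))) if (h >= iv[r, 1] && h < iv[r, 2]) return(TRUE)
  FALSE
}

#' Generate a synthetic distal temperature series
#'
#' `value(t) = MESOR + amplitude * cos(2*pi*(clock(t) - acrophase)/24)`
#' plus Gaussian noise, sampled every 10 minutes from midnight.
#'
#' @param spec a [subject_spec()].
#' @param days number of days (>= 1).
#' @param seed RNG seed (`NULL` = ambient stream).
#' @param start_date first midnight of the series.
#' @param subject_id series identifier.
#' @return a [temperature_series()].
#' @export
gen_temperature <- function(spec, days = 7, seed = NULL,
                            start_date = "2026-01-05", subject_id = "sim") {
  stopifnot(inherits(spec, "subject_spec"), days >= 1)
  t0 <- parse_time(start_date)
  n <- as.integer(days * 144)
  time <- t0 + 600 * (seq_len(n) - 1)
  h <- (as.numeric(time - t0, units = "secs") / 3600 + clock_hour(t0)) %% 24
  v <- spec$mesor + spec$amplitude * cos(2 * pi * (h - spec$acrophase) / 24)
  v <- v + with_seed(seed, rnorm(n, 0, spec$temp_noise_sd))
  temperature_series(subject_id, time, v)
}

#' Generate a synthetic RR-interval series
#'
#' Additive tachogram model: the instantaneous RR interval is the state
#' mean (sleep/wake per the schedule, naps included) plus an LF and an HF
#' sinusoidal tone plus Gaussian jitter; each beat advances time by its
#' own interval. Optionally a fraction of beats is corrupted into
#' ectopic-like artifacts (interval scaled by 1.7), with their indices
#' recorded in attribute `ectopic_idx` for filter-validation studies.
#'
#' @param spec a [subject_spec()].
#' @param hours recording duration.
#' @param seed RNG seed.
#' @param start_time recording start (clock anchors the sleep schedule).
#' @param subject_id series identifier.
#' @param ectopic_rate fraction of beats corrupted.
#' @return an [rr_series()].
#' @export
gen_rr <- function(spec, hours = 24, seed = NULL,
                   start_time = "2026-01-06 00:00:00", subject_id = "sim",
                   ectopic_rate = 0) {
  stopifnot(inherits(spec, "subject_spec"), hours > 0)
  t0 <- parse_time(start_time)
  start_h <- clock_hour(t0)
  iv <- asleep_clock_intervals(spec)
  dur <- hours * 3600
  cap <- ceiling(dur / max(0.25, (min(spec$rr_wake_ms, spec$rr_sleep_ms) -
                                    spec$lf_depth_ms - spec$hf_depth_ms -
                                    5 * spec$jitter_sd_ms) / 1000)) + 16L
  with_seed(seed, {
    jit <- if (spec$jitter_sd_ms > 0) rnorm(cap, 0, spec$jitter_sd_ms) else numeric(cap)
    rr <- numeric(cap)
    wlf <- 2 * pi * spec$lf_hz
    whf <- 2 * pi * spec$hf_hz
    t <- 0
    i <- 0L
    while (t < dur) {
      i <- i + 1L
      if (i > length(rr)) {   # short intervals can exceed the preallocation
        jit <- c(jit, if (spec$jitter_sd_ms > 0) rnorm(cap, 0, spec$jitter_sd_ms)
                      else numeric(cap))
        rr <- c(rr, numeric(cap))
      }
      h <- (start_h + t / 3600) %% 24
      base <- if (in_intervals(h, iv)) spec$rr_sleep_ms else spec$rr_wake_ms
      x <- base + spec$lf_depth_ms * sin(wlf * t) +
        spec$hf_depth_ms * sin(whf * t) + jit[i]
      # below 1 ms the beat-advance step collapses toward zero, so treat it
      # as the same degenerate condition as a non-positive interval
      if (x < 1) stopf("generated RR <= 0: tone depths too large for mean RR")
      rr[i] <- x
      t <- t + x / 1000
    }
    rr <- rr[seq_len(i)]
    ect <- integer(0)
    if (ectopic_rate > 0) {
      ect <- which(rbinom(i, 1, ectopic_rate) == 1)
      rr[ect] <- rr[ect] * 1.7
    }
    out <- rr_series(subject_id, t0, rr)
    attr(out, "ectopic_idx") <- ect
    out
  })
}

#' Generate a synthetic actigraphy trace
#'
#' One-minute epochs from midnight: Poisson counts with mean
#' `wake_lambda` while awake (including the sleep-latency minutes in
#' bed), and mostly-zero counts while asleep with isolated movement
#' bursts; naps inherit the asleep model. With `activity_noise = FALSE`
#' counts are deterministic (`wake_lambda` awake, 0 asleep).
#'
#' @inheritParams gen_temperature
#' @return an [activity_series()].
#' @export
gen_activity <- function(spec, days = 7, seed = NULL,
                         start_date = "2026-01-05", subject_id = "sim") {
  stopifnot(inherits(spec, "subject_spec"), days >= 1)
  # latency minutes count as wake; naps validated against the night window
  iv <- asleep_clock_intervals(spec, include_naps = FALSE)
  if (!is.null(spec$naps)) {
    for (i in seq_len(nrow(spec$naps))) {
      s <- spec$naps$start_h[i]
      e <- s + spec$naps$dur_min[i] / 60
      if (any(s < iv[, 2] & e > iv[, 1]))
        stopf("nap interval overlaps the nocturnal sleep window")
    }
    iv <- asleep_clock_intervals(spec)
  }
  t0 <- parse_time(start_date)
  n <- as.integer(days * 1440)
  time <- t0 + 60 * (seq_len(n) - 1)
  h <- (as.numeric(time - t0, units = "secs") / 3600 + clock_hour(t0)) %% 24
  asleep <- vapply(h, in_intervals, logical(1), iv = iv)
  counts <- with_seed(seed, {
    if (!spec$activity_noise) {
      ifelse(asleep, 0, spec$wake_lambda)
    } else {
      cw <- rpois(n, spec$wake_lambda)
      burst <- rbinom(n, 1, spec$sleep_move_prob) * rpois(n, spec$sleep_burst_lambda)
      ifelse(asleep, burst, cw)
    }
  })
  activity_series(subject_id, time, counts)
}

#' Synthetic cohort specification
#'
#' @param n_cs,n_oload group sizes (>= 2 each).
#' @param seed master seed; per-subject sub-seeds are derived from it, so
#'   an identical seed reproduces the cohort bit for bit.
#' @param days days of temperature/actigraphy recording.
#' @param rr_hours duration of the RR recording (starting at the second
#'   midnight, so a full night falls inside it).
#' @param start_date first midnight of all recordings.
#' @param cs,oload group-level [subject_spec()]s.
#' @param between named list of between-subject SDs for the physiological
#'   parameters (`acrophase`, `mesor`, `amplitude`, `rr_wake`, `rr_diff`,
#'   `bed_min`); see [default_between_sds()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cs = 19, n_oload = 31, seed = NULL, days = 7,
                        rr_hours = 24, start_date = "2026-01-05",
                        cs = default_subject_spec("CS"),
                        oload = default_subject_spec("O-LOAD"),
                        between = default_between_sds()) {
  if (n_cs < 2 || n_oload < 2) stopf("need n >= 2 per group for statistics")
  structure(list(n_cs = as.integer(n_cs), n_oload = as.integer(n_oload),
                 seed = seed, days = days, rr_hours = rr_hours,
                 start_date = start_date, cs = cs, oload = oload,
                 between = between),
            class = "cohort_spec")
}

#' Default between-subject parameter SDs
#'
#' Between-subject spread of the generated physiology, per group, on the
#' scale of the emulated cohort (SE * sqrt(n) of the respective group
#' block): temperature acrophase 1.82/1.33 h, amplitude 0.43/0.46 degC,
#' MESOR 0.54 degC (both groups; see the methods vignette for why the
#' at-risk MESOR spread is not taken at face value), wake RR 83/93 ms and
#' sleep-minus-wake RR difference 105/100 ms (drawn as wake + difference
#' so the two state means stay strongly correlated within subject), and
#' about 1 h of bed-time spread.
#'
#' @return named list with `CS` and `O-LOAD` entries.
#' @export
default_between_sds <- function() {
  list(
    "CS" = c(acrophase = 1.82, mesor = 0.54, amplitude = 0.43,
             rr_wake = 82.6, rr_diff = 105.5, bed_min = 58),
    "O-LOAD" = c(acrophase = 1.33, mesor = 0.54, amplitude = 0.46,
                 rr_wake = 93.0, rr_diff = 100.1, bed_min = 74)
  )
}

#' Construct a score with a target correlation to realized physiology
#'
#' Linear-plus-noise construction: with `z` the standardized physiology
#' values, returns `mean + sd * (r * z + sqrt(1 - r^2) * eps)`,
#' `eps ~ N(0, 1)`, whose population correlation with the physiology is
#' `r`. Used by [gen_cohort()] to tie a cognitive score to each
#' subject's realized (post-pipeline) state L/H.
#'
#' @param x realized physiology values (one per subject).
#' @param r target correlation, `|r| < 1`.
#' @param mean,sd score distribution.
#' @return numeric vector of scores, same length as `x`.
#' @export
inject_correlated_score <- function(x, r, mean = 0, sd = 1) {
  if (abs(r) >= 1) stopf("|r| must be < 1")
  z <- as.numeric(scale(x))
  z[is.na(z)] <- 0
  mean + sd * (r * z + sqrt(1 - r^2) * rnorm(length(x)))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject physiological parameters around the group-level
#' specs, generates each subject's raw temperature, activity, diary and
#' RR series, optionally runs the full analysis pipeline on them, and
#' draws cognitive scores. When a group's `inject_r` is non-zero, that
#' score is constructed from the subject's *realized* (post-pipeline)
#' state L/H by the linear-plus-noise construction
#' `score = mean + sd * (r * z + sqrt(1 - r^2) * eps)` with `z` the
#' standardized realized L/H, so the injected association exercises the
#' whole analysis chain.
#'
#' @param spec a [cohort_spec()].
#' @param cfg a [run_config()] used for the internal pipeline run.
#' @param analyze run the analysis pipeline (forced `TRUE` when any
#'   injection is requested).
#' @return list with `cohort` (a [cohort_table()] including scores),
#'   `series` (per-subject list of `rr`, `activity`, `temperature`,
#'   `diary`), `derived` (per-subject pipeline outputs, see
#'   [analyze_cohort()]; `NULL` if not analyzed) and `truth` (per-subject
#'   generating parameters and the injection settings).
#' @export
gen_cohort <- function(spec = cohort_spec(), cfg = run_config(), analyze = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("CS", spec$n_cs), rep("O-LOAD", spec$n_oload))
  n <- length(groups)
  ids <- sprintf("S%02d", seq_len(n))
  seeds <- derive_seeds(spec$seed, n + 1L)
  inject_any <- spec$cs$inject_r != 0 || spec$oload$inject_r != 0
  if (inject_any) analyze <- TRUE

  subjects <- vector("list", n)
  series <- vector("list", n)
  names(series) <- ids
  truth_rows <- vector("list", n)
  sex_v <- character(n)
  age_v <- numeric(n)
  for (i in seq_len(n)) {
    g <- groups[i]
    gs <- if (g == "CS") spec$cs else spec$oload
    bw <- spec$between[[g]]
    si <- with_seed(seeds[[i]], {
      acro <- rtrunc_norm(1, gs$acrophase, bw[["acrophase"]], gs$acrophase - 6,
                          gs$acrophase + 6) %% 24
      mes <- rtrunc_norm(1, gs$mesor, bw[["mesor"]], 26, 38)
      amp <- rtrunc_norm(1, gs$amplitude, bw[["amplitude"]], 0.1, 2.5)
      rrw <- rtrunc_norm(1, gs$rr_wake_ms, bw[["rr_wake"]], 550, 1200)
      rrd <- rnorm(1, gs$rr_sleep_ms - gs$rr_wake_ms, bw[["rr_diff"]])
      bed_shift <- round(rtrunc_norm(1, 0, bw[["bed_min"]], -110, 110))
      list(acro = acro, mes = mes, amp = amp, rrw = rrw, rrd = rrd,
           bed_shift = bed_shift,
           age = round(rtrunc_norm(1, gs$age_mean, gs$age_sd, 40, 65)),
           sex = if (runif(1) < gs$p_female) "F" else "M")
    })
    sex_v[i] <- si$sex
    age_v[i] <- si$age
    bed_h <- (clock_to_hours(gs$bed_time) + si$bed_shift / 60) %% 24
    sspec <- gs
    sspec$mesor <- si$mes; sspec$amplitude <- si$amp; sspec$acrophase <- si$acro
    sspec$rr_wake_ms <- si$rrw; sspec$rr_sleep_ms <- si$rrw + si$rrd
    sspec$bed_time <- sprintf("%02d:%02d", floor(bed_h), round((bed_h %% 1) * 60) %% 60)
    subjects[[i]] <- sspec
    sub_seeds <- derive_seeds(seeds[[i]], 4L)
    t0 <- parse_time(spec$start_date)
    diary_dates <- format(t0 + 86400 * (seq_len(max(1, spec$days - 1)) - 1), "%Y-%m-%d")
    series[[i]] <- list(
      temperature = gen_temperature(sspec, spec$days, sub_seeds[[1]],
                                    spec$start_date, ids[i]),
      activity = gen_activity(sspec, spec$days, sub_seeds[[2]],
                              spec$start_date, ids[i]),
      rr = gen_rr(sspec, spec$rr_hours, sub_seeds[[3]],
                  start_time = t0 + 86400, subject_id = ids[i]),
      diary = sleep_diary(diary_dates, sspec$bed_time, sspec$rise_time)
    )
    truth_rows[[i]] <- data.frame(
      id = ids[i], group = g, acrophase = si$acro, mesor = si$mes,
      amplitude = si$amp, rr_wake_ms = si$rrw,
      rr_sleep_ms = si$rrw + si$rrd, rr_diff_ms = si$rrd,
      bed_time = sspec$bed_time)
  }
  truth <- do.call(rbind, truth_rows)

  derived <- NULL
  if (analyze) derived <- analyze_cohort(series, cfg)

  cohort <- with_seed(seeds[[n + 1L]], {
    df <- data.frame(id = ids, group = groups, sex = sex_v, age = age_v,
                     stringsAsFactors = FALSE)
    score_names <- union(names(spec$cs$score_means), names(spec$oload$score_means))
    for (sc in score_names) df[[sc]] <- NA_real_
    for (g in c("CS", "O-LOAD")) {
      gs <- if (g == "CS") spec$cs else spec$oload
      gi <- which(df$group == g)
      for (sc in names(gs$score_means)) {
        mu <- gs$score_means[[sc]]
        sdv <- gs$score_sds[[sc]]
        if (!is.na(gs$inject_score) && sc == gs$inject_score && gs$inject_r != 0) {
          lh_col <- paste0(gs$inject_state, "_lh_ratio")
          lh <- derived[[lh_col]][match(df$id[gi], derived$id)]
          df[[sc]][gi] <- inject_correlated_score(lh, gs$inject_r, mu, sdv)
        } else {
          df[[sc]][gi] <- mu + sdv * rnorm(length(gi))
        }
      }
    }
    df
  })

  list(cohort = cohort_table(cohort), series = series,
       derived = derived,
       truth = list(subjects = truth,
                    injection = data.frame(
                      group = c("CS", "O-LOAD"),
                      r = c(spec$cs$inject_r, spec$oload$inject_r),
                      score = c(spec$cs$inject_score, spec$oload$inject_score),
                      state = c(spec$cs$inject_state, spec$oload$inject_state)),
                    seed = spec$seed))
}
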