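# one night of activity: bed 00:00, rise 08:00, 24 h of 1-min epochs
one_night <- function(counts, start = "2026-01-05 00:00:00") {
  tm <- as.POSIXct(start, tz = "UTC") + 60 * (seq_along(counts) - 1)
  activity_series("fx", tm, counts)
}

# diary date names the evening the night starts: the night scored here is
# 2026-01-05 00:00 -> 08:00, i.e. the night following Jan 4
night_diary <- sleep_diary("2026-01-04", "00:00", "08:00")

test_that("all-quiet in-bed epochs all score sleep with onset at bed time", {
  # quiet for 10 min past rise so the scoring window sees no morning activity
  ac <- one_night(c(rep(0, 8 * 60 + 10), rep(300, 16 * 60 - 10)))
  si <- score_epochs(ac, night_diary)
  expect_false(si$nights$flagged)
  expect_equal(si$nights$onset, night_diary$bed)
  sp <- sleep_params(si)
  expect_equal(sp$efficiency, 100)
  expect_equal(sp$duration_asleep, 480)
  expect_equal(sp$time_awake, 0)
})

test_that("uniformly high activity flags the night as no-sleep", {
  ac <- one_night(rep(400, 24 * 60))
  si <- score_epochs(ac, night_diary)
  expect_true(si$nights$flagged)
  expect_error(sleep_params(si), "no scorable night")
})

test_that("epoch scores match a straight-line implementation of the weighting", {
  set.seed(31)
  counts <- rpois(24 * 60, 30) * rbinom(24 * 60, 1, 0.4)
  cfg <- run_config(rescore = FALSE)
  si <- score_epochs(one_night(counts), night_diary, cfg)
  w <- cfg$ck_weights
  oracle <- numeric(length(counts))
  for (i in seq_along(counts)) {
    acc <- 0
    for (j in -4:2) {
      k <- i + j
      if (k >= 1 && k <= length(counts)) acc <- acc + w[j + 5] * counts[k]
    }
    oracle[i] <- acc
  }
  expect_equal(si$epochs$score, oracle, tolerance = 1e-12)
  expect_equal(si$epochs$state == "sleep",
               oracle < cfg$ck_threshold & si$epochs$time < night_diary$rise &
                 si$epochs$time >= night_diary$bed)
})

test_that("rescoring strips sleep minutes after sustained wake", {
  # 12 min of strong activity inside the night, then quiet
  counts <- c(rep(0, 120), rep(400, 12), rep(0, 24 * 60 - 132))
  raw <- score_epochs(one_night(counts), night_diary, run_config(rescore = FALSE))
  res <- score_epochs(one_night(counts), night_diary, run_config(rescore = TRUE))
  extra <- sum(raw$epochs$state == "sleep") - sum(res$epochs$state == "sleep")
  expect_equal(extra, 4)   # wake run >= 15 min strips 4 min of following sleep
})

test_that("sleep parameters are plain arithmetic on the scored labels", {
  # 24 isolated movement bursts, spaced widely: each wakes exactly 1 min
  counts <- rep(0, 24 * 60)
  burst_at <- seq(10, 470, by = 20)
  counts[burst_at] <- 100
  counts[8 * 60 + 2 + seq_len(16 * 60 - 62)] <- 300   # daytime awake
  si <- score_epochs(one_night(counts), night_diary, run_config(rescore = FALSE))
  sp <- sleep_params(si)
  expect_equal(sp$duration_asleep, 480 - length(burst_at))
  expect_equal(sp$time_awake, length(burst_at))
  expect_equal(sp$efficiency, 100 * (480 - 24) / 480)
  expect_equal(sp$efficiency, 95)
})

test_that("adding awake epochs inside the in-bed window never raises efficiency", {
  set.seed(33)
  counts <- c(rep(0, 8 * 60), rep(300, 16 * 60))
  base <- sleep_params(score_epochs(one_night(counts), night_diary))$efficiency
  for (k in c(5, 25, 60)) {
    c2 <- counts
    c2[sample(8 * 60, k)] <- 300
    e2 <- sleep_params(score_epochs(one_night(c2), night_diary))$efficiency
    expect_lte(e2, base)
  }
})

test_that("every epoch carries exactly one state label", {
  sp <- default_subject_spec("O-LOAD")
  sp$naps <- data.frame(start_h = 14, dur_min = 60)
  ac <- gen_activity(sp, days = 3, seed = 41)
  dr <- default_diary(sp, nights = 2)
  si <- score_epochs(ac, dr)
  expect_true(all(si$epochs$state %in% c("wake", "sleep", "nap")))
  expect_equal(nrow(si$epochs), nrow(ac))
  expect_gt(nrow(si$naps), 0)
  # naps sit outside every in-bed interval
  for (i in seq_len(nrow(si$naps)))
    expect_true(all(si$naps$start[i] >= si$nights$rise |
                      si$naps$end[i] <= si$nights$bed))
})

test_that("scored onset tracks the generated schedule within 15 min", {
  sp <- default_subject_spec("O-LOAD")
  ac <- gen_activity(sp, days = 7, seed = 43)
  si <- score_epochs(ac, default_diary(sp))
  sched_onset <- (clock_to_h(sp$bed_time) + sp$latency_min / 60) %% 24
  sp2 <- sleep_params(si)
  expect_lt(abs(clock_diff(sched_onset, sp2$start_time)), 0.25)
  expect_lt(abs(clock_diff(clock_to_h(sp$rise_time), sp2$end_time)), 0.25)
})

test_that("deterministic counts give near-perfect, identical nights", {
  # wake activity bleeds into the first in-bed minutes through the scoring
  # window, so efficiency saturates just below 100%
  sp <- default_subject_spec("CS")
  sp$activity_noise <- FALSE
  sp$latency_min <- 0
  ac <- gen_activity(sp, days = 7, seed = 1)
  si <- score_epochs(ac, default_diary(sp))
  sp2 <- sleep_params(si)
  expect_gt(sp2$efficiency, 98)
  expect_equal(sp2$n_nights, 6)
  expect_equal(sp2$n_flagged, 0)
  # scoring-window bleed (~3 min) plus rescoring (4 min) delay the scored onset
  expect_lt(abs(clock_diff(clock_to_h(sp$bed_time), sp2$start_time)), 10 / 60)
})

test_that("diary outside the recording is rejected", {
  ac <- one_night(rep(0, 24 * 60))
  bad <- sleep_diary("2026-01-09", "00:00", "08:00")
  expect_error(score_epochs(ac, bad), "outside")
  expect_error(sleep_diary("2026-01-05", "23:00", "22:00"), "16 h")
})
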