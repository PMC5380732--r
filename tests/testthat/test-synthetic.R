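test_that("noiseless temperature peaks at the programmed acrophase", {
  sp <- subject_spec(mesor = 33, amplitude = 1, acrophase = 3.8, temp_noise_sd = 0)
  ts <- gen_temperature(sp, days = 7)
  expect_equal(nrow(ts), 7 * 144)
  day1 <- ts[1:144, ]
  h <- (as.numeric(day1$time - day1$time[1]) / 3600) %% 24
  # sampled maximum sits at the grid point nearest the acrophase
  expect_lt(abs(h[which.max(day1$temp_c)] - 3.8), 1 / 6)
  expect_equal(max(ts$temp_c) - mean(ts$temp_c), 1, tolerance = 1e-3)
  expect_equal(max(ts$temp_c), 33 + cos(2 * pi * (23 / 6 - 3.8) / 24),
               tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  sp <- default_subject_spec("O-LOAD")
  expect_identical(gen_temperature(sp, 7, seed = 5), gen_temperature(sp, 7, seed = 5))
  expect_identical(gen_rr(sp, 1, seed = 5)$intervals, gen_rr(sp, 1, seed = 5)$intervals)
  expect_identical(gen_activity(sp, 2, seed = 5), gen_activity(sp, 2, seed = 5))
})

test_that("degenerate RR spec yields a constant series", {
  sp <- subject_spec(lf_depth_ms = 0, hf_depth_ms = 0, jitter_sd_ms = 0,
                     rr_wake_ms = 800, rr_sleep_ms = 800)
  s <- gen_rr(sp, hours = 0.2)
  expect_true(all(s$intervals == 800))
  # floating accumulation of 0.8 s can admit one extra closing beat
  expect_true(length(s$intervals) %in% c(900, 901))
})

test_that("state modulation and tones drive the expected downstream HRV", {
  # HF-dominant spec: downstream hf_nu above 0.9
  sp <- subject_spec(lf_depth_ms = 2, hf_depth_ms = 40, jitter_sd_ms = 0,
                     rr_wake_ms = 800, rr_sleep_ms = 800)
  s <- gen_rr(sp, hours = 0.2, seed = 2)
  m <- band_metrics(wavelet_spectrum(s, run_config()))
  expect_gt(m$hf_nu, 0.9)

  # sleep/wake mean split appears in the generated intervals
  sp2 <- subject_spec(rr_wake_ms = 795, rr_sleep_ms = 925, jitter_sd_ms = 0,
                      lf_depth_ms = 0, hf_depth_ms = 0,
                      bed_time = "00:00", rise_time = "08:00", latency_min = 0)
  s2 <- gen_rr(sp2, hours = 24, seed = 3)
  h <- (s2$beat_times / 3600) %% 24
  expect_equal(mean(s2$intervals[h < 8]) - mean(s2$intervals[h > 9]), 130,
               tolerance = 0.01)
})

test_that("impossible RR specs error out", {
  expect_error(subject_spec(lf_hz = 1.5), "frequencies")
  expect_error(subject_spec(lf_depth_ms = -1), "depths")
  expect_error(subject_spec(acrophase = 24), "acrophase")
  sp <- subject_spec(rr_wake_ms = 50, rr_sleep_ms = 50, lf_depth_ms = 40,
                     hf_depth_ms = 40, jitter_sd_ms = 0)
  expect_error(gen_rr(sp, hours = 0.01), "RR <= 0")
})

test_that("all-wake activity has no long zero-count runs", {
  sp <- subject_spec(bed_time = "03:00", rise_time = "03:01", latency_min = 0)
  ac <- gen_activity(sp, days = 2, seed = 29)
  z <- rle(ac$counts == 0)
  expect_lt(max(c(0, z$lengths[z$values])), 20)
})

test_that("overlapping nap and night windows are rejected", {
  sp <- subject_spec(bed_time = "23:00", rise_time = "07:00",
                     naps = data.frame(start_h = 6, dur_min = 120))
  expect_error(gen_activity(sp, 1, seed = 1), "overlap")
})

test_that("generated series satisfy the io validators by construction", {
  sp <- default_subject_spec("CS")
  expect_s3_class(gen_temperature(sp, 7, seed = 4), "temperature_series")
  expect_s3_class(gen_rr(sp, 1, seed = 4), "rr_series")
  expect_s3_class(gen_activity(sp, 2, seed = 4), "activity_series")
  # re-validate explicitly through the constructors
  s <- gen_rr(sp, 1, seed = 4)
  expect_silent(rr_series(s$subject_id, s$start_time, s$intervals))
})

test_that("a small cohort is reproducible and carries coherent ground truth", {
  ol_plain <- default_subject_spec("O-LOAD")
  ol_plain$inject_r <- 0   # no injection, so no pipeline run is needed
  cs <- cohort_spec(n_cs = 2, n_oload = 2, seed = 77, days = 3, rr_hours = 3,
                    oload = ol_plain)
  a <- gen_cohort(cs, analyze = FALSE)
  b <- gen_cohort(cs, analyze = FALSE)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$subjects, b$truth$subjects)
  expect_identical(a$series$S01$rr$intervals, b$series$S01$rr$intervals)
  expect_equal(nrow(a$cohort), 4)
  expect_equal(a$cohort$group, c("CS", "CS", "O-LOAD", "O-LOAD"))
  expect_true(all(c("acrophase", "rr_wake_ms", "rr_diff_ms") %in%
                    names(a$truth$subjects)))
})

test_that("injection ties the score to realized physiology at the target strength", {
  set.seed(55)
  reps <- replicate(200, {
    lh <- rnorm(23, 14, 4)
    cor(inject_correlated_score(lh, -0.744, 42.9, 7.24), lh)
  })
  expect_lt(abs(mean(reps) - (-0.744)), 0.05)
  expect_error(inject_correlated_score(rnorm(5), 1.2), "< 1")
})
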