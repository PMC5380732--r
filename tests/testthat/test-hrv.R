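test_that("time-domain measures match direct evaluation of their formulas", {
  expect_equal(time_domain(make_rr(c(800, 800, 800))),
               data.frame(rrm = 800, sdnn = 0, rmssd = 0))
  td <- time_domain(make_rr(c(800, 810, 790, 805)))
  expect_equal(td$rrm, 801.25)
  expect_equal(td$sdnn, sd(c(800, 810, 790, 805)))          # n-1 convention
  expect_equal(td$rmssd, sqrt(mean(c(10, -20, 15)^2)))      # approx 15.546
  expect_equal(td$rmssd, 15.5456, tolerance = 1e-4)
  expect_error(time_domain(make_rr(800)), "at least 2")
})

test_that("rrm and sdnn are order-invariant but rmssd is not", {
  set.seed(5)
  rr <- runif(100, 700, 900)
  per <- sample(rr)
  a <- time_domain(make_rr(rr))
  b <- time_domain(make_rr(per))
  expect_equal(a$rrm, b$rrm)
  expect_equal(a$sdnn, b$sdnn)
  expect_false(isTRUE(all.equal(a$rmssd, b$rmssd)))
})

test_that("clean_rr removes out-of-bound and jumping intervals and reports the fraction", {
  s <- make_rr(rep(800, 10))
  expect_equal(clean_rr(s)$intervals, s$intervals)
  expect_equal(attr(clean_rr(s), "removed_fraction"), 0)

  rr <- rep(800, 20)
  rr[10] <- 3000
  cl <- clean_rr(make_rr(rr))
  expect_equal(length(cl$intervals), 19)
  expect_equal(attr(cl, "removed_fraction"), 1 / 20)
  # beat time of surviving beats is preserved, not re-accumulated
  expect_equal(cl$beat_times, make_rr(rr)$beat_times[-10])

  rr2 <- rep(800, 10)
  rr2[4] <- 1000   # 25% jump
  expect_equal(length(clean_rr(make_rr(rr2))$intervals), 9)

  heavy <- make_rr(c(rep(800, 6), rep(3000, 4)))
  expect_false(attr(clean_rr(heavy), "usable"))
})

test_that("injected ectopic-like beats are caught by the filter", {
  sp <- default_subject_spec("CS")
  s <- gen_rr(sp, hours = 0.5, seed = 21, ectopic_rate = 0.05)
  ect <- attr(s, "ectopic_idx")
  expect_gt(length(ect), 20)
  cl <- clean_rr(s)
  surviving <- sum(s$beat_times[ect] %in% cl$beat_times)
  expect_lt(surviving / length(ect), 0.05)
})

test_that("dyadic band edges reproduce the nominal HRV bands at 2.4 Hz", {
  e <- band_edges(2.4, 6)
  expect_equal(e$high_hz[e$level == "D6"], 0.0375)  # VLF upper edge
  expect_equal(e$low_hz[e$level == "D6"], 0.01875)
  expect_equal(e$high_hz[e$level == "D4"], 0.15)    # LF upper edge
  expect_equal(e$low_hz[e$level == "D5"], 0.0375)   # LF lower edge
  expect_equal(e$high_hz[e$level == "D2"], 0.6)     # HF upper edge
  expect_equal(e$low_hz[e$level == "D3"], 0.15)     # HF lower edge
  expect_equal(e$band, c("TP-only", "HF", "HF", "LF", "LF", "VLF", "VLF"))
})

test_that("the DWT conserves energy exactly at every length", {
  set.seed(9)
  for (n in c(64, 256, 1024)) {
    x <- rnorm(n)
    d <- dwt_db4(x, 6)
    expect_equal(sum(vapply(d$details, function(z) sum(z^2), numeric(1))) +
                   sum(d$approx^2),
                 sum(x^2), tolerance = 1e-12)
  }
  expect_error(dwt_db4(rnorm(100), 6), "divisible")
})

test_that("level powers sum to the resampled-signal variance (Parseval)", {
  set.seed(13)
  cfg <- run_config()
  for (i in 1:20) {
    s <- make_rr(rnorm(300 + 50 * i %% 3, 800, 40))
    bd <- wavelet_spectrum(s, cfg)
    xr <- resample_tachogram(s, cfg$resample_hz)
    expect_equal(bd$tp, mean(xr^2), tolerance = 0.01)
    expect_equal(bd$tp, sum(bd$level_power))
    expect_gte(bd$tp, bd$vlf)
  }
})

test_that("band power scales quadratically and normalized units are scale-free", {
  set.seed(17)
  dev <- rnorm(400, 0, 25)
  s1 <- make_rr(800 + dev)
  # same beat times, doubled fluctuations: the whole chain is linear in the
  # tachogram values, so powers scale exactly by 4
  s2 <- rr_series("fx", T0, 800 + 2 * dev, beat_times = s1$beat_times)
  b1 <- wavelet_spectrum(s1, run_config())
  b2 <- wavelet_spectrum(s2, run_config())
  expect_equal(b2$tp / b1$tp, 4, tolerance = 1e-10)
  m1 <- band_metrics(b1)
  m2 <- band_metrics(b2)
  expect_equal(m1$lf_nu, m2$lf_nu, tolerance = 1e-10)
  expect_equal(m1$lh_ratio, m2$lh_ratio, tolerance = 1e-10)
})

test_that("band fractions agree with the FFT periodogram oracle for pure tones", {
  cfg <- run_config()
  for (f in c(0.10, 0.25)) {
    s <- make_tone_rr(f, minutes = 5)
    bd <- wavelet_spectrum(s, cfg)
    or <- fft_band_power(s)
    dwt_lf <- bd$lf / (bd$lf + bd$hf)
    fft_lf <- or[["lf"]] / (or[["lf"]] + or[["hf"]])
    expect_lt(abs(dwt_lf - fft_lf), 0.10)
    if (f < 0.15) expect_gt(dwt_lf, 0.9) else expect_gt(1 - dwt_lf, 0.9)
    # dominant band matches the tone's band
    dom <- c("vlf", "lf", "hf")[which.max(c(bd$vlf, bd$lf, bd$hf))]
    expect_equal(dom, if (f < 0.15) "lf" else "hf")
  }
})

test_that("spectral metrics obey their algebraic identities", {
  s <- make_tone_rr(0.12, minutes = 5)
  m <- band_metrics(wavelet_spectrum(s, run_config()))
  expect_identical(m$lf_nu + m$hf_nu, 1)
  expect_equal(m$ln_lf - m$ln_hf, log(m$lh_ratio), tolerance = 1e-12)
  fake <- structure(list(tp = 4, vlf = 1, lf = 1.5, hf = 1.5), class = "band_decomp")
  mm <- band_metrics(fake)
  expect_equal(mm$lf_nu, 0.5)
  expect_equal(mm$hf_nu, 0.5)
  expect_equal(mm$lh_ratio, 1)
  fake$hf <- 0
  expect_error(band_metrics(fake), "zero band power")
})

test_that("wavelet_spectrum rejects too-short or degenerate segments", {
  expect_error(wavelet_spectrum(make_rr(rep(800, 5)), run_config()), "2 min")
  expect_error(wavelet_spectrum(make_rr(rep(800, 100)), run_config()), "2 min")
  expect_error(wavelet_spectrum(make_rr(rep(800, 200)), run_config()), "all-zero")
})
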