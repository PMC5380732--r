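# fixtures built in code: tiny RR/temperature/activity builders and the
# independent FFT periodogram oracle used against the wavelet path

T0 <- "2026-01-06 00:00:00"

make_rr <- function(intervals, id = "fx", start = T0) {
  rr_series(id, start, intervals)
}

# pure-tone tachogram: RR(t) = base + depth*sin(2*pi*f*t), beat-advanced
make_tone_rr <- function(f, minutes = 5, depth = 40, base = 800, id = "tone") {
  t <- 0
  rr <- numeric(0)
  while (t < minutes * 60) {
    x <- base + depth * sin(2 * pi * f * t)
    rr <- c(rr, x)
    t <- t + x / 1000
  }
  rr_series(id, T0, rr)
}

# mirror of the package's preprocessing (detrend + spline resample),
# kept separate so the FFT oracle does not call the wavelet code path
resample_tachogram <- function(s, fs = 2.4) {
  t <- s$beat_times
  res <- stats::lm.fit(cbind(1, t), s$intervals)$residuals
  xr <- stats::spline(t, res, xout = seq(t[1], t[length(t)], by = 1 / fs))$y
  xr - mean(xr)
}

# FFT periodogram band fractions on the resampled signal
fft_band_power <- function(s, fs = 2.4) {
  xr <- resample_tachogram(s, fs)
  n <- length(xr)
  P <- Mod(stats::fft(xr))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  half <- fr <= fs / 2
  c(vlf = sum(P[half & fr > 0 & fr <= 0.0375]),
    lf = sum(P[half & fr > 0.0375 & fr <= 0.15]),
    hf = sum(P[half & fr > 0.15 & fr <= 0.6]))
}

# a week of diary rows matching the generators' default start date
default_diary <- function(spec, start_date = "2026-01-05", nights = 6) {
  dates <- format(as.POSIXct(start_date, tz = "UTC") + 86400 * (seq_len(nights) - 1),
                  "%Y-%m-%d")
  sleep_diary(dates, spec$bed_time, spec$rise_time)
}

clock_to_h <- function(hhmm) {
  p <- as.numeric(strsplit(hhmm, ":", fixed = TRUE)[[1]])
  p[1] + p[2] / 60
}

expect_roundtrip <- function(write_fun, read_fun, obj, ...) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_fun(obj, f)
  expect_equal(read_fun(f, ...), obj, ignore_attr = TRUE)
}
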