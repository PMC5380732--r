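#' Filter artifacts and ectopic beats from an RR series
#'
#' Removes intervals outside a physiological range or jumping more than
#' `max_rel_jump` (relative) from the previous accepted interval. Beat
#' times of accepted beats are preserved, so the tachogram keeps its true
#' time axis across the gaps.
#'
#' @param series an [rr_series()].
#' @param bounds acceptable RR range in ms.
#' @param max_rel_jump maximum relative jump between successive accepted
#'   intervals.
#' @param max_removed_frac removal fraction beyond which the segment is
#'   flagged unusable (attribute `usable = FALSE`).
#' @return the cleaned `rr_series`, with attributes `removed_fraction` and
#'   `usable`.
#' @export
clean_rr <- function(series, bounds = c(300, 2000), max_rel_jump = 0.2,
                     max_removed_frac = 0.2) {
  stopifnot(inherits(series, "rr_series"))
  rr <- series$intervals
  n <- length(rr)
  keep <- logical(n)
  prev <- NA_real_
  for (i in seq_len(n)) {
    ok <- rr[i] >= bounds[1] && rr[i] <= bounds[2] &&
      (is.na(prev) || abs(rr[i] - prev) <= max_rel_jump * prev)
    keep[i] <- ok
    if (ok) prev <- rr[i]
  }
  if (!any(keep)) stopf("RR cleaning removed every beat")
  out <- series
  out$intervals <- rr[keep]
  out$beat_times <- series$beat_times[keep]
  frac <- 1 - sum(keep) / n
  attr(out, "removed_fraction") <- frac
  attr(out, "usable") <- frac <= max_removed_frac
  out
}

#' Time-domain HRV measures
#'
#' @param segment an [rr_series()] (typically one 30-min fragment).
#' @return data frame row with `rrm` (mean RR, ms), `sdnn` (sample SD,
#'   ms) and `rmssd` (root mean square of successive differences, ms;
#'   `NA` with fewer than 3 intervals).
#' @export
time_domain <- function(segment) {
  rr <- segment$intervals
  if (length(rr) < 2) stopf("need at least 2 intervals")
  data.frame(rrm = mean(rr),
             sdnn = sd(rr),
             rmssd = if (length(rr) >= 3) sqrt(mean(diff(rr)^2)) else NA_real_)
}

#' Wavelet band decomposition of an RR segment
#'
#' The tachogram (beat time, RR interval) is detrended by removing its
#' least-squares line (which removes the mean), evenly resampled by cubic
#' spline interpolation at `cfg$resample_hz`, mean-centred, zero padded to
#' the next power of two and decomposed with a 6-level periodized
#' Daubechies-4 DWT. The power attributed to each level is that level's
#' contribution to the signal variance: the sum of its squared
#' coefficients divided by the un-padded sample count, so that the level
#' powers add up exactly to the variance of the resampled signal
#' (Parseval) and zero padding does not dilute power (the padding
#' contributes no energy).
#'
#' Band sums follow the dyadic mapping at 2.4 Hz: VLF = A6 + D6
#' (0--0.0375 Hz), LF = D4 + D5 (0.0375--0.15 Hz), HF = D2 + D3
#' (0.15--0.6 Hz); TP is the sum over all levels.
#'
#' @param segment an [rr_series()] covering at least 2 min of beats.
#' @param cfg a [run_config()].
#' @return object of class `band_decomp`: list with `level_power`, `tp`,
#'   `vlf`, `lf`, `hf`, `edges`, `fs`, `n_resampled`.
#' @export
wavelet_spectrum <- function(segment, cfg = run_config()) {
  stopifnot(inherits(segment, "rr_series"))
  t <- segment$beat_times
  rr <- segment$intervals
  if (length(rr) < 8 || diff(range(t)) < 120)
    stopf("segment shorter than 2 min of beats")
  # detrend: remove least-squares line (includes the mean)
  fit <- lm.fit(cbind(1, t), rr)
  res <- fit$residuals
  fs <- cfg$resample_hz
  xout <- seq(t[1], t[length(t)], by = 1 / fs)
  xr <- spline(t, res, xout = xout)$y
  xr <- xr - mean(xr)
  L <- length(xr)
  levels <- cfg$wavelet_levels
  if (L < 2^levels)
    stopf("segment shorter than one level-%d support", levels)
  npad <- 2^ceiling(log2(L))
  xp <- c(xr, numeric(npad - L))
  if (all(abs(xp) < 1e-9)) stopf("all-zero tachogram after detrending")
  dec <- dwt_db4(xp, levels)
  pow <- numeric(levels + 1)
  for (j in seq_len(levels)) pow[j] <- sum(dec$details[[j]]^2) / L
  pow[levels + 1] <- sum(dec$approx^2) / L
  names(pow) <- c(paste0("D", seq_len(levels)), paste0("A", levels))
  band <- band_of_level(names(pow), levels)
  structure(list(level_power = pow,
                 tp = sum(pow),
                 vlf = sum(pow[band == "VLF"]),
                 lf = sum(pow[band == "LF"]),
                 hf = sum(pow[band == "HF"]),
                 edges = band_edges(fs, levels),
                 fs = fs, n_resampled = L),
            class = "band_decomp")
}

#' @export
print.band_decomp <- function(x, ...) {
  cat(sprintf("<band_decomp> fs %g Hz, %d resampled samples\n", x$fs, x$n_resampled))
  cat(sprintf("  TP %.4g | VLF %.4g | LF %.4g | HF %.4g (ms^2 scale)\n",
              x$tp, x$vlf, x$lf, x$hf))
  invisible(x)
}

#' Frequency-domain HRV metrics from a band decomposition
#'
#' Logged band powers, normalized units and sympathovagal balance.
#' Normalized units are defined as each band's fraction of the combined
#' LF + HF power, so `lf_nu + hf_nu = 1` exactly.
#'
#' @param bands a `band_decomp` from [wavelet_spectrum()].
#' @return data frame row with `ln_tp`, `ln_vlf`, `ln_lf`, `ln_hf`,
#'   `lf_nu`, `hf_nu`, `lh_ratio`.
#' @export
band_metrics <- function(bands) {
  stopifnot(inherits(bands, "band_decomp"))
  if (bands$lf <= 0 || bands$hf <= 0 || bands$vlf <= 0 || bands$tp <= 0)
    stopf("zero band power: spectral metrics undefined")
  lf_nu <- bands$lf / (bands$lf + bands$hf)
  data.frame(ln_tp = log(bands$tp), ln_vlf = log(bands$vlf),
             ln_lf = log(bands$lf), ln_hf = log(bands$hf),
             lf_nu = lf_nu, hf_nu = 1 - lf_nu,
             lh_ratio = bands$lf / bands$hf)
}

#' All HRV measures for one RR fragment
#'
#' Convenience wrapper: cleaning, time domain and wavelet frequency
#' domain in one row. Returns `NULL` if the fragment is unusable (too few
#' beats or excessive artifact removal).
#'
#' @param segment an [rr_series()] fragment.
#' @param cfg a [run_config()].
#' @param clean apply [clean_rr()] first.
#' @return one-row data frame of [time_domain()] and [band_metrics()]
#'   fields, or `NULL`.
#' @export
hrv_metrics <- function(segment, cfg = run_config(), clean = TRUE) {
  seg <- segment
  if (clean) {
    seg <- tryCatch(clean_rr(seg, cfg$rr_bounds, cfg$max_rel_jump,
                             cfg$max_removed_frac),
                    error = function(e) NULL)
    if (is.null(seg) || !isTRUE(attr(seg, "usable"))) return(NULL)
  }
  if (length(seg$intervals) < 8 || diff(range(seg$beat_times)) < 120) return(NULL)
  td <- time_domain(seg)
  fd <- tryCatch(band_metrics(wavelet_spectrum(seg, cfg)),
                 error = function(e) NULL)
  if (is.null(fd)) return(NULL)
  cbind(td, fd)
}
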