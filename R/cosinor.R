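#' Cosinor fit of a 24-h rhythm
#'
#' Ordinary least squares on a partial Fourier basis with a 24-h
#' fundamental: `y ~ 1 + sum_k [cos(2*pi*k*t/24) + sin(2*pi*k*t/24)]`,
#' `k = 1..harmonics`, with `t` in clock hours. The MESOR is the
#' intercept; the fitted composite curve is evaluated over one period and
#' its maximum defines the amplitude (max minus MESOR) and acrophase (the
#' clock time of the maximum), so both remain meaningful when more than
#' one harmonic is used. Percent rhythm is the percentage of variance
#' explained by the full rhythmic model.
#'
#' @param series a [temperature_series()] (or any data frame with `time`
#'   and `temp_c`/`value` columns).
#' @param harmonics number of harmonics (1 = pure cosine).
#' @return object of class `cosinor_fit` with fields `mesor`, `amplitude`,
#'   `acrophase` (decimal clock hours in `[0,24)`, `NA` when the fitted
#'   rhythm is flat), `pct_rhythm`, `coefficients`, `residual_sd`, `n`.
#' @export
fit_cosinor <- function(series, harmonics = 1L) {
  harmonics <- as.integer(harmonics)
  if (harmonics < 1) stopf("harmonics must be >= 1")
  y <- if ("temp_c" %in% names(series)) series$temp_c else series$value
  t <- parse_time(series$time)
  n <- length(y)
  p <- 2L * harmonics + 1L
  if (n < 2L * p) stopf("need at least %d samples for %d harmonic(s)", 2L * p, harmonics)
  if (diff(range(as.numeric(t))) < 24 * 3600 - 1)
    stopf("need at least one full day of data")
  # hours since the midnight preceding the first sample: phases are clock-anchored
  th <- as.numeric(difftime(t, midnight_of(t[1]), units = "hours"))
  X <- cosinor_basis(th, harmonics)
  qrX <- qr(X)
  if (qrX$rank < p) stopf("rank-deficient cosinor design (degenerate sampling times)")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  ssr <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  pct <- if (sst > 0) 100 * (1 - ssr / sst) else 0
  curve_fun <- function(h) drop(cosinor_basis(h, harmonics) %*% beta)
  grid <- seq(0, 24, by = 1 / 60)[-(24 * 60 + 1)]
  cv <- curve_fun(grid)
  i <- which.max(cv)
  lo <- grid[i] - 1 / 60
  hi <- grid[i] + 1 / 60
  opt <- optimize(curve_fun, c(lo, hi), maximum = TRUE, tol = 1e-10)
  mesor <- unname(beta[1])
  amplitude <- opt$objective - mesor
  acro <- opt$maximum %% 24
  if (!is.finite(amplitude) || amplitude < 10 * .Machine$double.eps * max(1, abs(mesor))) {
    amplitude <- max(0, amplitude)
    acro <- NA_real_
  }
  structure(list(mesor = mesor, amplitude = amplitude, acrophase = acro,
                 pct_rhythm = min(100, max(0, pct)),
                 coefficients = beta, harmonics = harmonics,
                 residual_sd = sqrt(ssr / max(1, n - p)), n = n),
            class = "cosinor_fit")
}

cosinor_basis <- function(hours, harmonics) {
  X <- matrix(1, length(hours), 2L * harmonics + 1L)
  for (k in seq_len(harmonics)) {
    w <- 2 * pi * k * hours / 24
    X[, 2L * k] <- cos(w)
    X[, 2L * k + 1L] <- sin(w)
  }
  colnames(X) <- c("mesor",
                   as.vector(rbind(paste0("cos", seq_len(harmonics)),
                                   paste0("sin", seq_len(harmonics)))))
  X
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(paste0("<cosinor_fit> %d harmonic(s), n = %d\n",
                     "  MESOR %.3f | amplitude %.3f | acrophase %s h | %%rhythm %.1f\n"),
              x$harmonics, x$n, x$mesor, x$amplitude,
              ifelse(is.na(x$acrophase), "undefined", sprintf("%.3f", x$acrophase)),
              x$pct_rhythm))
  invisible(x)
}

#' @export
plot.cosinor_fit <- function(x, series = NULL, ...) {
  grid <- seq(0, 24, by = 1 / 60)
  cv <- drop(cosinor_basis(grid, x$harmonics) %*% x$coefficients)
  plot(grid, cv, type = "l", xlab = "clock hour", ylab = "fitted value",
       main = "Cosinor fit over one period", ...)
  abline(h = x$mesor, lty = 2)
  if (!is.na(x$acrophase)) abline(v = x$acrophase, lty = 3)
  invisible(x)
}

#' Signed circular acrophase difference
#'
#' Returns the phase delay of `b` relative to `a` in hours, mapped to
#' `(-12, +12]`.
#'
#' @param a,b `cosinor_fit` objects (or bare acrophases in clock hours).
#' @return hours; positive means `b` peaks later than `a`.
#' @export
phase_difference <- function(a, b) {
  ha <- if (inherits(a, "cosinor_fit")) a$acrophase else as.numeric(a)
  hb <- if (inherits(b, "cosinor_fit")) b$acrophase else as.numeric(b)
  if (is.na(ha) || is.na(hb)) stopf("undefined acrophase input")
  clock_diff(ha, hb)
}
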