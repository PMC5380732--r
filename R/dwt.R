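# Periodized orthonormal discrete wavelet transform with the Daubechies
# order-4 (db4, 8-tap, four vanishing moments) filter pair.
#
# Implemented here because the dyadic band decomposition is the core of
# the frequency-domain HRV method: a pyramid of circular filter-decimate
# steps with an orthonormal conjugate-quadrature pair, which conserves
# energy exactly (sum of squared coefficients across all levels equals
# the sum of squared input samples).

# db4 scaling (lowpass) filter; sums to sqrt(2), unit energy.
db4_h <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
           -0.0279837694168599, -0.1870348117190931, 0.0308413818355608,
           0.0328830116668852, -0.0105974017850690)
# conjugate-quadrature highpass: g[n] = (-1)^n h[L-1-n]
db4_g <- rev(db4_h) * c(1, -1, 1, -1, 1, -1, 1, -1)

# one circular analysis step: returns list(approx, detail), each length N/2
dwt_step <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)          # 0-based start per output coeff
  a <- numeric(half)
  d <- numeric(half)
  for (m in seq_along(db4_h)) {
    xi <- x[((idx0 + m - 1L) %% n) + 1L]
    a <- a + db4_h[m] * xi
    d <- d + db4_g[m] * xi
  }
  list(approx = a, detail = d)
}

#' Periodized Daubechies-4 discrete wavelet transform
#'
#' Multi-level pyramid decomposition with the orthonormal Daubechies
#' order-4 (8-tap) filter pair and circular (periodized) boundary
#' handling. The input length must be divisible by `2^levels`.
#'
#' @param x numeric signal.
#' @param levels number of decomposition levels.
#' @return list with `details` (list `D1`..`D<levels>`) and `approx`
#'   (the final approximation, `A<levels>`).
#' @export
dwt_db4 <- function(x, levels = 6L) {
  levels <- as.integer(levels)
  n <- length(x)
  if (n %% 2L^levels != 0L)
    stopf("signal length %d not divisible by 2^%d", n, levels)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a)
    details[[j]] <- st$detail
    a <- st$approx
  }
  names(details) <- paste0("D", seq_len(levels))
  list(details = details, approx = a)
}

#' Nominal dyadic band edges of the decomposition
#'
#' Detail level `Dk` nominally covers `fs/2^(k+1)` to `fs/2^k` Hz; the
#' final approximation covers 0 to `fs/2^(levels+1)` Hz. At the default
#' 2.4 Hz and 6 levels this reproduces the classical HRV band edges:
#' VLF upper edge 0.0375 Hz (D6), LF upper edge 0.15 Hz (D4) and HF upper
#' edge 0.6 Hz (D2).
#'
#' @param resample_hz even-sampling rate in Hz.
#' @param levels decomposition depth.
#' @return data frame with `level`, `low_hz`, `high_hz`, `band`.
#' @export
band_edges <- function(resample_hz = 2.4, levels = 6L) {
  k <- seq_len(levels)
  df <- data.frame(level = c(paste0("D", k), paste0("A", levels)),
                   low_hz = c(resample_hz / 2^(k + 1), 0),
                   high_hz = c(resample_hz / 2^k, resample_hz / 2^(levels + 1)))
  df$band <- band_of_level(df$level, levels)
  df
}

# band membership used for the 6-level HRV mapping:
# HF = D2+D3, LF = D4+D5, VLF = A+D6, D1 only enters total power
band_of_level <- function(level, levels = 6L) {
  out <- rep("TP-only", length(level))
  out[level %in% c("D2", "D3")] <- "HF"
  out[level %in% c("D4", "D5")] <- "LF"
  out[level %in% c("D6", paste0("A", levels))] <- "VLF"
  out
}
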