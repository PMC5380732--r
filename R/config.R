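#' Pipeline run configuration
#'
#' Bundles every tunable numeric choice of the pipeline in one validated
#' object, so that analyses are reproducible from a single record.
#'
#' @param epoch_length actigraphy epoch length in seconds.
#' @param fragment_min RR segmentation fragment length in minutes.
#' @param resample_hz even-sampling rate of the tachogram before the
#'   wavelet decomposition, in Hz. With the default 2.4 Hz and 6
#'   decomposition levels the dyadic band edges land on 0.0375 Hz (VLF/LF),
#'   0.15 Hz (LF/HF) and 0.6 Hz (upper HF).
#' @param wavelet_levels number of DWT decomposition levels.
#' @param harmonics number of Fourier harmonics in the cosinor fit
#'   (1 = pure 24-h cosine).
#' @param alpha two-sided significance level for the statistics layer.
#' @param rr_bounds plausible RR interval range in ms; beats outside are
#'   removed by [clean_rr()].
#' @param max_rel_jump maximum tolerated relative jump between successive
#'   accepted RR intervals (artifact/ectopy filter).
#' @param ck_weights Cole-Kripke 7-epoch weight vector (epochs -4..+2
#'   around the scored minute).
#' @param ck_threshold score threshold; weighted activity below it scores
#'   the epoch as sleep.
#' @param rescore apply Webster-style wake-after rescoring rules.
#' @param onset_run_min sleep onset/offset requires a run of at least this
#'   many consecutive sleep epochs inside the in-bed window.
#' @param nap_min minimum duration (minutes) of a daytime sleep bout to be
#'   labelled a nap.
#' @param state_overlap fraction of a fragment that must overlap a scored
#'   sleep (or nap) interval for the fragment to take that state.
#' @param max_removed_frac RR cleaning beyond this removal fraction flags
#'   the segment unusable.
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(epoch_length = 60,
                       fragment_min = 30,
                       resample_hz = 2.4,
                       wavelet_levels = 6L,
                       harmonics = 1L,
                       alpha = 0.05,
                       rr_bounds = c(300, 2000),
                       max_rel_jump = 0.2,
                       ck_weights = 1e-5 * c(404, 598, 326, 441, 1408, 508, 350),
                       ck_threshold = 1,
                       rescore = TRUE,
                       onset_run_min = 5L,
                       nap_min = 10L,
                       state_overlap = 0.5,
                       max_removed_frac = 0.2) {
  num_pos <- c(epoch_length = epoch_length, fragment_min = fragment_min,
               resample_hz = resample_hz, wavelet_levels = wavelet_levels,
               harmonics = harmonics, alpha = alpha,
               ck_threshold = ck_threshold, onset_run_min = onset_run_min,
               nap_min = nap_min, state_overlap = state_overlap,
               max_removed_frac = max_removed_frac)
  if (any(!is.finite(num_pos)) || any(num_pos <= 0))
    stopf("all configuration scalars must be positive and finite")
  if (length(rr_bounds) != 2 || rr_bounds[1] <= 0 || rr_bounds[2] <= rr_bounds[1])
    stopf("rr_bounds must be an increasing positive pair (ms)")
  if (max_rel_jump <= 0) stopf("max_rel_jump must be positive")
  if (length(ck_weights) != 7 || any(ck_weights < 0))
    stopf("ck_weights must be 7 non-negative weights")
  structure(list(
    epoch_length = epoch_length, fragment_min = fragment_min,
    resample_hz = resample_hz, wavelet_levels = as.integer(wavelet_levels),
    harmonics = as.integer(harmonics), alpha = alpha,
    rr_bounds = rr_bounds, max_rel_jump = max_rel_jump,
    ck_weights = ck_weights, ck_threshold = ck_threshold,
    rescore = isTRUE(rescore), onset_run_min = as.integer(onset_run_min),
    nap_min = as.integer(nap_min), state_overlap = state_overlap,
    max_removed_frac = max_removed_frac
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  fragments: %g min | resample: %g Hz | DWT levels: %d\n",
              x$fragment_min, x$resample_hz, x$wavelet_levels))
  cat(sprintf("  cosinor harmonics: %d | alpha: %g\n", x$harmonics, x$alpha))
  cat(sprintf("  RR bounds: %g-%g ms, max jump %g; CK threshold %g\n",
              x$rr_bounds[1], x$rr_bounds[2], x$max_rel_jump, x$ck_threshold))
  invisible(x)
}
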