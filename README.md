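# circadia

Chronobiological and autonomic analysis of week-long ambulatory
recordings, for studies that ask whether circadian physiology — the
sleep–wake cycle, the rhythm of distal skin temperature, and the
day–night modulation of cardiac autonomic control — differs between
groups (e.g. a healthy control group and an at-risk group) and tracks
cognitive performance.

The package implements the full chain:

* **Actigraphy sleep scoring.** Wrist activity counts in 1-min epochs are
  scored sleep/wake with the Cole–Kripke weighted window
  (score < 1 ⇒ sleep) plus Webster rescoring, inside diary-reported
  in-bed intervals; onset/offset, minutes asleep, time awake and
  efficiency (%) follow, averaged over nights with circular means for
  clock times.
* **Cosinor rhythmometry.** Least squares on a partial Fourier basis with
  a 24-h fundamental: `y(t) = M + Σₖ aₖcos(2πkt/24) + bₖsin(2πkt/24)`.
  MESOR `M`, amplitude (curve maximum − MESOR), acrophase (clock time of
  the maximum) and % rhythm (variance explained) are extracted from the
  composite fitted curve.
* **HRV by sleep/wake state.** RR intervals are cleaned, cut into 30-min
  fragments, and each fragment yields RRM/SDNN/RMSSD plus a
  wavelet-frequency decomposition: detrend, cubic-spline resample at
  2.4 Hz, zero-pad to a power of two, 6-level periodized Daubechies-4
  DWT. Levels map onto VLF = A6+D6 (0–0.0375 Hz), LF = D4+D5
  (0.0375–0.15 Hz), HF = D2+D3 (0.15–0.6 Hz); metrics are ln band powers,
  normalized units `lf_nu = LF/(LF+HF)` (so `lf_nu + hf_nu = 1` exactly)
  and the sympathovagal balance `L/H = LF/HF`. Fragments are assigned to
  wake/sleep by ≥50% overlap with the scored intervals (naps excluded
  from both averages) and summarised as wake, sleep, and sleep−wake
  difference.
* **Cohort statistics.** Pooled-variance t-tests (Welch by flag),
  chi-square for sex, and a Pearson correlation screen between state-wise
  HRV and cognitive scores with per-block Bonferroni flags (family size
  `m` recorded in every row).
* **Synthetic cohort with ground truth.** `gen_cohort()` simulates both
  groups — temperature cosine + noise, additive-modulation RR tachograms
  with LF/HF tones and a sleep/wake mean split, Poisson actigraphy, and
  cognitive scores optionally tied to each subject's *realized* sleep L/H
  at a target correlation — so every stage is validated by parameter
  recovery. The methods vignette
  (`vignettes/circadian-autonomic-pipeline.Rmd`) documents the model and
  every numerical choice.

## Worked example

One at-risk subject, simulated and pushed through the whole pipeline:

```r
library(circadia)

sp <- default_subject_spec("O-LOAD")   # group-mean physiology
rr <- gen_rr(sp, hours = 24, seed = 42, start_time = "2026-01-06 00:00:00")
ac <- gen_activity(sp, days = 7, seed = 43)
tm <- gen_temperature(sp, days = 7, seed = 44)
dr <- sleep_diary(format(as.POSIXct("2026-01-05", tz = "UTC") + 86400 * (0:5),
                         "%Y-%m-%d"), sp$bed_time, sp$rise_time)

res <- subject_pipeline(rr, ac, tm, dr)
res$cosinor
#> <cosinor_fit> 1 harmonic(s), n = 1008
#>   MESOR 32.153 | amplitude 0.951 | acrophase 3.793 h | %rhythm 83.5
round(res$sleep[, c("start_time", "end_time", "duration_asleep", "efficiency")], 2)
#>   start_time end_time duration_asleep efficiency
#> 1       0.13     7.91          458.17      94.47
round(res$summary[, c("rrm", "sdnn", "rmssd", "lf_nu", "hf_nu", "lh_ratio")], 3)
#>           rrm   sdnn  rmssd lf_nu  hf_nu lh_ratio
#> wake  794.009 25.715 28.975 0.194  0.806    0.241
#> sleep 924.266 27.822 32.230 0.198  0.802    0.248
#> diff  130.257  2.107  3.255 0.004 -0.004    0.007
```

The fit recovers the subject's generating rhythm (acrophase 3.79 h vs the
programmed 3.80 h); sleep is scored within minutes of the schedule; and the
sleep−wake RRM difference of +130 ms is the programmed slowing of the heart
during sleep. `lf_nu + hf_nu = 1` by construction, and HF dominance
(hf_nu ≈ 0.8) reflects the stronger programmed respiratory (HF) tone.

## The analysis workflow

`analysis/` holds numbered drivers that reproduce the full study-style
analysis on a simulated cohort (seed fixed in `01`), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + ground truth
Rscript analysis/02_sleep_actigraphy.R    # sleep parameters per subject
Rscript analysis/03_temperature_rhythm.R  # cosinor fits + group phase delay
Rscript analysis/04_hrv_circadian.R       # state-wise HRV summary
Rscript analysis/05_group_statistics.R    # comparisons + Bonferroni screen
```

On the default cohort this detects the programmed 1.24-h acrophase delay
(t-test on unwrapped phases, p ≈ 0.04 at n = 19 + 31) and the injected
negative correlation between sleep L/H and verbal memory survives the
per-block Bonferroni screen.

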