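---
title: "Circadian and autonomic analysis of ambulatory recordings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian and autonomic analysis of ambulatory recordings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadia)
```

`circadia` implements the analysis chain used to characterise circadian and
autonomic function in ambulatory cohort studies: wrist actigraphy is scored
into sleep and wake, distal skin temperature is summarised by a cosinor fit,
and a 24-h RR-interval recording is analysed in the time and
wavelet-frequency domains, segmented into 30-min fragments and averaged by
the actigraphy-defined behavioural state. A statistics layer compares the
two groups of a case--control design and screens correlations between
physiology and cognitive scores under Bonferroni control. Because raw
recordings of this kind are rarely shareable, the package ships a
synthetic-cohort generator with fully known ground truth; every analysis
stage is validated by parameter recovery against it.

## Time conventions

All timestamps are local clock time stored as POSIXct in UTC, so daylight
saving arithmetic can never shift a phase. Circadian quantities (acrophase,
sleep onset/offset) are decimal clock hours on a 24-h circle. Averages of
clock times use the circular (vector) mean; group comparisons of circular
quantities are run after unwrapping onto `reference + (-12, 12]` hours
(`unwrap_clock()`), so a phase cluster straddling midnight is not torn
apart.

## Actigraphy sleep scoring

Activity counts arrive in 1-min epochs. Each epoch receives the
Cole--Kripke weighted window score
$S_i = 10^{-5}(404\,A_{i-4} + 598\,A_{i-3} + 326\,A_{i-2} + 441\,A_{i-1} +
1408\,A_i + 508\,A_{i+1} + 350\,A_{i+2})$
and is scored *sleep* when $S_i < 1$. The weight vector and threshold sit in
`run_config()` because the commercial package that popularised this scoring
family does not publish its exact constants; the values above are the
canonical published ones. Webster-style rescoring (on by default) reclasses
the first 1/3/4 sleep minutes after a wake run of at least 4/10/15 min,
which counteracts the scoring window's tendency to call quiet wakefulness
sleep.

Within each diary in-bed interval, sleep onset is the start of the first
run of at least 5 consecutive sleep epochs and offset the end of the last
such run; both run lengths are configurable, as is the 10-min minimum for a
daytime sleep bout to count as a nap. Efficiency is minutes asleep divided
by the in-bed interval, in percent; "duration" is minutes *asleep*, not
time in bed (the two are sometimes conflated in published tables; we pick
the definition under which duration + time awake = time in bed holds
exactly). A consequence of the windowed score worth knowing: activity in
the minutes before bed bleeds into the first in-bed epochs, so even a
perfectly still sleeper scores a few wake minutes right after bed time and
efficiency saturates slightly below 100%.

## Temperature cosinor

`fit_cosinor()` is ordinary least squares on the partial Fourier basis
$\{1, \cos(2\pi k t/24), \sin(2\pi k t/24)\}_{k=1..H}$ with $t$ in clock
hours. The default is $H = 1$ (a pure 24-h cosine) with $H$ up to 3
available; since the fitted curve for $H > 1$ is no longer a cosine, the
amplitude and acrophase are always defined from the composite fitted curve:
the curve is evaluated on a 1-min grid over one period, the maximum is
refined by golden-section search to ~1e-10 h, amplitude = maximum −
MESOR and acrophase = the clock time of the maximum. Percent rhythm is the
total model $R^2 \times 100$ (the harmonic-subset alternative differs only
for $H > 1$; we use the total because it is what "variance explained by the
fitted model" means operationally). A fitted amplitude below
$10\,\varepsilon\,|\mathrm{MESOR}|$ leaves the acrophase undefined (`NA`)
rather than noise-determined. Distal skin temperature peaks during sleep,
roughly in antiphase to core temperature; acrophases here are reported as
measured, with no 12-h correction.

## HRV: cleaning, time domain, wavelet frequency domain

`clean_rr()` removes intervals outside 300--2000 ms or jumping more than
20% from the previous accepted interval (both configurable); beat times of
surviving beats are preserved so the tachogram keeps its true time axis
across gaps. Segments losing more than 20% of beats are flagged unusable
and dropped from state averages. Time-domain measures are the mean RR
(RRM), the sample standard deviation (SDNN) and the root mean square of
successive differences (RMSSD).

The frequency domain follows the wavelet recipe: the tachogram is
detrended (least-squares line, which removes the mean), evenly resampled
at 2.4 Hz by cubic spline, mean-centred, zero-padded to the next power of
two and decomposed by a 6-level discrete wavelet transform with the
orthonormal Daubechies order-4 filter pair (8 taps, four vanishing
moments) under periodized boundary handling. "Daubechies four" is
ambiguous between this filter and the 4-tap two-vanishing-moment one; we
use the order-4 filter because its roll-off is what the band mapping
needs — with the 4-tap filter roughly 15% of a mid-LF tone's energy leaks
across the LF/HF boundary, which would make the nominal band labels
misleading.

At 2.4 Hz the dyadic levels map onto the classical HRV bands: detail
level $D_k$ spans $2.4/2^{k+1}$ to $2.4/2^k$ Hz, so VLF = A6 + D6
(0--0.0375 Hz), LF = D4 + D5 (0.0375--0.15 Hz) and HF = D2 + D3
(0.15--0.6 Hz). Total power is the sum over *all* levels (D1 and the
0.6--1.2 Hz range included; a "0--0.5 Hz" label sometimes attached to TP is
not representable on the dyadic grid, and the nominal edges are carried as
metadata instead).

The power assigned to each level is the sum of its squared coefficients
divided by the un-padded sample count — i.e. the level's contribution to
the variance of the resampled signal. Two alternatives were considered and
rejected. The raw variance of the coefficients at each level is *not*
additive: for an orthonormal transform of white noise every level's
coefficient variance equals the signal variance, so the seven level
variances would sum to seven times it. Restricting the sum to the
un-padded coefficient support breaks exactness the other way, discarding
boundary-wrap energy (errors up to a few percent). With the convention
used here, Parseval holds exactly: level powers sum to the resampled
signal's variance, zero padding contributes nothing, and all derived
ratios are invariant to any common rescaling of the convention.

Normalized units are defined as fractions of the combined LF + HF power,
`lf_nu = LF/(LF+HF)` and `hf_nu = 1 - lf_nu`, so they are exactly
complementary; the sympathovagal balance is `L/H = LF/HF`. A printed
formula of the form "LF/(TP − VLF)/100" appears in parts of the applied
literature, but it is algebraically incompatible with complementary nu
pairs (TP − VLF additionally contains D1), so the LF+HF denominator is
used. Zero band power is an error, not `-Inf`: a segment whose spectrum
vanishes is unusable, and silent `-Inf`s would poison downstream state
averages.

## Circadian segmentation

The RR recording is cut into consecutive half-open 30-min fragments from
the recording start; a beat exactly on a boundary belongs to the next
fragment and the trailing partial fragment is dropped. A fragment is
*sleep* if at least 50% of its span lies within a scored nocturnal sleep
interval (onset to offset), *nap* if at least 50% lies within a scored nap,
and *wake* otherwise. Nap fragments are excluded from the wake average by
definition and from the sleep average as an interpretive choice — "sleep"
then means nocturnal sleep, which keeps the sleep--wake difference a
day--night contrast. State summaries are unweighted means over fragments,
and the difference record is sleep minus wake for every field (positive
RRM difference = longer beats, slower heart rate asleep). The L/H ratio is
averaged across fragments, *not* recomputed from averaged powers; the two
disagree by Jensen's inequality and the per-fragment convention is the one
under which a table of state means is self-consistent.

## Statistics layer

Continuous variables are compared with a two-sample t-test, pooled
variance by default (Welch by flag); sex composition with a chi-square
test without continuity correction (correction by flag). The correlation
screen computes two-sided Pearson correlations on pairwise-complete
observations; cells with fewer than 4 complete pairs return `NA`. The
Bonferroni family size `m` defaults to the number of tests actually
performed in the call — one state block at a time in `build_tables()` —
and is recorded in every output row, with a `table`-wide family available.
The family choice is genuinely underdetermined in most published reports;
recording `m` per row keeps whichever choice auditable.

## The synthetic cohort

The generator's defaults are the emulated study's conditions: 19 CS and
31 O-LOAD subjects; temperature rhythms with group means MESOR
33.03/32.16 °C, amplitude 0.99/0.96 °C, acrophase 2.56/3.80 h (a 1.24-h
programmed delay) and Gaussian sample noise of 0.3 °C; wake/sleep mean RR
of 778.5/902.9 ms (CS) and 794.7/926.3 ms (O-LOAD); bed times around
00:33/23:50 with rise at 07:55. Between-subject spreads are the printed
group SEs scaled by $\sqrt{n}$ of the corresponding measurement block;
wake RR and the sleep−wake difference are drawn as (wake, difference)
pairs so the two state means stay correlated within subject the way the
printed difference SEs imply. One printed dispersion is not taken at face
value: an SE of 1.15 °C for the at-risk MESOR would imply a ±6 °C
between-subject spread of mean skin temperature, which collides with the
physiological plausibility window; both groups use the control-derived
0.54 °C spread instead.

RR series are generated by additive tachogram modulation: instantaneous
RR = state mean + LF tone + HF tone + white jitter, each beat advancing
time by its own interval. This was chosen over an integral-pulse-frequency
heart model because the pipeline only ever sees RR intervals and the
additive model's band powers are analytically known (a tone of depth $d$
contributes $d^2/2$). Tone defaults (LF 0.10 Hz at 15 ms, HF 0.25 Hz at
30 ms, jitter 10 ms) put the HF fraction near the emulated cohort's
printed normalized units. Within-subject HRV variability has no published
value to anchor on; the jitter and depth defaults are free parameters and
documented as such. Activity counts are Poisson (mean 200 awake) with
isolated movement bursts during sleep whose size (mean 120) and rate
(0.015/min) were chosen once so that Cole--Kripke scoring of the default
trace lands in the ~95% efficiency regime typical of healthy cohorts.
Cognitive scores are Gaussian with the emulated group means and SDs.

When a correlation between physiology and a score is requested
(`inject_r`, default −0.744 between sleep L/H and RAVLT in O-LOAD), the
score is built from the subject's *realized, post-pipeline* L/H by
`score = mean + sd(r z + sqrt(1-r^2) eps)` with `z` the standardized
realized values — so recovering the association exercises the entire
chain, not just the random number generator. This is why `gen_cohort()`
runs the analysis pipeline internally.

What the generator does not emulate: masking of the temperature rhythm by
behaviour and environment (real distal-temperature fits explain ~25% of
variance, not the ~80% seen here at 0.3 °C white noise), respiratory
sinus arrhythmia coupled to real breathing, ectopy and artifact beyond
the optional uniform ectopic corruption, off-wrist intervals, and any
non-sinusoidal rhythm waveform. Passing recovery tests therefore
demonstrates correctness of the computations, not robustness to every
failure mode of field recordings.

## Problem sizes and numerical choices

The validation suite uses the study-scale conditions throughout: 7-day
temperature and actigraphy records, 24-h RR recordings (~100k beats),
48 fragments per subject, and a 50-subject cohort for the end-to-end
recovery run; simulation-calibration checks use 200--2000 replicates
(Parseval, test size, family-wise error, correlation recovery) and 500
seeds for noisy-acrophase recovery. Degenerate inputs are errors, not
warnings: constant tachograms, zero band powers, rank-deficient cosinor
designs, diaries outside the recording, implausible (>16 h) in-bed
intervals, and RR modulation that drives the instantaneous interval below
1 ms (where the beat-advancing generator would otherwise stall). Ties in
the cosinor grid maximum are resolved by the first grid maximum before
local refinement; the 12-h reflection ambiguity of a cosine fit is
resolved by constraining the amplitude to be non-negative.

## Known limitations

The Cole--Kripke constants stand in for an unpublished commercial scoring
algorithm; scored onset can trail a diary bed time by several minutes by
construction (window bleed plus rescoring). The wavelet band edges are
nominal dyadic labels — a db4 level is not a brick-wall filter, and a few
percent of a tone's energy appears in adjacent levels. Group comparisons
of acrophase assume the unwrapped phases are approximately normal;
heavily multimodal phase distributions would need circular statistics
proper. The statistics layer implements the classical screen
(t / chi-square / Pearson + Bonferroni) deliberately, to mirror the
analysis style it reproduces; nothing here is a substitute for a
pre-registered model when one is available.
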