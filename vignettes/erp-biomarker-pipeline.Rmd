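---
title: "ERP biomarkers of antidepressant outcome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ERP biomarkers of antidepressant outcome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpmark)
```

## The analysis

`erpmark` implements a cohort analysis relating three acute EEG/ERP
markers to antidepressant treatment outcome in major depressive
disorder. Per subject the pipeline produces a biomarker vector — frontal
alpha asymmetry (FAA) for F5/F6 and F7/F8, the LDAEP slope, and the MMN
composite amplitude — and the cohort statistics then relate each marker,
median-split into low/high groups, to the HAM-D course over weeks
0/2/4/8.

The statistical model for the trajectory analysis is a split-plot
(repeated-measures) ANCOVA: week is the within-subject factor with four
levels, biomarker group the between factor, and age, sex (0/1), baseline
HAM-D and medication type (0/1) enter as between-subject covariates. The
univariate week-by-group interaction F is computed from orthonormalized
within-subject contrast scores: with `Y` the n-by-4 score matrix and `C`
a 4-by-3 orthonormal contrast basis, the model `Y C = X B + E` is fitted
by least squares and

    F = [tr(H) / (k-1)] / [tr(E) / ((k-1) df_e)],

with `H` the hypothesis SSCP of the group row. This "univariate
approach" assumes sphericity of the contrast covariance; Mauchly's W
tests that assumption on the error covariance of the same fit, and when
it rejects (p < 0.05, the declared convention) the degrees of freedom
are multiplied by the Greenhouse–Geisser epsilon

    eps = (sum lambda)^2 / ((k-1) sum lambda^2),

from the eigenvalues of the contrast error covariance, so that
`df1 = eps (k-1)` and `df2 = eps (k-1)(n - g - c)`. The test suite
verifies F, W, eps and the corrected p against `car::Anova` as an
independent implementation. Note that with n = 52, two groups and four
covariates the unadjusted error df is 3 × 46 = 138, so an epsilon of
0.8533 yields the df pair (2.560, 117.76).

Remission is a week-8 HAM-D total of 7 or less; response is a drop of at
least 50% from baseline. Both boundaries are inclusive. Group-by-outcome
tables use the uncorrected Pearson chi-square: the package deliberately
applies no Yates continuity correction, because the printed statistics
this analysis is checked against (5.20 and 3.90 on the reconstructed
remission/response tables) are the uncorrected values — this
reconstruction is itself an acceptance test. Partial correlations are
residual correlations: both variables are regressed on the covariate set
and the residuals correlated, with df = n − 2 − q and a two-sided t
test. All p-values in the package are two-sided; no multiple-testing
correction is applied across the four indices, mirroring the analysis
design (the report notes this).

Two deliberate echoes of the original design are worth flagging.
Baseline HAM-D serves both as the first repeated-measures level and as a
covariate; this double use is implemented as described because the
published df algebra is only consistent with it (`rm_ancova()` takes an
arbitrary covariate frame, so a sensitivity analysis without the double
use is one argument away). And values exactly at the median go to the
*low* group — a deterministic tie rule; the analysis this mirrors
reports exact 26/26 splits, implying no material ties.

## Signal processing

- **Filtering.** Zero-phase Butterworth filtering via forward-backward
  application (`signal::filtfilt`): a 2nd-order high-pass at the low
  edge (0.1 Hz sits so close to DC that higher-order recursive
  high-passes become numerically fragile) cascaded with a 4th-order
  low-pass. The forward-backward pass squares the magnitude response,
  giving better than 90% amplitude rejection of 50 Hz line-adjacent
  activity for the 0.1–30 Hz ERP band. The 60 Hz notch is a biquad with
  quality factor 30 (−3 dB width 2 Hz), also applied zero-phase.
  Channels are demeaned before filtering.
- **Epoching.** All sample windows are half-open `[start, end)`: 2.048 s
  at 1000 Hz is exactly 2048 samples, and an event at sample s with a
  100 ms/600 ms window covers samples s−100 … s+599. Resting analysis
  takes the first 30 clean consecutive epochs in temporal order (a
  deterministic selection rule). Event epochs are baseline-corrected by
  subtracting the channelwise pre-stimulus mean.
- **Artifact rejection.** Resting epochs are dropped when any scored
  channel exceeds 100 µV in absolute value; event epochs when exceeding
  ±75 µV *after* baseline correction (the threshold is about residual
  signal; the order is a declared convention). The threshold is
  interpreted as absolute amplitude, not peak-to-peak — the stricter
  and more common reading; both thresholds and the scored-channel list
  are arguments, so the peak-to-peak sensitivity analysis is available
  to the user.
- **Band power.** Per-epoch Hann-tapered periodograms, one-sided powers
  summed over FFT bins whose center frequency lies in [8, 10) Hz
  (bin-center inclusion, half-open band edges — fixed so results are
  bit-reproducible), averaged over the 30 epochs. The scaling makes the
  one-sided total equal the signal variance; a sinusoid of amplitude a
  contributes a²/2 to its band, which the tests verify against a
  time-domain variance oracle. No log transform is applied anywhere —
  the asymmetry index is computed from raw absolute powers, and the
  index (a ratio) is invariant to any common rescaling.
- **Peaks.** N1 is the in-window minimum, P2 the in-window maximum;
  windows are closed intervals in ms, they intentionally overlap in
  150–200 ms, and latency ties resolve to the earliest sample. The
  LDAEP regression uses intensity/10 as the regressor so the slope is
  natively in µV per 10 dB.
- **MMN.** The 130–280 ms window is fixed, never re-selected from the
  data, and the composite is the unweighted mean of the nine
  frontocentral site amplitudes (the aggregation was not further
  specified in the source analysis; the unweighted mean is the declared
  convention here).

## The synthetic-data model

The generators exist to make every extractor identifiable, not to be
physiologically realistic; they use the simplest signal model with that
property: pink (1/f amplitude) background noise plus deterministic
event-locked components.

- **Resting EEG**: per-channel pink noise (default sd 2 µV) plus a
  sinusoidal alpha oscillation (default 9 Hz, 5 µV² baseline band
  power). For each asymmetry pair the left/right powers are set to
  `P0 · sqrt(rho)` and `P0 / sqrt(rho)` with
  `rho = (100 + A)/(100 − A)`, so the injected index is exact for the
  noiseless oscillation; broadband noise adds equal expected power to
  both channels of a pair and therefore attenuates the observed index
  slightly toward zero, which the ±5-unit recovery tolerance absorbs.
- **LDAEP**: tones in randomized order, ISI uniform on 500–900 ms; each
  tone evokes a negative Gaussian (100 ms, sd 20 ms) and a positive
  Gaussian (200 ms, sd 30 ms) at Cz scaled across the scalp by a fixed
  topography, with N1/P2 peak-to-peak amplitude
  `n1_base + p2_base + slope · (I − 80)/10` (defaults 2.5 + 3.5 µV at
  the 80 dB reference). The tiny residual overlap of the two Gaussians
  makes the noiseless round trip accurate to ~0.5% rather than machine
  precision; the exactness of the slope *fit* itself is tested
  separately on crafted amplitudes.
- **MMN**: 750 stimuli, 10% deviants, fixed 500 ms ISI. Conflicting
  ISI statements exist for this paradigm in the source description
  (500 ms in one sentence, 1500 ms in another); the generator makes the
  ISI configurable and defaults to 500 ms rather than silently picking
  between them. Deviants carry an extra negative Gaussian (205 ms, sd
  40 ms) at the nine sites, scaled so its mean over 130–280 ms equals
  the target amplitude exactly.
- **Clinical cohorts**: true biomarker values are drawn from the
  published cohort moments (FAA F5/F6 0.03 ± 14.13; F7/F8
  −1.73 ± 15.81; LDAEP 1.55 ± 2.85 µV/10 dB; MMN −2.97 ± 1.34 µV;
  HAM-D baseline 26.13 ± 6.80; CORE 4.35 ± 5.98; age 45.87 ± 11.69;
  48/52 female). HAM-D scores are rounded, zero-truncated Gaussians
  around a geometric decline `hamd0 · f^(w/8)`, where the week-8
  remaining fraction f is lognormal with per-group medians 0.17 (low
  FAA) / 0.29 (high FAA) and log-sds 0.55/0.80. The lognormal was
  chosen because end-of-trial severity distributions are right-skewed:
  these settings put the simulated week-8 group means, their spread,
  and the remission/response proportions in the vicinity of the
  published cohort (roughly 5 and 10 points, with ~60% remission
  overall). Setting both groups' parameters equal produces exact null
  cohorts for calibration. CORE is a rounded Gaussian censored at 0
  whose latent correlation with true F7/F8 FAA is configurable
  (default 0.34); the censoring attenuates the realized correlation by
  a percent or two, which recovery tests allow for.

What the generator does *not* emulate: volume conduction and channel
covariance (channels are independent except for the shared evoked
components), ocular/muscle artifacts (rejection is exercised with
synthetic high-amplitude segments in tests instead), non-stationary
alpha dynamics, integer-valued rating-scale item structure, or
dropout. Passing recovery tests therefore demonstrate correctness of
the *extraction and statistics*, not robustness to real-world artifact
structure.

## Numerical conventions and degenerate inputs

- Determinism: every generator output is a pure function of
  `sim_config()` including its seed; per-subject, per-paradigm
  sub-seeds are derived arithmetically so subjects are independent but
  reproducible.
- The asymmetry index errors on `P_left + P_right = 0` (undefined), the
  median split errors when all values are identical, the chi-square
  errors on zero margins (the pipeline reports NA for that index
  instead of aborting the cohort when everyone remits), response is
  undefined at baseline 0, and the within-subject covariance must be
  nonsingular for Mauchly's test.
- Constant covariates (e.g. an all-female cohort) are aliased with the
  intercept and dropped; reported dfs reflect the retained set.
- Greenhouse–Geisser correction is applied only when Mauchly's p <
  0.05; epsilon is bounded in (1/(k−1), 1], so for four weeks df1 never
  drops below 1.

## Problem sizes used by the test suite

Unit tests run on reduced recordings (70 s resting, 8 trials per
intensity, 150 oddball stimuli). The recovery suite uses 20 replicates
per injected value at the default noise level and full trial counts;
the calibration suite uses 200 null cohorts of n = 52; the acceptance
script uses 8 replicates per injected value. These sizes were chosen so
the complete suite exercises every paradigm at full fidelity while
remaining comfortably runnable on a laptop.

## Known limitations

- The EDF writer quantizes to 16 bits (as the format requires);
  lossless round trips use the JSON + binary container instead.
- The ocular-artifact regression of the original commercial
  preprocessing stack is not reproducible from its description and is
  deliberately out of scope; amplitude-threshold rejection stands in
  for it.
- High-alpha (10–12 Hz) and broadband-alpha asymmetry variants are not
  computed in the analysis path (the source analysis restricted itself
  to the low band); `band_power()` accepts arbitrary bands for
  exploration.
- Subject-level published results (the cohort's r = 0.34, F = 3.84,
  week-8 group means) depend on unavailable patient data; the package
  treats them as realistic simulation settings, and its tests check
  parameter recovery and statistical calibration, not reproduction of
  those cohort-specific numbers.
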