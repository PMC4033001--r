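---
title: "From force trace to outcome statistics: methods behind tapsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force trace to outcome statistics: methods behind tapsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsync)
```

`tapsync` turns raw force-sensitive-resistor recordings of finger tapping
into clinical outcome statistics for two-group rehabilitation studies. This
vignette documents the measurement model, the conventions and defaults, the
numerical choices, and what the synthetic-data generator does and does not
establish about real recordings.

## The measurement chain

### Preprocessing

A recording is a force time series sampled nominally at 3 kHz. Preprocessing
is fixed as **trim, then calibrate, then smooth**:

1. `trim_edges()` discards the first and last 0.5 s, where the experimenter's
   handling of the device contaminates the signal. The trimmed trace keeps a
   `start_sample` offset so all landmark times stay in original-recording
   coordinates.
2. `calibrate()` maps raw ADC readings to Newtons by piecewise-linear
   interpolation over a device-specific calibration table, clamping readings
   outside the table's range to its end forces. Calibration is monotone and
   applied exactly once (the `units` field enforces raw → newton).
3. `smooth_bartlett()` convolves with a unit-sum triangular window, 160
   samples (≈ 53 ms at 3 kHz) by default. The kernel is centered and edges
   are handled by reflection, so constants are fixed points, the integral of
   interior pulses is conserved, and landmarks are not systematically
   shifted by the filter's phase. Trimming before smoothing keeps the edge
   transients out of the convolution entirely.

The window length matters because it sets a resolution floor: any feature of
the force profile shorter than ~53 ms is attenuated, and the supra-threshold
span of a pulse is widened by up to half a window on each side. This has two
visible consequences that users should expect: measured dwell times exceed
the physical contact time by a few tens of ms, and the onset landmark leads
or lags the physical contact by a constant that depends only on the pulse
shape. Because that latency is constant within a recording and across
sessions of the same patient, it cancels from within-subject contrasts
(PRE/POST changes, session effects) and from the resultant length R, which
is invariant under rotation of all phases. It does not cancel from the
absolute mean asynchrony, which is therefore reported but not interpreted at
better than window resolution.

### Tap landmarking

`detect_taps()` scans the smoothed trace forward:

* **onset**: first sample with force strictly above the threshold
  (default 0.05 N) once at least 75 ms have elapsed since the previous
  offset;
* **offset**: first sample with force strictly below threshold at least
  40 ms after that onset. Brief dips inside the 40-ms window do not
  terminate the tap — the offset lands on the *final* sub-threshold
  crossing, which is what the refractory rule is for;
* a trailing onset with no qualifying offset before the end of the trace is
  discarded.

Conventions fixed here: threshold crossing is strict (`>` on the way up,
`<` on the way down; a sample exactly at threshold fires nothing); the
landmark is the first supra-threshold *sample*, not an interpolated
sub-sample crossing (at 3 kHz the difference is below 0.34 ms); no slope
criterion is applied beyond the threshold rule; and the same threshold is
used for onset and offset (no hysteresis). Recordings where the patient
tapped too softly get an explicit per-recording `threshold_override_n`
carried into the output attributes with a free-text reason — an auditable
replacement for interactive threshold adjustment.

Raising the threshold can only remove candidate crossings, so the number of
detected taps is non-increasing in the threshold (property-tested).

### Interval metrics

Inter-tap intervals are onset-to-onset differences. `filter_itis()` flags —
rather than deletes — intervals outside **[120, 2000] ms**: shorter ones are
overwhelmingly double-tap recording artifacts, longer ones are pauses
(patients asking questions, repositioning) rather than motor capacity. The
bounds are inclusive because the excluded regions are described as strictly
beyond them ("larger than", "shorter than"). Blocks recorded around the same
session are pooled by concatenating their kept intervals
(`pool_session_blocks()`); no interval ever spans a block boundary.

* **Speed** = sample median of kept intervals (ms). The median is robust to
  the residual right tail that survives filtering.
* **Variability** = coefficient of variation in percent after a single
  (non-iterated) 3-SD trim: compute mean and sample SD, drop intervals more
  than 3 SD from the mean, then CV = 100 · SD/mean of the remainder. The SD
  is the sample SD (n − 1), the clinical-statistics convention. The
  denominator uses the post-trim mean so numerator and denominator describe
  the same set; `denominator = "pre_trim"` switches to the other reading of
  an ambiguous convention.

A methods fact worth knowing when interpreting CVs: for well-behaved
(approximately log-normal) interval data the 3-SD trim removes ~0.3% of the
mass in the tails and thereby shrinks the measured CV by about 2% of its
value (e.g. a generating CV of 10% is measured as ≈ 9.8%). This is a
property of the estimator, not a pipeline defect; comparisons between
sessions or groups use the same estimator and are unaffected.

### Metronome synchronization

For paced tapping at 69 BPM the click cycle is T = 60000/69 ≈ 869.57 ms.
Each onset within the analysis window (60 s from the first tap, matching
the task protocol) is referred to its **nearest** click:
φ = 2π(t − t_click)/T ∈ (−π, π], a tie at exactly half a cycle mapping to
+π. Nearest-click referencing is symmetric and presumes nothing about
whether taps lead or lag the beat. Summaries are the mean resultant length
R, the circular mean phase, the angular SD √(−2 ln R), and the Rayleigh
test p from Z = nR² with the standard series approximation. R is the
synchronization outcome fed to group-level analysis (higher = more tightly
locked); the angular SD is exported as an equivalent alternative — which
transform of the circular summary enters the ANOVA is a genuinely open
convention, so the package exposes both.

### Clinical scores

* 9HPT improvement = POST − PRE completion time in seconds; negative means
  faster after therapy.
* POMS: exactly 35 items rated 1–5, summed into depression/anxiety (14
  items), fatigue (7), vigor (7) and hostility (7). Subscale scores are
  **sums**, and the default item→subscale mapping
  (`inst/extdata/poms_mapping.csv`) follows the 14/7/7/7 structure of the
  German 35-item short form; the instrument's exact item order is not fixed
  by any single convention, so the mapping is an editable input, not a
  hard-coded fact.
* Faces scale: an ordered list of face drawings coded by letter; the default
  scale has 7 faces, saddest = 1 to happiest = 7. Both cardinality and
  direction are configuration, since instruments in circulation vary.

### Statistics

`mixed_anova()` fits the classical univariate split-plot decomposition for
one between-subjects factor (therapy group) and one within-subjects factor
(session/timepoint), on complete within-balanced data — every subject at
every level exactly once; group sizes may differ (dropouts). Missing cells
are an error, never imputed. The strata are

* between subjects: group (df a−1) against subject-within-group error
  (df N−a);
* within subjects: session (df k−1) and group×session (df (a−1)(k−1))
  against the session×subject error (df (N−a)(k−1)).

Sphericity is assessed by Mauchly's W on k−1 orthonormalized contrasts of
the covariance pooled within groups, with the first-order chi-square
approximation for its p-value. The Greenhouse–Geisser
ε̂ = (Σλ)²/((k−1)Σλ²) comes from the eigenvalues of the same contrast
covariance; ε is exactly 1 when k = 2, and always in (1/(k−1), 1]. Both the
uncorrected p and the ε-corrected p are always reported; when Mauchly's test
is significant at α = 0.05 the corrected p is flagged as the headline value
(`p_headline`). Effect sizes are generalized eta squared,
η²_G = SS_effect / (SS_effect + SS_subject error + SS_within error), the
design-robust choice for mixed designs. Post-hoc contrasts use the
studentized range (`tukey_hsd()`, Tukey–Kramer SE for unequal cells).

Tapping outcomes (median ITI, CV) are log-transformed before group analysis
(`log_transform_outcomes()`, which refuses non-positive values and records
the transform in a provenance column): both are strictly positive and
right-skewed, and the log scale brings their residuals much closer to the
ANOVA's normality assumption.

The nonparametric battery: `fisher_exact_2x2()` (two-sided by the
"probability at most that of the observed table" rule — the convention that
reproduces standard printed values), `friedman_test()` with mid-ranks and
tie correction, `mann_whitney()` reporting the rank-sum W together with a
tie- and continuity-corrected normal Z, and `welch_t()` with fractional
Welch–Satterthwaite df.

**Approximation quality.** The chi-square approximations in the Friedman
and Mann–Whitney tests are excellent in the tail regime where such studies
report their effects (p ≲ 0.05) and at cohort-sized blocks (n ≈ 28), which
the test suite verifies against exhaustive permutation/enumeration oracles
to within 0.01 and 0.02 respectively. With very small, heavily tied samples
(e.g. 5 vs 5 ordinal ratings) the normal approximation can be off by more
than 0.1 in the mid-range; for such data an exact test should be preferred.

### Minimization randomization

`assign_minimized()` reproduces quasi-random group assignment under accrual
in batches of 2–3 (a batch of 1 is allowed for accrual tails). Every
labelling keeping |n_A − n_B| ≤ 1 is enumerated and scored by the summed
standardized imbalance — |mean difference|/pooled SD for numeric covariates
(age, Barthel index, 9HPT baseline), |proportion difference| for sex — and
the minimal-imbalance labelling wins, ties broken uniformly at random under
the supplied seed. Equal covariate weights and pooled-SD standardization
are this package's choice of metric; the principle (size constraint first,
covariate balance second) is what matters, and the test suite checks the
behavioral consequences: the size constraint is never violated, and final
imbalance is stochastically far below random allocation.

## The synthetic-data generator

The generator exists so that every stage has checkable ground truth.

`generate_unpaced_trace()` draws inter-tap intervals **log-normal**,
parameterized by arithmetic mean (default 300 ms — a realistic impaired
speed-tapping rate) and CV (default 0.10): strictly positive and
right-skewed like real ITIs, which no symmetric choice reproduces. Each tap
is a piecewise-linear force pulse (10 ms rise, plateau at 0.5 N, 10 ms
fall, 100 ms contact): the only property the landmarking rules rely on is a
sharp threshold crossing, so any steep, unimodal shape would do. Artifact
processes mirror what patient recordings contain:

* **soft taps** (rate 0 by default) draw their peak uniformly below the
  0.05 N threshold — undetectable by design, they exercise the
  threshold-override path;
* **double taps** insert a brief (30 ms) re-contact 5–15 ms after the
  parent's release, creating onset-to-onset intervals under 120 ms for the
  interval filter to catch;
* **pauses** replace an interval with a 2.2–3.5 s gap, beyond the 2000-ms
  filter bound.

Sensor noise is additive Gaussian (SD 5 mN) clipped at 0 N, since a
resistive sensor cannot report negative force.

The ground truth records, per contact, the physical contact/release times
and the landmark that the full measurement convention — smoothing,
0.05 N threshold, 40/75 ms refractory — assigns on the noiseless trace.
That landmark is computed by a run-level walk over supra-threshold runs,
a deliberately different implementation from the detector's sample-level
scan, so the two routes cross-validate each other to within one sample.
The refractory rules belong in the ground truth because they are part of
the landmark definition: a re-contact 60 ms after an offset has, by
convention, no onset of its own.

`generate_paced_trace()` places clicks exactly 60000/tempo ms apart
(69 BPM, 60 s by default) and draws tap asynchronies from a normal
distribution wrapped onto the click cycle (defaults −30 ± 40 ms: tappers
anticipate the beat). The wrapped-normal mean and SD map to circular mean
phase and R = exp(−σ_φ²/2), which the sync summaries recover.

`generate_cohort()` produces the two-group clinical structure: ages ~66 ±
11 (truncated to the 30–75 inclusion range), Barthel ~48 ± 13, 9HPT
baseline 57.5 ± 34.8 s with a common therapy improvement of −10.5 ± 12 s
(negative = faster), POMS item ratings built from a per-patient latent mood
with PRE→POST subscale shifts (defaults: depression/anxiety −4, fatigue −3,
vigor +0.5, hostility −2 points — reduced distress, little vigor change),
and faces ratings on 12 time points with a gentle upward trend
(0.1 steps/session in both groups). Pegboard times use inverse-CDF
truncated normals rather than clamping, so no probability mass piles up at
the truncation boundary to distort change-score distributions. Group
differences are zero by default: the default cohort is a null cohort for
the group factor, and the test suite verifies type-I calibration of the
group×time interaction (≈ 0.05 over 1000 seeded replicates).

**What passing tests do and do not show.** The generator emulates pulse
shape, interval structure, artifact types and noise level — enough to prove
the chain recovers known ground truth bit-reproducibly. It does not emulate
tremor, force drift, sensor nonlinearity beyond the calibration table,
off-sensor strikes, or accelerometer kinematics; recovery rates measured on
synthetic traces are therefore upper bounds for real recordings, which is
precisely why the visual-inspection step of the original workflow survives
here as the audit flags and override provenance.

## Numerical conventions and degenerate inputs

* Empty metric inputs propagate as `NA` ("missing"), never as zero: the
  median of no intervals, the CV of fewer than two, and the sync summary of
  no onsets are all missing.
* An even interval count medians to the mean of the central pair
  (`stats::median`).
* Phases at exactly half a cycle map to +π; phases of empty onset lists are
  empty.
* The Rayleigh p is clamped to (0, 1]; uniform phases give p = 1 by the
  series expression at Z = 0.
* Mauchly's test is undefined at k = 2 (W = NA) where sphericity holds
  trivially and ε = 1 exactly.
* Minimization ties (identical candidates, symmetric states) are broken by
  seeded uniform sampling, making accruals reproducible.
* Seeds: every generator takes an integer seed and identical (params, seed)
  give bit-identical output; derived seeds stay below 2³¹ − 1.

## Problem sizes used in the checks

The packaged verification (`scripts/acceptance.R` and the acceptance test
file) uses 100 zero-noise 14-s traces for landmark recovery (~4200 taps),
twenty 120-s traces (~7900 kept intervals) for interval-metric recovery,
ten 90-s paced traces (~690 taps) for synchronization recovery, 1000 null
cohorts of 28 patients for ANOVA calibration, and 300 simulated 28-patient
accruals against 1000 random allocations for the randomizer — sizes chosen
so Monte-Carlo error is comfortably inside each stated tolerance.

## Known limitations

* The onset landmark carries a constant pulse-shape-dependent latency
  relative to physical contact (bounded by half the smoothing window);
  absolute asynchronies inherit it, within-subject contrasts and R do not.
* The trimmed CV under-reads the generating CV by ≈ 2% of its value (trim
  bias); all comparisons use the same estimator.
* Friedman/Mann–Whitney normal approximations are unreliable for tiny,
  heavily tied samples; the package reports them anyway (they are the
  study-battery convention) and the vignette's guidance is to use exact
  tests below n ≈ 10 with ties.
* No hysteresis in threshold crossing: a trace hovering at the threshold
  plus noise can chatter; the smoothing window suppresses this for
  realistic noise levels (tested at SD up to 20% of threshold).
* The POMS item→subscale mapping and faces-scale cardinality are
  configurable conventions, not instrument facts; results depend on
  supplying the mapping actually used in data collection.
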