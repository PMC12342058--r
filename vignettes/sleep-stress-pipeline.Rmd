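---
title: "Sleep staging, slow-wave metrics and resilience scoring on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging, slow-wave metrics and resilience scoring on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific background

`somnostress` implements the analysis chain of a mouse social-defeat
sleep study: rule-based wake/NREM/REM/artifact staging of EEG/EMG
polysomnography in 10 s epochs, delta-band slow-wave metrics, sleep-bout
architecture and sleep-restriction accounting, social-interaction-ratio
scoring with resilient/susceptible classification, and the statistical
toolkit (mixed repeated-measures ANOVA with Holm-Šídák step-down post-hocs,
Mann-Whitney U, Shapiro-Wilk gating, power-based sample sizing).

Because real recordings of this kind are rarely deposited, the package
carries a first-class synthetic polysomnography generator. Every downstream
stage is therefore testable end to end: the generator plants known
structure, the pipeline must recover it, and the test suite checks that it
does.

# The synthetic generator

## Hypnograms

States follow a semi-Markov chain over WAKE/NREM/REM with
geometric-per-epoch dwell (10 s epochs) whose means depend on state and
light phase; REM is entered only from NREM, the standard rodent staging
constraint. The base architecture was chosen once to look like a
C57BL/6-style 12:12 LD mouse: mean dwell (epochs, light/dark) of 22/31 for
WAKE, 15/10 for NREM, 6/5 for REM, NREM-to-REM branch probabilities
0.35/0.25 and REM-to-WAKE 0.60/0.70. These values give roughly 42% NREM and
6% REM in the light phase (about 148 min NREM and 21 min REM over ZT0-6,
in the range a gentle-handling restriction protocol removes) and about 25%
NREM in the dark.

Phenotype presets perturb that base: males have shorter dark-phase NREM
dwell and shorter dark wake bouts (more NREM bouts in the dark), females
have 1.4x longer REM bouts, susceptible animals another 1.3x in the light
phase. On post-defeat days NREM dwell is scaled 1.5x for susceptible
females, and 1.25x (with 0.75x wake dwell) for resilient males — the two
groups that gain NREM sleep after stress in this design. Defeat-day sleep
itself is left at baseline parameters: the emulated design quantifies
sleep at baseline, after restriction and after the defeat series, not
during it, so defeat-day deltas would be uninformed calibration knobs and
are deliberately not planted.

## The homeostat and the signals

A two-process Process-S variable drives NREM delta amplitude: exponential
saturating rise in wake (time constant 8.6 h), exponential discharge in
NREM (1.8 h), frozen in REM, clipped to [0.2, 1]. The constants are the
classical mouse values for delta-power dynamics; the bounds are arbitrary
units of the generator.

EEG is synthesized per epoch directly on the 0.1 Hz FFT grid as a sum of
band-limited Gaussian noise components — delta 0.5-4 Hz, theta 6-10 Hz, and
a 0.5-30 Hz broadband floor — with state-dependent time-domain amplitudes
(µV): wake 12/10/20, NREM 42·sqrt(S)/12/15, REM 8/32/8. The REM theta
component is narrowband noise rather than a deterministic sinusoid: it
plays the role of a theta oscillator with realistic cycle-to-cycle
variability while keeping the synthesis a single mechanism. No 1/f fractal
spectrum is modelled; the pipeline only consumes band powers, for which
this mixture is sufficient. Two EEG leads are produced; the parietal lead
carries 1.2x the frontal delta amplitude, which gives lead-specific
relative SWA something to detect. EMG is white noise with state-ordered
scale 30/10/4 µV (wake/NREM/REM). Artifact epochs add a 1 s, ±500 µV
clipping transient at epoch start. All synthesis is chunked through
`mvfft`, so a 24 h, 3-channel, 100 Hz day costs a few seconds.

What the generator does *not* emulate: mixed epochs at stage boundaries,
gradual state transitions, micro-arousals, spindles or slow-oscillation
events, movement artifacts with spectral structure, electrode drift, or
estrous-cycle modulation. Staging accuracies near 99% on this material are
therefore an upper bound; on real data the same rules would degrade, which
is why the acceptance bar is the scorer-agreement level (95%), not the
observed synthetic ceiling.

## Arena trajectories

Social-interaction trials are biased random walks at 10 Hz in the 30x30 cm
arena with a solid 9x9 cm cage against one wall: per-axis step SD 0.8 cm
(about 8 cm/s, a realistic exploration speed), reflecting walls, and a
drift of `bias x stepSd/20` toward (positive) or away from (negative) the
cage centre in the target trial only. Bias 0 gives symmetric occupancy, so
the expected interaction ratio is near 1; the mean SIR is monotone in the
bias and saturates around 1.3 because the interaction zone (within 15 cm
of the cage *boundary*) covers most of the arena. Cohort defaults plant
post-defeat bias +2.5 for resilient and -2.5 for susceptible presets,
which produce clearly separated SIR distributions while leaving a
realistic minority of animals in the excluded 0.9-1.1 band.

## Seeds

Every generator entry point takes an explicit seed; a master seed is split
into per-subject and per-day child seeds by a fixed affine map modulo
2^31 - 1, so cohorts are bit-reproducible and no two streams collide.

# Staging

Features per 10 s epoch: delta, theta and total (0.5-30 Hz) band power of
the staging lead (frontal by default), EMG RMS, and peak absolute
amplitude. The decision rule mirrors the classical manual criteria, in
order: artifact screens; high EMG → WAKE; else high theta/delta with low
delta → REM; else high delta → NREM; else WAKE.

Thresholds are calibrated per recording so that staging is invariant to
amplitude scale. The EMG threshold is the 0.60 quantile of the epoch
EMG-RMS distribution. For the delta threshold a single quantile is the
wrong tool: its correct placement equals the recording's non-NREM
fraction, which moves with phenotype and collapses on sleep-restriction
days, and a misplaced quantile lands inside the wake cluster and bleeds
wake into NREM. The default is therefore the geometric midpoint of the
0.30 and 0.97 delta-power quantiles: the low quantile sits in the
wake/REM cluster and the high one in the NREM cluster for any NREM
fraction between roughly 5% and 65%, so the midpoint falls in the gap
between clusters. Both thresholds remain per-recording quantile statistics
(order-free and scale-equivariant); absolute thresholds are available as a
calibration mode. The theta/delta REM ratio is 1.5, and the artifact
screens are a 400 µV absolute-amplitude limit plus a total-power z-score
of 6. No temporal smoothing is applied by default, matching epoch-wise
manual scoring; a 3-epoch majority filter is available behind a flag.
Trailing partial epochs are dropped, never padded. Files with strictly
more than 5% artifact epochs are excluded from all analyses.

# Spectral metrics

Spectra come from a rectangular-window FFT of each raw 10 s segment, whose
native resolution is 0.1 Hz (a Hann window is available by argument, with
power correction so Parseval holds either way). Power is stored as a
one-sided density, so summed band power over [lo, hi) times the bin width
equals that band's share of the segment mean square. Band edges are
half-open so delta + (4-30) partitions the total band without
double-counting the 4 Hz bin; closed intervals are available by argument.

Normalized SWA divides epoch delta power by the baseline-day mean;
because SWA is defined during NREM sleep, the divisor averages over
baseline NREM epochs only by default (the all-epoch divisor is an
argument, since the convention is not universal). Slow-wave energy is the
running sum of delta power x 10 s over NREM epochs only — artifact and
non-NREM epochs contribute nothing but carry the total forward — and is
reported both raw and, in cohort summaries, normalizable to baseline.
Time courses are per-ZT-bin NREM means with SEM; empty bins are missing,
never zero.

# Architecture and behavior conventions

Bouts are maximal runs of identical state; ARTIFACT runs break bouts and
are excluded from bout statistics (kept as rows so segmentation is
invertible). A bout spanning the light/dark boundary belongs to the phase
of its onset — per-phase minute totals are unaffected because they count
epochs, not bouts. All windows are half-open `[start, end)` with epochs
assigned by their start time. Sleep lost is baseline-minus-restriction
over ZT0-6 per state; recovery is the hourly cumulative gain over
ZT6-24; total sleep is NREM + REM.

The interaction zone is measured from the cage *boundary*, not its centre:
a 15 cm radius from the centre of a 9 cm cage would barely clear the cage
itself; centre mode is available by argument. Trajectories are resampled
to a uniform 10 Hz grid before time integration. SIR > 1.1 is resilient,
SIR < 0.9 susceptible, and the closed band [0.9, 1.1] is excluded from
sleep analyses while remaining in behavioral tables; a zero empty-cage
time raises an error for manual review rather than silently excluding the
subject.

# Statistics

The mixed repeated-measures ANOVA fits a multivariate linear model over
the within-subject (time) responses with sum-to-zero contrasts and
Type-III sums of squares, i.e. an unweighted-means solution for unbalanced
between-subject cells such as 12 females versus 8 males. Between effects
are tested against subjects-within-groups, within effects against the
subject-by-time residual. No sphericity correction is applied by default,
matching the classical reporting style; Greenhouse-Geisser adjusted
p-values are available by argument. Degenerate all-equal data yield F = 0,
p = 1 rather than 0/0.

Holm-Šídák compares the i-th smallest of k p-values against
`1 - (1 - alpha)^(1/(k - i + 1))` and stops at the first failure. The
Mann-Whitney U uses midranks, full enumeration of group assignments for
combined n ≤ 8 (exact even under ties) and a tie-corrected,
continuity-corrected normal approximation above.

The sample-size rule is the two-sample, two-sided normal approximation
`n = ceil((z_{1-a/2} + z_{1-b})^2 * 2 sd^2 / diff^2)` with floor 2; with
sd 14.6 min and difference 25 min at alpha 0.05 and power 0.8 it returns
6 per group. This is the only standard variant that yields 6 for those
inputs; the exact noncentral-t iteration is more conservative (7) and is
offered as `method = "t"`. Consistently, the Monte-Carlo power check in
the test suite simulates the stated normal (known-variance) model, under
which n = 6 achieves about 84% power.

# Numerical and design choices

* Problem sizes in the tests were chosen to exercise each property at
  meaningful scale while keeping a default run near three minutes: ten
  full synthetic days for stager fidelity, 20 seeds for restriction
  recovery, 50 replicate 16-subject cohorts for the planted-contrast
  detection rate, 2000 null replicates for the type-I check of the
  ANOVA-gate + Holm-Šídák pipeline, 250 seeds for arena symmetry.
* `runStudy()` groups sleep analyses by the *measured* post-defeat
  phenotype, as the emulated protocol does, so preset/classification
  mismatches contribute realistic noise; the planted-contrast power check
  instead conditions on the true presets, since it measures the stats
  module, not the arena.
* The cohort pipeline can run at hypnogram level (`signalDays =
  character(0)`): staging and spectral stages are bypassed and true
  hypnograms feed the architecture stages directly. This mode exists for
  Monte-Carlo work; the full-signal mode is the default.
* Recordings live in memory as named channel vectors with sampling-rate
  metadata; hypnograms, trajectories and spectral tables serialize to
  CSV/TSV. No binary signal format is written.
* Exported analysis functions are deterministic; all stochastic entry
  points take explicit seeds.

# Known limitations

The stager is validated only against its own generator (see above); its
quantile calibration assumes the recording contains at least a few percent
of each state. The semi-Markov generator has geometric dwell, hence
exponential-like bout-duration tails without the heavy tails of real wake
bouts. The arena model has no thigmotaxis or cage-sniffing behaviour
beyond drift, so absolute SIR magnitudes above ~1.5 are not reachable even
at strong bias. Estrous-cycle effects, aggressor behaviour and any
biophysical stress mechanism are out of scope.
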