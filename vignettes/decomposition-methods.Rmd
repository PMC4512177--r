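---
title: "Separating learning probability from response amplitude in delay eyeblink conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating learning probability from response amplitude in delay eyeblink conditioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyeblinkr)
```

## The problem

In delay eyeblink conditioning a head-fixed mouse learns that a light flash
(the conditioned stimulus, CS, 280 ms) predicts a corneal airpuff (the
unconditioned stimulus, US, 30 ms, co-terminating with the CS). With
training, an anticipatory eyelid closure — the conditioned response (CR) —
develops, peaking near the expected US time. The classical summary, the
fraction of trials whose eyelid deflection crosses a fixed threshold
("%CR"), conflates two different things: how often the animal produces a
learned response, and how large the responses are when they occur.
`eyeblinkr` implements an analysis that separates the two, together with
everything around it: a protocol-faithful trial scheduler and trace
simulator, normalization against the reflex blink, response detection and
timing, and the group statistics used to compare genotype cohorts.

## The decomposition

For each session, the peak normalized eyelid deflection in a measurement
window after CS onset is collected for every trial, keeping the **signed
extremum** (the value of largest magnitude, with its sign), so that
negative-going eyelid *openings* populate negative bins. These values are
histogrammed with a bin centered exactly on zero (width 0.025, so the zero
bin spans −0.0125 to 0.0125).

Trials in which the animal fails to respond scatter symmetrically around
zero. The part of the histogram below zero, *plus its reflection across the
zero axis, plus the zero bin*, is therefore an estimate of the non-response
distribution; its integral divided by the trial count is the **failure
rate**, and

- **response probability** = 1 − failure rate,
- **response amplitude** = center of mass of the response distribution
  (the positive side after subtracting the reflected negative side, floored
  at zero per bin).

The amplitude is undefined (returned as `NA`) when no response mass
remains, e.g. for a perfectly symmetric histogram.

```{r decomposition-example}
set.seed(1)
n <- 1000
responding <- runif(n) < 0.4
peaks <- ifelse(responding, rnorm(n, 0.40, 0.05), rnorm(n, 0, 0.02))
reflect_and_decompose(build_histogram(peaks))
```

### Numerical conventions

* Values map to the nearest bin center (half-open bins, left edge
  inclusive), so one bin always spans exactly `[-w/2, +w/2)`.
* The whole zero bin is assigned to the non-response side by default; the
  alternative of splitting it half/half is available
  (`zero_bin = "split"`).
* Failure rate and probability are clamped to `[0, 1]`; per-bin response
  mass is floored at 0.
* Measurement window: 100–250 ms after CS onset on paired trials (stopping
  at the US so the reflex blink cannot contaminate the peak), 100–280 ms on
  unpaired CS trials where no US occurs. Both are configurable; the
  source protocol described both variants and we keep each where it is
  well-defined.
* US-only trials carry no CS window and never enter the histogram.

### Known limitations

The floored center-of-mass amplitude is slightly biased downward when the
response probability is small: with noise SD 0.02 and bin width 0.025,
random surpluses of positive over negative noise counts survive the
flooring and add spurious mass near zero (about a dozen trials' worth at
n = 1000), which drags the center of mass down by ≈0.03–0.04 when only
~10% of trials respond. The unfloored signed alternative is much worse —
its denominator is the difference of two large counts and the estimate's
variance explodes — so the floored estimator is kept. At response
probabilities ≥0.3 the bias is below 0.01. The probability estimate itself
is unbiased throughout (the reflection cancels any symmetric noise
distribution exactly in expectation).

## Normalization and preprocessing

Raw traces are in sensor volts. Each trial is rescaled so its pre-CS
baseline (mean of the 500 ms before CS onset; the window is configurable —
the protocol described only "the baseline") maps to 0 and the
unconditioned-response (UR) peak maps to 1. Paired and US-only trials use
their own UR, searched within 200 ms of US onset (UR latency plus rise time
sum to well under that); unpaired CS trials carry forward the UR range of
the most recent US-containing trial in the session. A CS-only trial with no
prior US reference, or a trial whose UR peak fails to exceed its baseline,
is marked invalid rather than raising an error. A session-wide-average-UR
normalization is available as `normalization = "session_average"` for the
equivalence comparison.

Smoothing is a zero-phase (centered) moving average, default width 10 ms,
applied before peak collection and before timing analysis. All threshold
comparisons are strict, and all windows are closed on both ends unless
stated; times are in ms from CS onset (from US onset for US-only trials).

The adaptive intertrial-interval rule is represented by
`check_baseline_stability()`: a trial may begin only when every sample of
the final 1 s before the planned CS stays within ±10% of the average UR
amplitude around the window median; each violation postpones the trial by
1 s. Offline, `stable` is judged on the final window, and
`extensions_needed` counts how many consecutive shifted-back windows fail
the criterion — a reconstruction of how many postponements immediately
preceded the trial.

Trials whose normalized response exceeds 0.05 between 0 and 99 ms after the
CS are excluded from CR scoring (`early_movement_flag()`). By default this
exclusion applies to unpaired-trial response timing only, where it was
stated for CR scoring; `exclude_early_movement = TRUE` extends it to the
decomposition input as well.

## Response detection and timing

On unpaired CS trials, a trace scores as a CR when it exceeds 0.15 between
100 and 400 ms after CS onset while staying below 0.05 in the early window.
For scored CRs:

* **peak latency** — argmax of the smoothed trace in the CR window, ties to
  the earliest sample;
* **onset latency** — the change in concavity of the eyeblink,
  operationalized as the latest time before the 10%-of-peak crossing at
  which the centered second difference of the smoothed trace turns from
  ≤0 to >0. The second difference is itself lightly smoothed (3 samples)
  so noise flickers are not mistaken for concavity changes; if no change
  is found the 5%-of-peak crossing is used and flagged;
* **10–90% rise time** — time between the first crossings of 10% and 90%
  of peak after onset, with sub-sample linear interpolation.

The UR uses the same onset detector for internal consistency (its exact
published definition was not specified), searched within 75 ms of US onset,
plus the 10–90% rise time and the peak velocity (maximum first difference
per ms in the UR epoch). Photic eyelid openings — non-associative dips more
than 5% below baseline between 70 and 250 ms after the CS, but not before —
are detected only while the session has produced no CR yet, since they
occur before conditioning takes hold.

## The synthetic cohort generator

No public dataset accompanies the source experiments, so the package ships
a generative model that emulates them end to end, with ground-truth labels
for every trial:

* **Schedule**: 22 blocks of 10 trials per session; acquisition blocks hold
  9 paired + 1 unpaired CS trial, extinction blocks 5 CS-only + 5 US-only,
  each placed uniformly at random within the block from a seeded generator
  ("pseudorandomly" was all that was specified). 12 acquisition, 4
  extinction and 3 reacquisition daily sessions.
* **Learning dynamics**: the per-session true response probability follows
  a saturating exponential `p_s = p_max (1 − e^{−s/τ})` (defaults
  `p_max = 0.55`, `τ = 4` sessions, chosen so a wild-type-like cohort
  levels off near 51% over sessions 9–12); amplitude grows the same way
  toward 0.45. Extinction decays probability with its own constant
  (`τ_ext = 1.2`, giving near-disappearance by extinction day 4) and
  reacquisition regrows it with `τ_reacq = 1.2` — faster than acquisition,
  i.e. savings. Genotype phenotypes are expressed as changes to `p_max`,
  the amplitude asymptote, or the CR timing parameters.
* **Waveforms**: the CR is a monotone Hermite-spline bell parameterized
  directly by onset (Normal, mean 145 ms, SD 10 ms), peak time and 10–90%
  rise, with the fall mirroring the rise. Parameterizing the rise directly
  keeps every generated timing statistic known exactly; the per-trial rise
  is capped at 90% of the onset-to-peak span so the bell stays monotone,
  and when a configured rise demands a longer span than CS-onset-to-US the
  peak target shifts later — slow-rising phenotypes peak after the US time,
  as observed in their biological counterparts. The UR is a delayed
  (Normal, mean 30 ms, SD 5 ms) linear rise (65 ms) with exponential decay;
  its raw peak voltage defines the normalization scale. Traces carry
  Gaussian sensor noise (SD 0.02 normalized units), slow baseline drift
  (interpolated Gaussian knots, SD 0.01, 1 s spacing), and occasional
  negative photic openings (probability 0.1, depth 0.12, onset 70–250 ms
  after the CS).
* **Sampling**: 1 kHz, 2.5 s records with the CS at 1.0 s, leaving a full
  1 s baseline window. The analog bandwidth of the original recordings was
  reported but not the digitization rate; 1 kHz resolves every timing
  quantity analyzed here (sub-sample interpolation recovers the rest).

What the generator does *not* emulate: locomotion-coupled artifacts,
sensor-gain drift across sessions, habituation-phase behavior, blink
oscillations, or any within-session learning. Tests passing on this
generator show that the analysis recovers the generative quantities under
realistic noise; they do not certify performance on pathologies the
generator lacks.

Two reduced-scale harnesses exist for repeated-replicate studies:
`simulate_metrics_cohort()` draws each session's peak samples directly from
the two-component mixture the decomposition models (the natural scale for
type-I-error and power studies — 1000 cohort replicates of raw traces
would be pure runtime with no additional information), and
`simulate_timing_cohort()` generates compact unpaired-CS traces for
rise-time power analyses. Problem sizes used by the shipped studies: 1000
null replicates of 10+10 subjects × 12 sessions × 110 trials for type-I
calibration; 200 replicates each for the probability-deficit (12 vs 12
subjects, `p_max` 0.55 vs 0.35) and timing-deficit (rise 90 vs 140 ms, 8
trials/subject) detection studies.

## Group statistics

The statistics mirror the field's standard battery: unpaired and paired
t-tests; one-way ANOVA with Bonferroni correction applied to *planned*
comparisons only (the adjusted p is the raw p times the number of planned
pairs, capped at 1); a two-way mixed-design ANOVA (genotype between,
session within) computed as the classical balanced univariate analysis with
the genotype effect tested against the subject-within-group mean square —
session is treated as categorical and no sphericity correction is applied,
matching the uncorrected F/df reporting convention; ANCOVA with age as a
linear covariate followed by Tukey HSD on adjusted means (constant age
reduces it to one-way ANOVA rather than erroring); and Cohen's d with the
Bessel-corrected pooled SD, which for equal group sizes satisfies
`t = d·sqrt(n/2)` exactly. Missing data are excluded listwise per analysis
with a loud warning; nothing is imputed. Subjects lacking a phase are
dropped from the extinction/savings paired comparisons, and groups that
never acquired CRs are reported but skipped there.

One protocol note: the source description of extinction was internally
inconsistent (one passage implies 110 CS-only + 110 US-only trials *in
total* across four sessions, the procedural description gives 22 blocks of
5+5 *per session*). The scheduler follows the procedural description:
110 + 110 per session.

## Reproducibility

Every stochastic step takes a seed; cohorts derive per-subject,
per-session seeds deterministically from one master seed, so an entire
dataset and every analysis of it is reproducible byte for byte.
`run_pipeline()` logs per-stage trial accounting, and exported tables carry
a schema line, the config hash and the seed in their header.
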