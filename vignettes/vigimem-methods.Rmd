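---
title: "Scoring and inference methods in vigimem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and inference methods in vigimem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigimem)
```

vigimem analyses two-group cognitive studies built around two decrement
endpoints: the **vigilance decrement** (decline of detection accuracy with
time on a sustained-attention task) and the **episodic memory decrement**
(loss of recognition accuracy between an immediate and a delayed probe).
This vignette is the package's account of the underlying models, the
tunable parameters, the synthetic data generator, and the numerical and
design choices a maintainer should know about.

## The vigilance task and its scoring model

The task presents one digit per second, 60 trials per one-minute block,
nine scored blocks preceded by a practice block (index 0). The digit `0`
is the target, appearing with probability 0.25; participants respond by
keypress to targets only. Each trial is classified as TP (response to a
target), FP (response to a non-target), FN (missed target) or TN
(withheld response). Because a trial occupies a fixed one-second window,
a keypress is attributed to the stimulus on screen during that window and
multiple presses in one window count once; the input format encodes this
as a single `responded` flag per trial.

Per-minute accuracy is the F1 score,

$$F1 = \frac{2\,TP}{2\,TP + FP + FN},$$

the harmonic mean of precision and sensitivity. F1 disregards true
negatives, which is the property wanted for rare-target detection: doing
nothing for 45 of 60 trials should not look like 75% performance. F1 is
undefined (NA) in a block with no targets and no false alarms; affected
participants are dropped from aggregates that need that block, mirroring
listwise handling in two-sample comparisons.

Reaction times are summarized per block over TP trials only, after a
single (non-iterated) exclusion of RTs more than two sample standard
deviations (n − 1 denominator) from the block mean. With fewer than three
RTs the criterion is meaningless and trimming is skipped. The trimming is
applied per participant per block; applying it pooled would let slow
participants' RTs shadow fast participants' outliers.

Participant-level endpoints use three-block windows: baseline accuracy is
the mean F1 of blocks 1–3, final accuracy the mean of blocks 7–9, and

$$\text{vigilance decrement} = 100 \times
  \frac{\text{final} - \text{baseline}}{\text{baseline}}\ (\%).$$

The practice block is scored (it is plotted at t = 0) but never enters
baseline or final windows. A zero baseline leaves the decrement undefined
and flagged. Accuracies are carried as unit fractions internally and
rendered as percentages only at reporting, which avoids double-scaling
bugs; `memory_decrement()` is tested to be invariant to the input scale.

Fatigue and motivation ratings (0–100 visual-analogue scale, one pair
after every block) are summarized with the same windows: baseline is the
mean over ratings after blocks 1–3, change is last-3 minus first-3.

## Memory scoring and misbinding

The object-memory probe shows 20 items, each tested 8-alternative
forced-choice (chance 12.5%), once immediately and once after a
maintenance interval of roughly 30 minutes. Outcomes are
`correct`, `same_object_wrong_orientation`, or `other_error`. The second
category — right object, wrong orientation — is the *misbinding* error, a
failure to bind object identity to orientation in memory, and is tracked
as a separate false-alarm rate per phase.

The memory decrement is the delayed-minus-immediate accuracy change
normalized by immediate accuracy, in percent. Note a property of this
ratio statistic that shows up in real and synthetic cohorts alike: with
20-item probes, the per-participant immediate accuracy is noisy, and
E[(D − I)/I] is inflated relative to (E[D] − E[I])/E[I] (positive
covariance between the change and 1/I). Group *means* of the normalized
decrement can therefore sit well above the ratio of group mean
accuracies, especially in groups with little true change. The group
comparison is unaffected in calibration (type-I error stays nominal; see
the acceptance suite), but single-group means of this statistic should be
read with that bias in mind.

A maintenance-interval adjustment (`adjust_for_maintenance()`)
residualizes the decrement on the interval by least squares; it is a
robustness check for comparisons against groups tested with longer
intervals (e.g. elderly controls) and is only applied when explicitly
requested.

Word-memory probes (24 words, 50% non-targets) are accepted by the data
model with hit/miss/false-alarm/correct-rejection outcomes; accuracy is
(hits + correct rejections)/24. The exact published scoring rule for that
task is not stated, so this convention is configurable at scoring time.

## Resampling inference

Two bespoke procedures handle the unbalanced design (n = 53 vs 83 in the
emulated study; resample size N defaults to the smaller group, matching
both published uses N = 53 and N = 13):

**Time-series divergence.** Per iteration, N participants are drawn with
replacement from each group and the per-minute difference of mean F1
recorded. A minute is flagged when more than 95% of iteration differences
share a sign. Participants are redrawn jointly across timepoints (the
participant, not the cell, is the resampling unit; the alternative of
independent per-timepoint redraws would break within-participant
autocorrelation). Internally the resample is drawn as multinomial row
weights and the iteration loop becomes a matrix product; a test verifies
the flag rates agree with a directly coded index-resampling loop.

**Group test.** The same resampling applied to a scalar endpoint. The
literal >95% sign criterion is reported (`significant`), and alongside it
a conventional two-sided bootstrap p-value
`2 * min(P(diff <= 0), P(diff >= 0))`. The two are both emitted because
the literal sign criterion corresponds to a two-sided size of roughly
2α; reports label which is which. Ties at exactly zero count toward
neither sign, keeping the two proportions summing to at most 1 without
bias.

All resampling entry points take an explicit seed, restore the caller's
RNG state, and record seed and iteration count in their results.

## Parametric endpoints

- **t-tests** are pooled-variance Student by default (every recomputable
  published group comparison reproduces under the pooled form; Welch is
  available behind a flag). df is always the conventional n₁ + n₂ − 2 —
  some published tables print n − 1 for a two-sample test; the statistic
  itself is unaffected. Printed-table reproduction rounds t to one
  decimal, half away from zero (`round_half_away()`).
- **JZS Bayes factors** use the Cauchy(0, √2/2) prior on standardized
  effect size, computed by adaptive quadrature (relative tolerance 1e−8)
  over the inverse-gamma mixing parameter, with effective N =
  n₁n₂/(n₁+n₂) for two samples. Because the direction of a bare printed
  "BF" is ambiguous, results always carry both `bf10` and `bf01`
  (bf10·bf01 = 1 to 1e−9). An independent trapezoid-quadrature oracle
  backs the implementation in tests.
- **Chi-square** for 2×2 tables is Pearson without continuity correction
  (the form under which the published gender statistic reproduces).
- **Spearman correlations** use average ranks and the t-approximation
  for p; partial rank correlations rank-transform everything, residualize
  x and y on the covariates by least squares, and correlate residuals
  (df = n − 2 − k).
- **PCA composites** z-score each measure, take the first principal
  component, and orient its sign to correlate positively with the
  row-mean of the z-scored inputs, so "higher composite = better
  performance" whenever the inputs are coded that way. Zero-variance
  columns are dropped with a warning.
- **Bonferroni** adjustment takes an explicit family size m (default 29,
  the full ledger of battery tests in the emulated study), which may
  exceed the number of p-values passed.

## The synthetic cohort generator

The participant-level data of the study this package emulates are not
publicly deposited, so every pipeline stage is verified against a
generator (`cohort_config()` / `simulate_cohort()`) that reproduces the
study's data-generating *structure*:

- Two groups (default n = 53 "covid" vs 83 "control"), 9 scored blocks ×
  60 one-second trials plus practice, target probability 0.25.
- Hit probability drifts linearly per block on the probability scale,
  centred so blocks 1–3 average to the participant's baseline, then
  clipped to [0.01, 0.99] — the simplest model matching a roughly linear
  published decline. Defaults are expressed through `hit_rate_for_f1()`,
  which inverts the expected-F1 relation: baseline F1 0.755/0.785 and
  expected normalized decrements −12.3%/−0.9%.
- Between-participant heterogeneity: baseline hit rate SD 0.12 and drift
  SD 0.01 per block. These were chosen once to put baseline accuracy
  spreads near the published ~20-point SDs; the generator does not
  attempt to match the published decrement SDs exactly (the control
  group's published 29.1% spread implies slope heterogeneity beyond this
  model).
- RTs are log-normal (median 0.45 s, σ = 0.25 on the log scale)
  truncated to (0, 1 s] — the stimulus cadence bounds a valid RT.
- Recovery with time: the exposed group's drift is scaled by
  max(0, 1 − days/τ), τ = 270 days by default (decrements vanish by
  roughly nine months). The factor is renormalized to mean 1 over the
  configured days distribution (uniform on 5–330 days by default), so
  configured group decrement means are preserved in expectation — the
  property the parameter-recovery tests check.
- Memory: per-participant correct probability (mean 0.600/0.601,
  SD 0.12); misbinding probability scaled proportionally into the error
  mass; at delay, a per-participant transfer δ (mean 0.075/−0.017,
  SD 0.03) moves mass from `correct` to `same_object_wrong_orientation`
  only, leaving `other_error` fixed — the delayed deficit is localized to
  orientation misbinding. The published immediate-accuracy drop and
  orientation-FA rise are not exactly consistent with a pure-transfer
  model; the default δ matches the accuracy drop, the primary endpoint.
- Ratings follow linear group trajectories with Gaussian noise, clamped
  to [0, 100]; covariates (age, gender, grit and two other questionnaire
  scores, maintenance interval) are drawn at published group means/SDs.
- The within-participant correlation between vigilance and memory
  decrements is not a published quantity; `shared_latent_r` exposes an
  optional shared latent factor, default 0.

Every participant draws from an RNG stream derived from the seed, the
group and the within-group index, so cohorts are byte-reproducible and
either group can be enlarged without perturbing existing participants.

**What passing tests do and do not show.** The generator emulates
marginal trajectories, category frequencies and the recovery covariate;
it does not model response-window ambiguity, speed–accuracy trade-offs,
non-stationary lapses, distractor-similarity structure in memory errors,
or questionnaire item-level processes. Calibration and recovery results
on synthetic cohorts therefore validate the *pipeline arithmetic and its
statistical size/power*, not the psychological model of any real cohort.

## Problem sizes and numerical choices

Simulation-based tests use sizes chosen to give stable Monte-Carlo
verdicts while keeping the suite quick: null calibration uses 500
replicate cohorts of 40 + 40 participants (binomial 99% bounds around
α = 0.05 are then ±2.5 points); parameter recovery uses one 200 + 200
cohort and a 3-Monte-Carlo-SE criterion; oracle-equivalence suites use
1000 random instances per scalar operation. The acceptance script runs
the full default cohort (53 + 83) with 10 000 bootstrap iterations.

Degenerate inputs are handled in-band and tested: undefined F1 and RT
summaries propagate as NA; zero pooled variance yields t = 0 (equal
means) or flagged infinity; zero-variance PCA columns are dropped;
zero marginals make the chi-square NA; empty time-since-diagnosis bins
report n = 0 rather than erroring.

## Known limitations

- The decrement ratio statistic's small-sample bias (above) is inherited
  from its definition; comparisons are calibrated, single-group means
  are biased upward when the immediate score is noisy.
- The bootstrap sign criterion is reported faithfully but is
  anti-conservative as a two-sided test (~2α); use `p_two_sided` when a
  conventional error rate is wanted.
- Word-memory scoring and the exact time-bin edges beyond {2, 9} months
  are conventions, configurable at call time.
- The pipeline does not fit mixed-effects GLMs of minute-wise accuracy
  or severity models; those are deliberately out of scope.
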