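---
title: "Methods: pupillometry preprocessing and Bayes factor time-course analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry preprocessing and Bayes factor time-course analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilflow)
```

## The problem

Violation-of-expectation studies with preverbal infants infer what an
infant expected from how strongly they react to an outcome. Pupil dilation
is a sensitive index of surprise and processing effort, and — unlike
cumulative looking time — it resolves the reaction in time. A typical
design shows an agent watching an object move between two hiding
locations; on test trials the agent either witnesses a final change of
location (true belief, TB) or misses it (false belief, FB), and the
outcome is either reality-congruent or reality-incongruent. The dependent
measure is the baseline-corrected relative pupil change over a 5-s outcome
phase, contrasted between outcomes with default-prior Bayes factors, both
averaged over the phase and timepoint by timepoint.

`pupilflow` implements this analysis chain end to end: parsing and
segmenting 120 Hz binocular eye-tracker exports, the preprocessing cascade,
the Bayes-factor machinery, evidence-window detection, anticipatory-looking
scores from fixations, a sequential-design simulator, and a synthetic-data
generator that gives every stage a ground truth to be tested against.

## Trial timeline

All stages share one declarative timeline (`trial_timeline()`), with
half-open windows `[start, end)` in trial-relative milliseconds so that
boundary samples are never double counted. The default encodes a 23.2-s
trial at 120 Hz: anticipation 15–17 s, baseline 16.5–17 s (the 500 ms
immediately before the outcome reveal begins), reveal 17–18.2 s, outcome
18.2–23.2 s. The outcome grid has exactly
`5 s × 120 Hz = 600` sample slots.

## The preprocessing cascade

`preprocess_trial()` composes the stages in a fixed order; each is also
exported on its own:

1. **Grid snapping** (`snap_to_grid`). Hardware timestamps jitter, but the
   gap-interpolation rule below is defined in *samples*; each recorded
   sample is therefore assigned to the nearest slot of the nominal
   8.33-ms grid, and validity flags are applied.
2. **Unrealistic values** (`remove_invalid`). Negative pupil diameters are
   set to missing per eye; samples whose gaze point lies outside the
   screen lose both eyes' pupil values.
3. **Percentile artifact filter** (`percentile_filter`). Each sample gets a
   score: the mean of its absolute differences from the previous and next
   sample. Samples whose score *strictly* exceeds the 90th percentile of
   the trace's own score distribution are removed. Scores are computed once
   on the input — no iterative re-filtering — and the distribution is per
   trace (per eye, per trial), reading "the respective distribution" as the
   trace at hand. The strict inequality means a constant trace passes
   untouched.
4. **Gap interpolation** (`interpolate_gaps`). Missing runs of at most 8
   samples (~70 ms at 120 Hz) flanked by data on both sides are filled
   linearly; longer runs and edge runs stay missing. This bridges tracking
   dropouts but deliberately not blinks.
5. **Binocular averaging** (`combine_eyes`), then a second filter +
   interpolation pass on the averaged trace with the *same settings* (the
   percentile threshold is recomputed on the averaged trace — settings are
   reused, not thresholds).
6. **Baseline correction** (`baseline_correct`). The baseline is the mean
   of the valid samples in the baseline window; every outcome-phase sample
   becomes relative change `(x − b) / b`. The transform is unit-free: tests
   assert invariance under rescaling the raw trace. A single valid baseline
   sample suffices (the source procedure states no minimum; a stricter
   minimum can be emulated through the multiverse runner); a trial with an
   empty or non-positive baseline is excluded with reason `no_baseline`.
7. **MAD outlier exclusion** (`mad_exclude`). Outcome-phase points farther
   than 3 *unscaled* median absolute deviations from the trial median are
   removed, in a single pass. "Three median absolute deviations" is taken
   literally — no 1.4826 normal-consistency constant (a scaled variant is a
   flag). When the MAD is zero, the strict rule removes every point that
   differs from the median at all; on noise-free synthetic data this
   deletes a minority-window plateau, which the test suite documents
   explicitly. A consequence worth knowing: because the MAD fence sits
   near 2 noise SDs, large genuine responses are partially clipped, so
   amplitudes recovered through the full cascade are attenuated by roughly
   10–15% relative to the planted truth (tests quantify this).
8. **Inclusion rules**. A trial needs at least 10% valid outcome-window
   points ("less than 10% excluded" read strictly, so exactly 60/600 is
   kept; the robustness variant uses 50%), an on-screen-gaze fraction of at
   least 50% during the change-of-location window (the automated
   counterpart of the manual video-coding rule; window configurable,
   default 9–13.4 s), and subjects enter an analysis only with at least
   one included trial per required condition cell (`include_subject`).

Open choices resolved here: whether the percentile filter cuts at `>` or
`>=` is unstated in the source procedure — strict `>` was chosen (it also
keeps constant traces intact); the baseline uses the filtered signal, since
filtering precedes segmentation in the stated order.

`multiverse_run()` re-runs preprocessing plus the downstream contrast over
a grid of `filter_params()` variants (e.g. percentile 90/95 × inclusion
0.10/0.50) with identical seed policy, so the stability of a result
against these choices is a one-liner.

## Bayes factors

All contrasts are quantified by the Bayes factor `BF10`, the evidence for
the alternative relative to the null.

* **JZS t tests** (`jzs_ttest_bf`): the default-prior Bayes factor with a
  Cauchy prior (scale `sqrt(2)/2`) on the standardized effect, computed by
  numerical integration over the auxiliary g-prior representation, with
  the integrand evaluated in logs. The quadrature's relative error bound is
  returned in `numerical_error`; the test suite checks agreement to 1e-6
  with an independent oracle that integrates the noncentral-t likelihood
  against the Cauchy prior directly.
* **Mixed-model contrasts** (`bic_lmm_bf`): trial-level values with a
  condition fixed effect and a subject random intercept, fitted by maximum
  likelihood, with `BF10 = exp((BIC0 − BIC1)/2)` — the unit-information
  approximation. It is deterministic and fast, which the per-timepoint
  analysis needs; its known conservatism (a 1-SD effect at 30 subjects
  clears BF 3 in about 88% of simulations) is asserted in the tests rather
  than hidden. The random-intercept models are fitted by an exact
  profiled-ML routine: with `V(θ) = I + θZZ'`, the GLS quantities reduce
  to per-subject sums and the deviance is optimized over the single
  variance ratio θ; the fit is verified against `lme4::lmer(REML = FALSE)`
  to ~1e-13 in log-BF, and lme4 remains the fallback on numerical failure
  (with a final fallback to the subject-aggregated paired JZS test,
  recorded in the `method` field).
* **Interaction** (`interaction_bf`): `outcome * belief` against
  `outcome + belief`, same machinery.
* **Signed-rank** (`signed_rank_bf`): the exact Wilcoxon statistic W plus a
  default-prior BF computed by applying the JZS machinery to the signed
  ranks — a documented approximation to the latent-normal rank BF, chosen
  because an exact latent-normal sampler is out of proportion to its role;
  the method name is recorded in every result.
* **Binomial** (`binomial_bf`): uniform prior on the success probability,
  closed form `B(k+1, n−k+1) / (p0^k (1−p0)^(n−k))`.

`classify_bf()` maps a BF to the standard evidence grades (3–10 moderate,
10–30 strong, 30–100 very strong, >100 extreme; reciprocals against;
1/3–3 anecdotal), with a boundary value assigned to the stronger grade and
reciprocal symmetry asserted by tests.

## Time-resolved contrasts

`per_timepoint_bf()` runs the two-condition mixed-model contrast at every
outcome-grid point from 1000 ms onward (earlier points are dominated by
the reveal). Timepoints where either condition has fewer than 2 subjects
with valid data are skipped, not imputed — conservative and visible in the
output. `detect_windows()` then reports evidence windows: maximal runs of
consecutive points with `BF10 >= 3` and constant direction, half-open in
ms. The minimum run length defaults to 1 grid point because real analyses
report windows as short as 75 ms. No multiplicity correction is applied
across timepoints (none is standard for this descriptive analysis); the
result object carries a note saying so. Whether the per-timepoint models
should use trial-level or subject-aggregated data is not settled in the
source; trial-level mixed models are the default to match the stated model
structure, with `method = "jzs"` as the aggregated alternative.

## Gaze and anticipatory looking

`detect_fixations()` implements the Olsson-style sliding-window velocity
classifier behind the classic commercial fixation filter: for each sample
the mean gaze positions of the preceding and following 5 samples are
compared; displacements above the threshold (default 35, interpreted in
px/window as in the original tool — px/s mode available, and the mode is
part of the provenance) mark saccadic samples; runs of non-saccadic
samples become fixations; consecutive fixations with centroids closer than
35 px merge; fixations under 60 ms are dropped.

`anticipatory_scores()` clips fixations to the 15–17 s anticipation window
and scores looking toward the two hiding-location AOIs:
`DLS = (t_congruent − t_incongruent) / (t_congruent + t_incongruent)`,
with the AOI-total denominator (window-total is a config option), and the
first gaze as the AOI of the earliest in-window fixation. The exact AOI
rectangles are not derivable from the stimuli and therefore come from
configuration (`aoi_set()`); defaults place two 280×240 px rectangles in
the lower screen half. First gazes are aggregated per subject by majority
across trials before the group binomial test; parent-interference
exclusions are an input flag, not a detector. `cohen_kappa()` is provided
for inter-rater agreement on manual coding.

## Sequential design

`simulate_sequential()` characterizes the stopping rule "continue until
`BF >= 3` or `BF <= 1/3`, after a minimum of 25 participants": subject
scores are drawn from `N(effect, 1)`, the BF is recomputed at every look
(default cadence: every participant — the collection cadence is not
specified in the source, so it is configurable), and the first crossing is
recorded. The default test statistic is the same one-sample JZS BF used in
the analysis pipeline, so design simulation and analysis cannot drift
apart. Expected behaviour, asserted as seeded tests: misleading-evidence
rate under the null well below 15% at `max_n = 100`; power above 90% with
median stopping N below 50 at a 1-SD effect; support-for-H1 proportion
monotone in effect size.

## The synthetic generator

`generate_experiment()` emulates the recording conditions of an infant
pupillometry study: 120 Hz binocular streams per trial, subject baseline
diameters `N(4.0, 0.4)` mm, per-sample relative measurement noise
(SD 0.01) with left/right correlation 0.8 (pupil signals are largely
conjugate; blinks hit both eyes simultaneously), Poisson blinks at 0.1/s
lasting 100–300 ms, 1% random dropouts, and scripted AOI-directed gaze
with 3 px jitter. Effects are planted multiplicatively on the baseline —
`pupil = baseline × (1 + amplitude·kernel(t) + noise)` — so percent-change
recovery is exact by construction. The design mirrors the standard layout:
two blocks, 2×2 belief-by-outcome cells, one trial per cell per block,
trial order pseudorandomized per subject but identical across blocks,
congruent side counterbalanced across subjects.

The `paper_like_*` presets use the gamma-impulse kernel (shape 2, scale
400 ms: rise from the effect onset, peak 800 ms later, slow decay) rather
than a boxcar, because pupil dilation is a slow impulse response and
because a transient-only effect cannot simultaneously produce a localized
evidence window and the sustained full-window mean difference that real
event-locked dilations show. The boxcar remains the `synthetic_config()`
default for unit-level exactness tests. Peak amplitude 0.015 relative
change matches the magnitude reported for this paradigm.

What the generator does *not* emulate: slow arousal drift and
luminance-driven pupil responses (noise is white, so 5-s averages are less
variable than in real infants), smooth pursuit, head movement, or
asymmetric monocular loss. Passing tests therefore demonstrate that the
pipeline recovers what it is supposed to recover under controlled
conditions — not that any particular infant dataset will behave as
cleanly.

## Problem sizes and numerical choices

The replication-based tests use the study's own scale — 30 subjects per
dataset, 600-point grids — with 20 seeded replicates for the recovery and
false-evidence checks and 500 replicates per effect size for the
sequential-design characteristics; these sizes give Monte-Carlo rates
stable enough for the asserted bounds while keeping the default test run
at desk scale. Numerical conventions worth restating: strict inequalities
at the percentile and MAD fences; unscaled MAD; half-open windows
everywhere; ties at a grid slot resolved by first sample; BF category
boundaries assigned to the stronger grade; all simulation entry points
take explicit integer seeds and identical seeds reproduce outputs
byte-for-byte (the pipeline manifest records MD5 hashes of every file).

## Known limitations

The BIC approximation standing in for the unspecified "Bayesian LMM"
toolbox reproduces evidence direction and category, not any particular
printed BF value from real data. The rank-based BF is an approximation
flagged in its method name. Blink reconstruction, luminance modelling and
gaze-position artifact regression are out of scope, as is manual video
coding (its inclusion rule is automated here). Real-data inter-rater
agreement obviously cannot be computed from synthetic labels; the kappa
utility is provided for use with human codings.
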