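---
title: "Methods: slow-phase velocity, straight-ahead and search-center estimation under magnetic vestibular stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-phase velocity, straight-ahead and search-center estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvsgaze)
```

## The problem

The static field of a 3T MRI scanner exerts Lorentz forces on ionic
currents in the endolymph of the labyrinth — magneto-hydrodynamic
vestibular stimulation (MVS). A supine subject in darkness develops a
horizontal vestibulo-ocular reflex (VOR): the eyes drift slowly toward
one side and are returned by fast quick phases, producing the saw-tooth
position trace of a vestibular nystagmus. Beyond the reflex, the same
stimulation biases *voluntary* spatial behavior: the center of the
region a subject explores during visual search, and the subjective
straight-ahead (SSA), both shift toward the drift direction, mimicking
the ipsilesional biases of spatial neglect.

`mvsgaze` implements the complete measurement chain for such
experiments: 50 Hz 2D video-oculography is recorded in three phases
(outside the scanner, inside, outside again), each phase containing a
five-point calibration task, a 65 s "looking straight ahead" task (5 s
central light, then darkness), and a 172 s visual search task (six
targets fading in for 5 s each, separated by inter-target intervals that
are a permutation of 5–35 s, closed by a 2 s central light; 140 s of the
task are target-free darkness). Per subject and phase the pipeline
reports:

* `vor_h`, `vor_v` — the median de-saccaded horizontal/vertical eye
  velocity from 5 s after the central light offset to task end (deg/s,
  positive = rightward/upward);
* `ssa` — the median horizontal saccade endpoint in the same window, a
  proxy for where the subject believes "straight ahead" is;
* `search_center` — the mean horizontal saccade endpoint during the
  target-absent epochs of the search task, excluding a 5 s grace period
  after every target offset and the final central light.

## Pipeline and parameters

All tunables live in `analysis_config()`; the defaults are the published
analysis settings.

| parameter | default | role |
|---|---|---|
| `filter_cutoff_hz`, `filter_order` | 10 Hz, 2 | low-pass on raw position |
| `filter_phase` | `"zero"` | forward–backward vs causal filtering |
| `saccade_threshold_deg_s` | 15 | absolute velocity threshold |
| `speed_mode` | `"2d"` | threshold on `sqrt(vx²+vy²)` |
| `grace_after_target_s` | 5 | exclusion after each search target |
| `settle_after_fixation_s` | 5 | exclusion after the central light |
| `desaccade_margin_s` | 0.04 | extra mask around each saccade |
| `blink_margin_s` | 0.1 | margin around tracker signal loss |
| `sw_alpha` | 0.01 | Shapiro–Wilk gate for the log branch |
| `bonferroni_alpha` | 0.05/3 | family-adjusted alpha (three contrasts) |

Stages, in order:

1. **Low-pass filtering.** Second-order Butterworth at 10 Hz, applied
   zero-phase (one forward and one backward pass) so that no phase lag
   biases saccade timing; a causal single-pass variant is selectable
   because the original description does not state the phase handling.
   Runs of invalid samples split the trace and each valid segment is
   filtered independently with odd-reflection padding, so nothing bleeds
   across blinks. The application loop is compiled code because the test
   suite filters hundreds of millions of samples.
2. **Five-point calibration.** Per-axis affine fit (gain, offset) of the
   median raw position in each calibration fixation window against the
   known target locations (center and ±6°/±5° corners). The window is
   the last 1 s of each 2 s presentation — the first second absorbs the
   saccadic approach — pooled over both repetitions. Four of five
   targets must have ≥ 0.5 s of valid data; with five points and an
   unknown tracker projection, anything richer than an affine map per
   axis would be under-constrained.
3. **Blink exclusion.** Validity losses are widened by 100 ms on each
   side; pupil-based trackers distort position estimates around lid
   closure, and the margin is cheap relative to the 55 s analysis
   windows.
4. **Tonic offset compensation.** Per task and phase, the average
   difference between eye position during visible-target fixations
   (last second of each event) and the target positions is subtracted.
   This removes residual calibration drift between tasks; being a pure
   translation it cannot affect velocity estimates.
5. **Two-point differentiation.** `v[i] = (x[i] − x[i−1]) / 0.02`,
   assigned to the later sample (causal), undefined where either
   position is invalid.
6. **Saccade detection.** An event opens at the sample prior to the
   first sample whose speed exceeds 15 deg/s and closes at the first
   sample after speed drops below it. The threshold is applied to the
   2D speed by default: vertical saccades during search must be removed
   from the horizontal slow-phase record too. Events touching invalid
   samples, or still above threshold at the trace end, are discarded —
   their endpoints would be meaningless.
7. **De-saccading.** Samples from onset to offset of every event become
   missing. The pipeline masks an additional 0.04 s (2 samples) on each
   side: zero-phase filtering spreads each quick phase symmetrically
   beyond its threshold crossings, and the unmasked ring lobes otherwise
   bias the median slow-phase velocity upward by roughly +0.09 deg/s at
   typical nystagmus rates (45 quick phases/min). The margin was fixed
   by ground-truth simulation as the smallest value that removes this
   leakage; 0.04–0.10 s perform equivalently.

Every excluded sample is attributed to exactly one rule with fixed
precedence (blink > saccade > target-present > grace > settle), and the
per-phase exclusion log is attached to the `run_pipeline()` output.

## Group statistics

`paired_contrast()` reproduces the study's inferential treatment.
Differences `d = a − b` are tested with a paired t-test when a
Shapiro–Wilk test at α = 0.01 does not reject normality; otherwise the
differences are natural-log transformed and tested against zero with a
one-sample t-test (this is how the strongly skewed inside-phase velocity
differences are handled). The log branch refuses non-positive
differences loudly, naming the offending pairs — silently offsetting
them would change the hypothesis being tested. Effect sizes are Hedges
`g1 = J(df)·mean(d)/sd(d)` with `J(df) = 1 − 3/(4·df − 1)`, and 95%
confidence intervals come from inverting the noncentral t distribution
of the observed statistic. One-tailed tests are used for inside-versus-
outside contrasts (rightward hypothesis for head-first positioning,
leftward for feet-first), two-tailed between the outside phases and for
vertical velocity. With three contrasts per measure the Bonferroni-
adjusted alpha is 0.05/3 ≈ 1.7%.

Within-subject standard errors use Cousineau normalization (subtract the
subject mean, add the grand mean) with the Morey correction
`m/(m−1)` on the per-phase variances. The exploratory regression
`delta_regression()` relates per-subject changes (inside minus the mean
of both outside phases) in the behavioral measures to the change in
slow-phase velocity, pooling experiments; with 17 + 6 subjects it has
F(1, 21) degrees of freedom.

## The synthetic-data generator

`simulate_task()` builds the *true* gaze trajectory as a piecewise
process with ground-truth labels for every sample and event, then
overlays blinks (validity loss), adds white tracker noise, and maps the
result through the inverse of an affine miscalibration so the pipeline
must earn its calibration back.

* **Nystagmus.** In darkness gaze drifts horizontally at
  `slow_phase_velocity_h`; when displacement from the current goal
  exceeds `quick_phase_reset_amplitude` (2°), a resetting saccade
  returns gaze to the goal. Saccades last 40–80 ms with a minimum-jerk
  profile, so a 2° quick phase peaks far above the 15 deg/s threshold
  and detection is unambiguous; no kinematic data were available to fit,
  and the exact profile is immaterial to the measures.
* **Search.** Voluntary saccade goals are drawn at 2 Hz from a 2D
  Gaussian (SD 5°) centered on `attention_center_x` — the parameter the
  search-center measure must recover.
* **Straight-ahead.** The subject re-orients toward `ssa_bias_x` with
  occasional re-fixation saccades (0.5 Hz, goal scatter 1.5°); their
  endpoints, and those of the quick phases, form the cloud the SSA
  estimate summarizes.
* **Targets.** Visible targets are acquired after a latency (0.15–0.35 s
  for full-intensity lights, 1–3 s for fading search targets) and then
  fixated without drift, emulating visual suppression of the reflex.
  Saccade landing error is 0.4° SD.
* **Cohorts.** `simulate_cohort()` adds a stable between-subject offset
  (0.30 deg/s velocity, 3.8° attention/SSA) and independent
  phase-to-phase jitter (0.35 deg/s, 1.8°) to every varied parameter,
  plus signed per-phase effect deltas that reverse under feet-first
  orientation. The decomposition reproduces the per-phase dispersion
  reported in 3T cohorts (≈0.45 deg/s outside-phase velocity SD, ≈4.2°
  behavioral SD) and a paired-difference SD near 2.5° for the
  behavioral measures, the value implied by the published search
  contrast; published diff-SDs vary between measures (≈2.5–5°), and one
  common structure was fixed a priori. `study_simulation()` adds a
  shared standard-normal susceptibility factor scaling each subject's
  stimulation-induced deviation (fully for velocity, 0.6 for the
  behavioral measures), which couples the three measures within
  subjects and produces the cross-measure delta regression.

What the generator does **not** emulate: torsional eye movements,
set-point adaptation of the reflex over minutes, skewed (non-Gaussian)
velocity effect distributions, pupil-size artifacts around blinks
(blinks are pure validity loss), tracker nonlinearities beyond the
affine miscalibration, and head motion. Passing recovery tests therefore
shows the estimators are correct and unbiased under the stated noise
model — not that real recordings are free of these further effects.

## Numerical choices and degenerate inputs

* Sampling is validated strictly (0.02 s ± 1 ns steps); a file at the
  wrong rate is a data error, not a resampling candidate.
* Filter segments shorter than ~9 samples pass through unfiltered.
* Saccade events are discarded (not truncated) when they touch masked
  samples or the trace end.
* Measures are `NA` with a warning — never silently zero — when fewer
  than 5 s of de-saccaded samples or no qualifying saccade endpoints
  remain.
* `paired_contrast()` returns the degenerate null result (t = 0, p = 1,
  g1 = 0) for identically zero differences, and errors for constant
  nonzero ones.
* A calibration with fewer than four usable targets is an error;
  re-running the calibration task is the only sound remedy.

## Estimator accuracy at the default noise level

Two properties of the slow-phase velocity estimator are worth knowing.
First, with a zero-phase filter and strict onset-to-offset masking, the
median de-saccaded velocity is biased upward; the default 0.04 s
de-saccade margin removes this bias (recovery of a 1.5 deg/s drift is
then accurate to better than 0.01 deg/s in expectation). Second, the
estimator's run-to-run spread is set by the tracker noise: 0.1° white
noise at 50 Hz, low-pass filtered at 10 Hz and differentiated, leaves
~1.7 deg/s of velocity noise per sample, and the median over a 55 s
window (minus quick phases, blinks and margins, and including
calibration-gain uncertainty) retains an SD of ≈0.045 deg/s. Single-task
velocity estimates are therefore reproducible to about ±0.1 deg/s
(95% band), a floor inherent to the median-of-two-point-velocities
definition rather than to the implementation; group comparisons average
over subjects and are insensitive to it. The test suite measures
exactly this behavior.

## Problem sizes used in the checks

The packaged tests simulate full sessions (about 13 000 samples per
subject and phase): 100 straight-ahead tasks for velocity recovery,
1 000 randomized short traces for the detection oracle, 200 + 200
seventeen-subject cohorts for power and specificity of the gated
contrasts, and six-subject mirrored cohorts for the feet-first reversal.
`scripts/acceptance.R` simulates one full 17 + 6 subject study and
reports the recovered group means, the feet-first reversal, and the
pooled delta regressions.
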