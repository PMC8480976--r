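# mvsgaze

Oculomotor analysis of magnetic vestibular stimulation (MVS)
experiments.

The static magnetic field of a 3T MRI scanner stimulates the inner-ear
labyrinth of a supine subject (magneto-hydrodynamic vestibular
stimulation). In complete darkness this induces a horizontal
vestibulo-ocular reflex: the eyes drift slowly toward one side and fast
quick phases reset them, producing a saw-tooth nystagmus. The same
stimulation also shifts *voluntary* spatial behavior — the region
explored during visual search and the subjective straight-ahead (SSA) —
toward the drift direction, a neglect-like bias. `mvsgaze` is for
researchers analyzing 50 Hz 2D eye-tracking from such
inside/outside-scanner designs, and for anyone who needs a fully
simulatable, ground-truth-verified nystagmus analysis chain.

## What it computes

Per subject and scanner phase (`outside1`, `inside`, `outside2`):

- **Slow-phase velocity** `vor_h`, `vor_v` (deg/s): the median
  de-saccaded eye velocity of the straight-ahead task. Positions are
  low-pass filtered (2nd-order, 10 Hz, zero-phase), calibrated with a
  five-point affine fit, offset-compensated per task, differentiated
  two-point (`v[i] = (x[i] − x[i−1])/Δt`), and saccades — any run of 2D
  speed above 15 deg/s, from the sample before the crossing to the first
  sample after it — are masked out.
- **SSA** (deg): the median horizontal saccade endpoint while "looking
  straight ahead" in darkness.
- **Search center** (deg): the mean horizontal saccade endpoint during
  the target-free epochs of the visual search task (targets, a 5 s
  post-target grace period, and the final central light are excluded).

Group level: paired phase contrasts with a Shapiro–Wilk normality gate
(log-transformed differences when rejected), Hedges
`g1 = (1 − 3/(4·df − 1))·mean(d)/sd(d)` with noncentral-t 95% CIs,
Bonferroni-adjusted alpha 0.05/3 ≈ 1.7%, Cousineau–Morey within-subject
SEs, and an exploratory regression of behavioral changes on the
velocity change (deltas = inside − mean of both outside phases).

A synthetic-data module (`simulate_task`, `simulate_cohort`,
`study_simulation`) generates saw-tooth nystagmus, search saccades,
fixations, blinks, tracker noise and affine miscalibration with
ground-truth labels, so every stage is verifiable without human data.

## Worked example

```r
library(mvsgaze)

co <- simulate_cohort(6,
  effect = list(slow_phase_velocity_h = c(0, 1.3, 0),   # inside-only drift
                attention_center_x   = c(0, 3.4, 0),    # rightward search bias
                ssa_bias_x           = c(0, 3.7, 0)),
  seed = 42)
m <- cohort_measures(co)
head(m, 3)
#>   subject    phase vor_h   vor_v    ssa search_center n_saccades_used pct_samples_excluded
#> 1     s01 outside1 0.964  0.0294  1.980         -1.98             282                 53.4
#> 2     s01   inside 1.348  0.0205  3.946         -1.48             277                 52.5
#> 3     s01 outside2 0.228  0.0058 -0.127         -2.61             260                 51.3

st <- cohort_stats(m)
st$vor_h$contrasts$inside_vs_outside1
#> vor_h: inside vs outside1: t(5) = 2.269, p = 0.03629 (one-tailed)
#>   g1 [CI95] = 0.780 [-0.066, 1.577], SW p = 0.364
st$search_center$contrasts$inside_vs_outside1
#> search_center: inside vs outside1: t(5) = 3.238, p = 0.0115 (one-tailed)
#>   g1 [CI95] = 1.113 [0.138, 2.038], SW p = 0.334
round(st$vor_h$phase_means, 3)
#> outside1   inside outside2
#>    0.424    1.285    0.147
```

Reading this: the simulated cohort drifted rightward only inside the
scanner (group mean 1.29 deg/s recovered from a true 1.3 deg/s effect),
and the one-tailed inside-vs-outside contrasts on slow-phase velocity
and search center are significant at the 5% level for just six subjects
(the search-center contrast would also survive the 1.7%
Bonferroni-adjusted alpha). `pct_samples_excluded` accounts for every
discarded sample (blinks, saccades, target-present, grace and settling
windows); the full interval log is in `attr(m, "exclusions")`.

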