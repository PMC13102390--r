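---
title: "Age-dependent density regulation of nest excavation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-dependent density regulation of nest excavation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antnest)
```

## The model

Carpenter-ant colonies excavate two-dimensional sand nests whose area grows
with the colony and is repaired after collapses. The package's central
object is a density-regulation digging model in which each ant compares the
current area available per ant, $a = A/N$, with an *age-specific* target
area $a_{age}$ and digs at

$$\frac{da}{dt} = r\left(1 - \frac{a}{a_{age}}\right),$$

rectified at zero (ants do not refill the nest). The colony-level rate is
the sum over the ants present,
$dA/dt = \sum_i r\,(1 - a/a_{age_i})^+$, all ants sharing the one global
density cue. Digging therefore ceases exactly when $a$ reaches the largest
target in the colony: the youngest ants are the last to stop, and in a
growing colony virtually all excavation is performed by young workers,
while after a collapse (which lowers $a$ below everyone's target) ants of
all ages dig.

Two target specifications are provided:

* `target_line()` — the age-dependent model,
  $a_{age} = \max(0,\, 11.22 - 0.032\,\mathrm{age})$ cm² per ant. The line
  is clamped at zero near age 350 d, where it would otherwise go negative.
* `constant_target()` — the age-independent null model with a single
  target $a^\* = 11.6$ cm²/ant. Setting the line's slope to zero makes the
  two models coincide, which is tested.

The basal rate constant defaults to $r = 2.2$ cm² ant⁻¹ day⁻¹. It is an
age-independent ceiling: whatever the age, the per-ant rate lies in
$[0, r]$.

### Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r` | 2.2 | cm²/(ant·day) | basal digging rate at empty nest |
| `target_line()` slope | −0.032 | cm²/day of age | decline of the per-ant target with age |
| `target_line()` intercept | 11.22 | cm² | target of a newly eclosed ant |
| `constant_target()` | 11.6 | cm²/ant | null-model target |
| `maturation_delay` | 10 | days | age before a worker joins the dynamics |
| `queen_area_mean` (`_sd`) | 23.8 (8.0) | cm² | founding area dug by the queen |
| collapse fraction | 0.25–0.30 | — | protocol band for artificial collapses |

## Simulation

`simulate_excavation()` integrates the colony rate over a demographic
timeline (`colony_timeline`). Design choices that matter:

* **Integrator.** The dynamics are integrated with classical RK4 inside
  each step (default `dt = 0.1` d). Explicit Euler is available via
  `method = "euler"`, but at `dt = 0.1` its global error against the
  single-cohort closed form is about 0.4% of the trajectory scale, whereas
  the package's accuracy contract for the simulator is agreement within
  0.1%; RK4 meets it with ~10⁻⁹ to spare at negligible cost. The
  closed-form solution
  $A(t) = N[a_{age} + (a_0 - a_{age})e^{-rt/a_{age}}]$ serves as an
  independent oracle in the tests, including an Euler convergence check.
* **Maturation gating.** A callow worker joins the excavation dynamics —
  both as a digger *and* as a load on the shared density — only at
  `maturation_delay` (10 d). Biologically, callow ants remain on the brood
  pile and neither dig nor exert crowding pressure. This is also what makes
  the delay observable: if freshly eclosed ants counted toward density
  immediately, the already-mature young workers would absorb each
  emergence-induced density drop the same day and the digging response
  would show no lag relative to population growth. The observed census
  (`$n_ants`) still counts every ant alive.
* **Queen founding phase.** In colony-maturation timelines the queen digs
  her founding area (default 23.8 cm²) at a constant rate from
  introduction until the first worker ecloses, so the area on the
  first-emergence day equals the founding area exactly. Modelling this as
  a single-day jump instead would inject an artificial digging-rate
  impulse exactly coincident with the first population-growth event and
  contaminate any digging-vs-growth cross-correlation. After founding the
  queen's own target (she is over a year old) is zero and she ceases
  digging.
* **Cohort ages in fixed-demographics runs.** Fixed-demographics
  experiments last about three weeks and are analysed by cohort age; the
  simulator therefore holds each ant's *target* at its age on day 0
  (`age_advance = FALSE`, the default for `kind = "fixed"`), while
  maturation runs advance ages continuously. With advancing ages a
  three-week experiment's target would drift by ≈ 0.7 cm²/ant, which would
  make the model's collapse recovery structurally incomplete (≈ 85%)
  — contrary to the model's own fixed point, which restores the full
  pre-collapse plateau.
* **Collapses.** A collapse multiplies the current area by
  `1 − fraction`; the per-ant ledger is untouched (the ant really dug that
  area) and re-excavation accrues new credit. The model predicts complete
  recovery of the lost area; empirically colonies stop at about 93 ± 3% —
  a known model–data gap that the package reports but does not tune away.

The per-ant ledger records every increment, enabling
`attribute_by_group()` (queen / young / old at the 56-day threshold —
the young cohort's mean + SD, `young_old_threshold(40, 16)`) and
`per_ant_stats()` (mean, SD, and the area-weighted fraction contributed by
ants that dug within a band such as 5–13 cm²).

## Synthetic data

The generators emulate the study conditions rather than any particular
data set:

* `synth_maturation_colony()` — a founding queen plus workers whose
  emergence days are the crossings of a logistic expectation
  ($K$ uniform on 5–20 workers, $\rho = 0.05$/d, first emergence day 30,
  190-day horizon). Emergence is deterministic given $K$, so one seed
  reproduces a colony byte-for-byte. Deaths are off (mortality was rare on
  this timescale). The logistic's rate and onset are package defaults: the
  underlying study reports no fitted values.
* `synth_fixed_colony()` — a queen plus workers of one cohort, ages drawn
  from the young (40 ± 16 d) or old (171.56 ± 20 d) normal distribution
  truncated at ≥ 1 d.
* `observe_trajectory()` — the photographic record: 1–3-day sampling with
  5% multiplicative Gaussian noise on areas; ant counts are exact.
* `synth_nest_mask()` — rasterized chambers (oriented ellipses) and
  tunnels (thick segments) with per-pixel ground-truth class and
  orientation, label priority chamber > wide tunnel > tunnel.

What the generators deliberately do *not* emulate: demographic turnover at
carrying capacity (no births balancing deaths), brood dynamics, spatially
resolved digging, backfilling, or correlated observation noise. Passing
recovery tests on these synthetic colonies therefore demonstrates that the
estimators recover the model's parameters under the stated noise and
sampling — not that the model is true of any real colony.

One consequence deserves emphasis. Because the logistic demographics
saturate by day ~100–160 and no new workers arrive afterwards, the
youngest ants' targets have decayed to ≈ 8–10 cm² by the end of a 190-day
simulation, so the ensemble's late-time area per ant (≈ 9.7 cm²/ant) and
area-vs-population slope (≈ 9.0 cm²/ant) sit below the ≈ 10.7–11.6 cm²/ant
regulated by real colonies, in which fresh emergences continue near the
end of the observation window. This is a property of the model combined
with purely logistic demographics, not an estimation error; supplying
timelines with continued worker turnover moves both quantities up.

## Inference procedures

* `fit_target_line()` — OLS of per-ant saturation area on cohort age.
* `estimate_r()` — nonlinear least squares (Levenberg–Marquardt) of the
  closed form, estimating $r$ and the per-ant saturation jointly.
* `fit_area_vs_population()` — least squares through the origin
  ($y = 10.71x$ in the study has no intercept); $R^2$ is computed against
  the origin line.
* `rate_series()` — linear interpolation of the irregular samples to a
  daily grid, central differences, 3-day moving-average smoothing (the
  maximum photography gap; configurable).
* `xcorr_lagged()` — per-lag Pearson correlation of the overlapping,
  re-standardised segments, so edge effects do not bias the peak;
  `peak_lag()` breaks exact ties toward the smallest |lag|. Negative lag
  means population change precedes digging. Correlations are computed per
  colony and then averaged (`analyze_colonies()`).
* `area_per_ant_stabilization()` — mean of $A/N$ over the final five
  sampling points, with day 1 at the experiment start or at first worker
  emergence.
* `recovery_fraction()` — cessation is declared when the daily rate stays
  below 0.1 cm²/day for 5 consecutive days; the recovered fraction is
  measured at the end of that confirmation window. (At the window start
  the rate threshold still leaves a gap of ≈ 0.1·τ cm², biasing the
  fraction to ≈ 0.99.)
* `fit_logistic_population()` — symmetric logistic by nonlinear least
  squares, ignoring leading zero counts (they predate the first emergence
  and lie outside the logistic family); a constant series returns the
  constant degenerately.

Plateau detection differs by data type on purpose: `saturation_area()`
applies the rate-threshold rule to smooth model output, while noisy
observed series use the trailing-window mean — a 5% noise level produces
apparent day-to-day "rates" far above any sensible threshold.

## Nest-structure pipeline

Photograph to morphology in five steps, with conventions chosen once:

1. **Registration.** Homographies are estimated with the normalized DLT
   (SVD) from ≥ 4 control points — the frame's support blocks — and images
   are inverse-mapped with bilinear interpolation. Collinear control
   points are rejected.
2. **Binarization.** Current minus initial image (clipped at zero),
   intensity = per-pixel max of the green and blue channels, adaptive
   local-mean threshold (51-px window, offset 0.05 on a [0,1] scale —
   tuned on rendered fixtures; the source protocol states no values), then
   removal of components under 0.5 cm². Backlit excavations are bright, so
   white pixels are excavated area, and `area_cm2()` is the white-pixel
   count times the squared pixel scale.
3. **Skeletonization.** Zhang–Suen thinning; because simultaneous deletion
   can erase compact blobs entirely, any mask component left without a
   skeleton receives its distance-transform maximum as a one-pixel
   skeleton.
4. **Segmentation.** Junction pixels (≥ 3 skeleton neighbours) are removed
   to split branches; fragments shorter than 1 cm merge into the longest
   adjacent branch; then a reconnection pass merges adjacent fragments
   whose mean widths agree within a factor 1.5 and whose axial
   orientations differ by ≤ 45° — a corridor continuing through a crossing
   is one structure, while perpendicular arms of a crossing stay separate
   (a plus-shaped mask decomposes into its two strips). Branch width is
   twice the mean distance-transform value along the path; every mask
   pixel is assigned to its nearest branch by label propagation inside the
   mask, so per-branch areas partition the mask exactly.
5. **Classification and orientation.** Orientation is the principal axis
   of the branch path folded into [0°, 90°], with 0° horizontal and 90°
   aligned with gravity (row index increases downward); folding makes it
   invariant to left-right mirroring. A branch is a *chamber* if its width
   is ≥ 2.0 cm and its orientation ≤ 30°, a *wide tunnel* if its width
   lies in (1.2, 2.0) cm, else a *tunnel*. The width cut-offs reflect the
   ants' 0.8–1.7 cm body length and are configurable.
   `orientation_histogram()` reports area-weighted fractions over 10°
   bins (count-weighting available).

## Numerical choices and degenerate inputs

* Step size `dt ≤ 0.25` d enforced; events and emergences are resolved at
  grid precision.
* Truncations: cohort age draws at ≥ 1 d; observed areas at ≥ 0; the
  target line at 0 cm².
* A colony with no ants has no defined rate (`colony_rate` rejects it);
  per-ant statistics with an empty or all-zero worker ledger signal an
  error rather than returning NaN.
* Cross-correlation at lags with zero-variance segments is masked (NA),
  not forced to zero.
* Collapse fractions outside the 25–30% protocol band require an explicit
  override.

## Problem sizes

The shipped tests and analysis scripts use the study-scale designs: 22
maturation colonies per ensemble, 12 cohort ages × 3 replicates for the
target-line recovery, 20 replicates for the rate-constant recovery, and
nest fixtures of 8–9 primitives on a 40 × 30 cm canvas at 0.1 cm/px.
These sizes keep every analysis to seconds while leaving the Monte-Carlo
error well inside the reported uncertainty bands.

## Known limitations

* The late-time area-per-ant depression under purely logistic demographics
  (above) means ensemble-level regulation summaries depend on demographic
  turnover that the generator does not model.
* The model recovers 100% of collapse losses by construction; the
  empirical 93 ± 3% is reported for reference, not reproduced.
* Orientation is undefined for a single-pixel branch and ambiguous for
  circular chambers (equal eigenvalues); classification then rests on
  width alone.
* The segmentation merges same-width corridors that cross at shallow
  relative angles (≤ 45°) into one branch.
* The binarization assumes backlit photography (excavation brighter than
  sand); front-lit imagery would need an inverted difference.
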