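---
title: "Data-driven biomechanics of cross-country skiing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-driven biomechanics of cross-country skiing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimotion)
```

## The problem

Cross-country skiing performance emerges from whole-body coordination: which
sub-technique an athlete deploys (double pole, kick double pole, diagonal
stride, the grouped G2/G3/G4 skating gears, and glide phases), how compact
their posture is (frontal area is the dominant aerodynamic-drag proxy), how
parallel their skis run (external rotation adds snow friction), and how much
joint power the upper and lower body deliver during each propulsion. Wearable
full-body motion capture makes it possible to record every movement cycle an
athlete performs around a track, and data-driven methods — waveform PCA,
automated sub-technique classification, and exaggerated "avatar"
reconstructions — turn those recordings into interpretable feedback.

`skimotion` implements that analysis chain as a tested pipeline, together with
a synthetic skier simulator so every stage can be exercised and validated
without field recordings.

## Pipeline overview

1. **Trial representation** (`ski_trial`): a 76-point labelled cloud
   (body landmarks plus ski tip/mid/tail and pole points) at a nominal
   240 Hz, five joint-power channels (shoulders L/R, knees L/R, and the
   thorax–abdomen channel, "RTA"), and participant metadata. Interchange is a
   diff-able long-table CSV pair with units in the column names; tables
   without unit-bearing columns are rejected rather than guessed at.
2. **Alignment** (`align_to_pelvis()`): at every frame a proper rotation is
   built from the pelvis landmarks (ASIS pair for the mediolateral axis, the
   ASIS–PSIS midline for forward, vertical completing the right-handed
   triad) and inverted, so heading changes around the track are removed. The
   step is a pure rotation; translation removal is left entirely to
   `reference_to_t12()`, which puts the T12 spinous process at the origin of
   every frame. Because both steps are rigid, their order does not matter —
   asserted as a test.
3. **Segmentation** (`segment_cycles()`): propulsion cycles are delimited by
   local maxima of the left toe's displacement norm exceeding 1 cm. The
   displacement reference is the toe's **trial-mean** position in the aligned
   frame: a fixed reference is the only reading under which an absolute 1 cm
   threshold is meaningful (alternatives — cycle start or previous frame —
   would make the threshold depend on quantities segmentation has not yet
   determined).
4. **Time normalization** (`time_normalize()`): every channel of each segment
   is resampled to 101 evenly spaced points with a shape-preserving piecewise
   cubic Hermite interpolant (PCHIP), which reproduces linear signals and
   endpoints exactly and does not overshoot. Segments shorter than 4 samples
   (below the interpolant's minimum) or longer than 10 s (glide coasting, not
   propulsion) are discarded with a warning.
5. **Cycle database** (`build_cycle_database()`): one row per cycle, columns
   `[time(1–101) | x,y,z × 76 points (101 each) | power upper, lower, RTA
   (101 each)]` = 23,432 features. Upper power is the bilateral shoulder sum
   and lower is the bilateral knee sum, with RTA kept as its own channel; the
   further "knees + RTA = gross lower body" summation is applied at the
   metrics stage, not in the database. The time block carries elapsed time in
   seconds so cadence information survives normalization.
6. **Amplitude normalization** (`amplitude_normalize()`): the time,
   coordinate and power blocks carry different units, so each block is
   multiplied by a single scalar equalizing pooled amplitude ranges; scalars
   are stored and inverted exactly when reconstructions are exported.
7. **PCA** (`fit_pca()`): column-mean-centred SVD of the database (no
   per-column standardization — that is what block scaling is for). At 23,432
   features and thousands of rows the SVD route is much cheaper than forming
   a covariance matrix; a brute-force eigendecomposition oracle verifies
   equivalence in the tests. Components are retained up to 90% cumulative
   explained variance (`retain_components()`).
8. **Classification** (`train_technique_svm()` and friends): a degree-2
   polynomial-kernel SVM on the retained PC scores, trained on a small
   manually labelled subset (the simulator's ground truth stands in for
   manual labels), then applied to every cycle.
9. **Skill statistics** (`anova_per_pc()`): a fixed-effects one-way ANOVA per
   retained PC with the four-level skill factor. A PC is *selected* when
   significant (raw p < 0.05) and *stepwise* — its group means strictly
   monotone from beginner to elite.
10. **Reconstruction** (`mcr_reconstruct()`): the multi-component
    reconstruction `x̂ = x̄ + Σ uⱼ zⱼ` with each selected component at the
    95th percentile of its score distribution when its skill trend is
    positive (5th when negative) for the "elite" avatar, and the opposite
    tails for the "beginner" avatar. `metrics_for_reconstruction()` then
    reports frontal area, ski angle and peak mass-normalized power for both
    avatars side by side.

GNSS lap data are handled separately (`segment_laps()`, `demean_laps()`):
laps are cut at recurrent closest approaches to the start gate, demeaned to
discard positional drift between revolutions, resampled to a common
arc-length parameterization, and averaged into a mean lap.

## Design decisions in detail

**Sign conventions.** PCA signs are arbitrary, but the percentile-tail choice
in the reconstruction presumes fixed signs, so each loading's
largest-magnitude element is made positive. Percentiles use linear
interpolation between order statistics (R's default type 7). Score
percentiles are computed over all cycles rather than per skill group: the
avatars are meant to exaggerate dataset-wide modes of variation, and
group-wise tails would be much noisier at small cohort sizes.

**"Stepwise" formalized.** Strict monotonicity of the four ordered group
means is the only definition that is simultaneously testable, direction-aware
and faithful to the idea of a systematic progression; ties count as
non-monotone. No multiple-testing correction enters the selection rule
(per-PC raw p-values are the reported convention); a Holm-adjusted column is
shown alongside for the reader. Cycles are treated as independent
observations, which pseudo-replicates participants — a real limitation of the
cycle-level design that the package documents rather than silently "fixes".

**Segmentation conditioning.** With white sensor noise, the displacement norm
has a local maximum at nearly every frame, and almost all of them *exceed*
1 cm in height because they ride on a high displacement curve. Peak detection
therefore requires some conditioning: the norm is smoothed with a 0.1 s
centred moving average (an order of magnitude below any plausible propulsion
period), candidate peaks separated by a valley shallower than half the
threshold are merged (one excursion, not two), and a two-pass rule prunes
peaks closer than 0.25× the median inter-peak interval. With zero noise the
recovered boundaries are frame-exact against simulator ground truth.

**Frontal-area rectangles.** The drag proxy sums two frontal-plane
rectangles — mediolateral extent × vertical extent for the upper-body points
and likewise for the lower-body points. A purely anteroposterior extent
contributes no frontal (travel-facing) area; the point-cloud extremes in
all axes still determine which points span each box. Equipment points are
excluded from both groups.

**Ski angle.** The transverse-plane angle of the tip-minus-tail axis against
the forward axis, signed so that external rotation (tips flared outward) is
positive on both sides; a mirror reflection about the sagittal plane flips
the raw sign, which the tests assert. Vertically oriented skis have no
transverse projection and are skipped with a warning.

## The synthetic skier

No kinematic equations exist for the six sub-techniques, so the simulator
composes them from 1–3 harmonics per limb chain with technique-specific
amplitudes and phase offsets (documented invented defaults):
contralateral arm/leg sagittal oscillation for diagonal stride, bilateral
symmetric arm sweeps with quiet legs for double pole, a frontal-plane leg
push with ~14° externally rotated skis for skating (the per-ski angle from
the direction of travel), and near-quiet glides
(the free glide in a tucked posture). The whole body additionally travels
forward at 3 m/s with a slow sinusoidal heading change, exercising the
alignment stage.

The left toe follows a dedicated sagittal loop whose distance from its trial
mean is `sqrt(r0² + r0·r1·cos(φ−π) + r1²/4)` — exactly one mid-cycle local
maximum per cycle, so ground-truth boundaries are well defined and interior
to the trial. Power channels are nonnegative raised-cosine pulses
phase-locked to propulsion.

Skill (rank 0–3, beginner to elite) scales the embedded effects per rank
step: upper power ×1.25, lower power ×1.20, body cross-section ×0.94 (smaller
frontal area), ski external rotation −4°. Cycle periods are log-normal with
mean 1.4 s and 8% CV — deliberately *equal across skill levels*, so the
pipeline's cadence ANOVA should find nothing, mirroring the absence of a
cadence–skill association in field data. Sensor imperfection is i.i.d.
Gaussian coordinate noise (2 mm default) plus a slow linear drift
(0.5 mm/s), both applied last. The technique mix is skill-graded
(diagonal-stride-heavy beginners through double-pole/skating-heavy elites).

What the simulator does **not** emulate: muscle or ground-reaction dynamics,
snow friction, marker occlusion/gaps, non-stationary noise, athlete-specific
anthropometry, or within-trial technique switching (each synthetic trial is a
single technique). Passing tests therefore demonstrate that the pipeline
recovers structure *of the kind the generator embeds* — not that it is robust
to every artefact of field recordings.

## Problem sizes and statistical checks

The validation suites run at sizes chosen to make their statistical checks
meaningful:

* Cohort-level checks (classifier, avatar reconstruction) use 25 trials per
  skill level × 10 cycles (~950 cycles). Twenty-five trials per group is the
  scale at which technique-mix sampling noise averages out; below that, a
  single skill group can draw mostly glide trials and the cohort itself fails
  to embed monotone power, a technique-composition confound that is equally
  present in field data.
* The classifier is trained on a stratified 4% labelled subset (floor of 3
  per class), evaluated on the held-out remainder, with stratified 5-fold
  cross-validation available separately. Macro one-vs-rest AUC comes from
  trapezoidal ROC integration, which the tests tie to the Mann–Whitney rank
  statistic.
* ANOVA calibration uses 1,000 null simulations (rejection rate expected in
  [0.03, 0.07] at α = 0.05); selection (significant **and** monotone) is much
  rarer under the null (~α/12 for four groups) and is bounded, not bracketed.
* Segmentation recovery runs 100 seeded noise-free trials across all six
  techniques; boundary counts must be exact and positions within ±2 frames.
* PCA is checked against a covariance-eigendecomposition oracle at 200×50
  (variances and scores within 1e-6 up to sign) and the full-rank
  reconstruction identity within 1e-8.

## Worked example

```{r example, eval = FALSE}
library(skimotion)

cohort <- generate_cohort(25, seed = 1, n_cycles = 10)
cycles <- lapply(cohort$trials, preprocess_trial)
db <- amplitude_normalize(build_cycle_database(cycles))
model <- fit_pca(db)            # ~90% of variance in the retained set
glance(model)

res <- anova_per_pc(model)      # skill ANOVA per retained PC
sel <- select_pcs_for_mcr(res)  # significant + stepwise components
rec <- mcr_reconstruct(model, sel$pcs, sel$directions)
metrics_for_reconstruction(rec) # beginner vs elite avatar contrasts
autoplot(rec)                   # frontal-plane stick view
```

## Known limitations

* The 76-point registry is a documented default; real capture systems need a
  label remapping (supported) and the binary C3D container is not parsed —
  the long-table CSV pair is the interchange format.
* Cycle-level inference ignores the participant hierarchy (see above).
* The avatar metrics inherit every ambiguity of the underlying selection: if
  no PC is both significant and stepwise, both avatars collapse to the grand
  mean (with a warning) and the contrasts are zero.
* Boundary jitter under noise grows near the flat top of the toe-displacement
  curve; only the noise-free case carries a frame-exactness guarantee.
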