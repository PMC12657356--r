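# skimotion

Data-driven biomechanics of over-ground cross-country skiing from wearable
full-body motion capture, for sport scientists and coaching analysts who want
to turn raw kinematic trials into interpretable, skill-related feedback.

A trial is a 76-point labelled body/equipment cloud at 240 Hz plus five
joint-power channels (shoulders L/R, knees L/R, thorax–abdomen "RTA"). The
pipeline:

* segments **propulsion cycles** at left-toe displacement-norm peaks > 1 cm
  (after per-frame pelvis alignment and T12 referencing),
* time-normalizes every channel to 101 samples (PCHIP) and assembles the
  cycle database `[time | x,y,z × 76 points | power upper/lower/RTA]`
  (23,432 features per cycle, amplitude-normalized per unit block),
* decomposes it by PCA, retaining components up to 90% cumulative variance,
* classifies sub-techniques (double pole, kick double pole, diagonal stride,
  standing/free glide, skating) with a **quadratic-kernel SVM** on the
  retained PC scores trained from a small labelled subset,
* relates PC scores to the four-level skill ordering with per-PC one-way
  ANOVAs, selecting components that are significant (p < 0.05) *and*
  stepwise (strictly monotone group means),
* builds beginner/elite avatars by **multi-component reconstruction**

  x̂ = x̄ + Σⱼ uⱼ·zⱼ,  zⱼ = 95th / 5th score percentile

  (tail chosen by each component's skill-trend direction) and derives
  frontal area (drag proxy), transverse ski external-rotation angle, and
  mass-normalized upper/lower-body power for both avatars,
* reconstructs 3D track topography from 4 Hz GNSS laps (gate-based lap
  segmentation, per-lap demeaning, arc-length averaging).

A synthetic skier simulator (`generate_trial()`, `generate_cohort()`,
`generate_gnss_track()`) embeds ground-truthed, skill-graded effects — more
upper/lower-body power, smaller frontal area, less ski rotation, a
skill-graded technique mix — so the whole pipeline is testable end to end
with no field data.

## Worked example

```r
library(skimotion)

cohort <- generate_cohort(25, seed = 1, n_cycles = 10)   # 100 trials, 4 skill levels
cycles <- lapply(cohort$trials, preprocess_trial)        # align, segment, normalize
db     <- amplitude_normalize(build_cycle_database(cycles))
model  <- fit_pca(db)
model
#> <ski_pca> 936 cycles, 23432 features | 7 PCs retained (90.4% of variance at 90% threshold)

res <- anova_per_pc(model)
sel <- select_pcs_for_mcr(res)
rec <- mcr_reconstruct(model, sel$pcs, sel$directions)
metrics_for_reconstruction(rec)
#> # A tibble: 2 x 5
#>   avatar   mean_area_m2 mean_abs_ski_angle_deg peak_upper_wkg peak_lower_wkg
#> 1 beginner        0.849                   8.90           1.34           1.61
#> 2 elite           0.422                   1.38           7.76           2.34
```

The avatar table reads directly as coaching feedback: the elite-style avatar
occupies ~0.43 m² less frontal area (less aerodynamic drag), keeps its skis
~7.5° more parallel (less snow friction), and produces several-fold higher
peak upper-body and higher lower-body power per kilogram during propulsion.

Classifier, at 4% labelling of the same cohort:

```r
truth <- db$meta$technique
k <- model$retained_k
scores <- model$scores[, 1:k]; colnames(scores) <- paste0("PC", 1:k)
idx <- stratified_label_subset(truth, fraction = 0.04, seed = 2)
svm <- train_technique_svm(scores[idx, ], truth[idx])
evaluate_classifier(svm, scores[-idx, ], truth[-idx])
#> <ski_eval> accuracy 0.914 | macro one-vs-rest AUC 0.986 (6 classes)
```

Fitted objects have broom-style `tidy()` / `glance()` methods and ggplot2
`autoplot()` methods (scree plot, cadence violins, avatar stick views, track
plan view); see the methods vignette (`vignettes/ski-biomechanics.Rmd`) for
the model, its assumptions and the design decisions.

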