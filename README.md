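# turn360

Full-body kinematic analysis of the 360-degree turning task used to
characterise Parkinson's disease (PD) and freezing of gait (FOG). Turning
about a cone with the more affected limb on the inside is a demanding
postural transition; its spatiotemporal, range-of-motion, coordination and
centre-of-mass (COM) signatures separate people with PD from controls and
freezers from non-freezers. `turn360` implements the complete chain from
optical marker trajectories to clinical statistics, for movement
scientists and biostatisticians who want the whole protocol reproducible
and testable:

* **I/O** — the 39-label full-body marker model, a diffable wide-CSV
  trajectory dialect (`frame,LABEL_x,LABEL_y,LABEL_z,...`, metres or mm),
  per-trial metadata tables, and data-quality reports.
* **Preprocessing** — interior-gap cubic interpolation and a zero-phase
  fourth-order Butterworth low-pass at 10 Hz (dual-pass magnitude
  $1/(1+(\omega/\omega_c)^{2n})$; effective −6 dB near 8 Hz).
* **Turn segmentation** — pelvic heading from the ASIS–ASIS vector,
  analysis window from the 10° crossing to the completion of 360° (350°
  analysed, sub-frame refined), and coordinate-based heel-strike/toe-off
  detection.
* **Features** — 34 named turning features (`feature_registry()`): steps,
  duration, step width and inner/outer step lengths, support and stance
  phases, sagittal ROM of hip/knee/ankle/shoulder/pelvis/thorax, toe
  clearances, maximum anti-phase, incline angle, four arm–leg temporal
  coordination parameters Δt, and COM 95%-ellipse area
  ($\pi\,\chi^2_{0.95,2}\sqrt{\det\Sigma}$), AP/ML RMS, path length and
  velocity.
* **Statistics** — univariable screen → VIF filter (> 2.5) → stepwise
  binary logistic regression (LR tests, enter/remove 0.05/0.10, covariates
  age/sex/height/BMI forced; odds ratios, Nagelkerke $R^2$, Firth fallback
  for separation) and empirical ROC with Youden-index cutoffs (AUC ≡
  Mann–Whitney $U/n_1n_0$).
* **Classification** — LR, KNN, naive Bayes, LDA, regularized QDA,
  RBF-SVM and a random forest (Rcpp) under stratified fivefold CV with
  random oversampling strictly inside training folds and nested grid
  search; weighted precision/recall/F1 and normalized confusion matrices.
* **Association** — blockwise stepwise linear models (covariates forced,
  features stepwise on partial-F tests) linking clinical scores (UPDRS,
  PIGD, H&Y, NFOGQ) to turning features; Pearson/Spearman correlations.
* **Simulation** — a kinematic "puppet" that walks a parameterised 360°
  turn and emits ground-truth logs, cohort generators with PD and freezer
  archetypes, planted clinical-score links, and a direct feature-table
  simulator. Every downstream stage is testable without patient data.

See `vignettes/turning-analysis.Rmd` for the models, assumptions,
defaults and limitations, and `analysis/01...05_*.R` for the narrative
workflow (simulate cohorts → extract features → select → classify →
associate), which writes its tables under `results/`.

## Worked example

```r
library(turn360)

# a simulated turning trial with known ground truth (1 mm marker noise)
tr <- simulate_turn_trial(puppet_params(seed = 7))
fv <- extract_features(tr$set, tr$metadata)
round(fv[c("steps_total", "turn_duration", "step_length_inner",
           "step_width", "stance_inner", "max_anti_phase",
           "incline_angle")], 2)
#>       steps_total     turn_duration step_length_inner        step_width
#>             12.00              6.75             38.88             16.47
#>      stance_inner    max_anti_phase     incline_angle
#>             63.96             18.30              6.33
unlist(tr$truth[c("step_length_inner", "max_anti_phase", "incline_angle")])
#> step_length_inner    max_anti_phase     incline_angle
#>              40.0              18.0               6.3
```

The programmed step length (40 cm), peak trunk–pelvis anti-phase (18°)
and lean (6.3°) are recovered through the full filter → segment → detect
→ measure chain. On a simulated two-group cohort the measured features
feed the selection and classification stages:

```r
d <- archetype_effect_sizes("fog")           # moderate freezer separations
tab <- simulate_feature_table(60, d, n_noise = 30, seed = 3)
cv <- run_cv(tab$features, tab$labels, k = 5, seed = 3)
print(cv)
#> <cv_report> 5-fold CV, seed 3
#>   LR   accuracy  73.3 +/-  9.6  precision  73.7  F1  73.3
#>   KNN  accuracy  64.2 +/- 12.4  precision  64.2  F1  63.9
#>   NB   accuracy  70.0 +/-  7.5  precision  70.8  F1  69.8
#>   LDA  accuracy  67.5 +/- 10.8  precision  68.0  F1  67.3
#>   QDA  accuracy  68.3 +/-  8.1  precision  68.7  F1  68.1
#>   SVM  accuracy  76.7 +/- 10.0  precision  77.0  F1  76.6
#>   RF   accuracy  78.3 +/-  9.0  precision  79.0  F1  78.2
```

With moderate (FOG-like) group separations the classifiers land in the
60–80% band with the forest in front — the qualitative pattern reported
for freezer classification — while PD-scale separations push every
classifier above 95% (see `analysis/04_classification.R`, which prints
the four-case accuracy table).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full demonstration pipeline from scratch against the
installed package — cohort simulation, marker-level feature extraction,
feature selection, seven-classifier cross-validation and the clinical
association models — prints a one-line summary per stage, and writes the
JSON result file.
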