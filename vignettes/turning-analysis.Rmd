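---
title: "Full-body kinematics of the 360-degree turn: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-body kinematics of the 360-degree turn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turn360)
```

## The problem

Turning in place is one of the most demanding postural transitions for
people with Parkinson's disease, and the transition during which freezing
of gait is most often triggered. A 360-degree turn about a cone, performed
so that the more affected limb takes the inner steps, stresses exactly the
mechanisms that degenerate with the disease: asymmetric step generation,
trunk-on-pelvis dissociation, whole-body lean control, and temporal
coordination between the upper and lower limbs. `turn360` implements the
full measurement-and-analysis chain for this task from optical marker
trajectories: preprocessing, turn segmentation, a panel of 34 named
kinematic features, stepwise-logistic feature selection with ROC cutoffs,
a seven-classifier cross-validation harness, and blockwise clinical
association models — together with a kinematic "puppet" simulator that
makes every stage testable without patient data.

## Preprocessing

Marker trajectories (39-label full-body set, 100 Hz, metres) are cleaned
in two steps:

* **Gap filling** (`interpolate_gaps()`): interior gaps of at most
  `max_gap_frames` (default 10 frames, 0.1 s) are filled with a natural
  cubic spline per coordinate; longer or boundary gaps stay flagged and
  downstream code refuses them. The order *gaps then filter* is fixed:
  filtering across unfilled gaps would smear the sentinel values.
* **Filtering** (`filter_lowpass()`): a fourth-order Butterworth low-pass
  at 10 Hz applied forward and backward (zero phase). "Fourth order" refers
  to the single-pass coefficients; the dual pass squares the magnitude
  response, so the effective -6 dB point sits near 8 Hz. No cutoff
  correction factor is applied. The coefficients come from the analog
  prototype via the bilinear transform (no filter-design package is used),
  and both passes start from the exact unit-step steady state with
  odd-reflection padding, so constant signals pass bit-exactly and edge
  transients are suppressed. The implementation is verified against the
  closed-form dual-pass response $1/(1+(\omega/\omega_c)^{2n})$ with
  $\omega = 2 f_s \tan(\pi f/f_s)$ at 1, 10 and 30 Hz.

## Turn segmentation

The pelvic heading is the angle between the horizontal left-to-right ASIS
vector and the global X axis, unwrapped cumulatively from the first frame.
The analysis window opens when the cumulative heading passes 10 degrees
and closes when it completes 360 degrees, so 350 degrees of rotation are
analysed; both crossings are refined to sub-frame precision by linear
interpolation for duration measurements. Trials are not re-oriented: the
initial stance defines zero heading, which makes segmentation invariant to
where in the laboratory the subject stood and to either turn direction.

Gait events are detected from marker coordinates alone (no force plates).
A foot is considered in ground contact while its marker sits on its
vertical-minimum plateau — an adaptive threshold at
`min + max(4 mm, 8% of the vertical excursion)`. Heel strike is the onset
of heel-marker contact (the local minimum with near-zero vertical
velocity, reached as the heel descends onto its plateau); toe off is the
offset of toe-marker contact (the toe vertical velocity turning positive).
Same-type events closer than `min_step_time` (0.3 s) are merged, and a
contact that exists from the very first frame is not an event. The
detector is deliberately simple and exposed so it can be swapped; on
simulated turns with 1 mm marker noise it localises more than 95% of
events to within one frame of the programmed schedule.

## The feature panel

`extract_features()` produces 34 named features per trial and averages
element-wise over a subject's repeated trials (`feature_registry()` lists
the canonical names; the registry is extensible, and slots without an
extractor are carried as `NA` rather than guessed).

* **Spatiotemporal.** Steps and turn duration; step width and inner/outer
  step lengths from the perpendicular decomposition of successive
  contralateral heel contacts along the pelvis anterior direction at the
  later contact (during a turn, "forward" must be read off the pelvis, not
  the laboratory); single/double support and stance as percentages of the
  stepping foot's gait cycle.
* **Sagittal ranges of motion.** Hip, knee, ankle and shoulder on each
  side, plus pelvis and thorax pitch. Angles come from marker-level
  segment vectors projected onto the plane normal to the pelvis
  mediolateral axis — not a full three-dimensional Euler decomposition,
  which the 39-marker set cannot support reliably during fast turning.
* **Toe clearance.** Per-step swing maximum of the toe marker above its
  stance baseline (median height over contact frames).
* **Trunk dissociation and lean.** Maximum anti-phase = the largest
  horizontal-plane angle between the inner-to-outer ASIS vector and the
  inner-to-outer shoulder vector; incline angle = the largest angle
  between the base-of-support-to-head-centroid vector and the vertical.
* **Temporal coordination.** Four parameters $\Delta t$: the absolute time
  between an elbow-marker anterior-posterior displacement peak and its
  nearest knee-marker peak, measured in the pelvis-fixed frame (global AP
  is meaningless mid-turn), for the ipsilateral and contralateral pairings
  of the inner and outer arms. Unmatched edge peaks are dropped; values
  are reported as magnitudes, which matches how cutoffs on these
  parameters are quoted.
* **Centre of mass.** 95% prediction-ellipse area
  $\pi\,\chi^2_{0.95,2}\sqrt{\det\Sigma}$ of the horizontal COM cloud, AP
  and ML RMS deviations about the window mean (global axes), path length
  and mean velocity.

Two design choices deserve emphasis because the underlying definitions are
circular or under-determined in the clinical literature:

* **COM estimate.** The default is the pelvis-marker centroid; a weighted
  segment model (pelvis + legs 0.50, thorax + arms 0.42, head 0.08 of body
  mass at the respective marker centroids) is available via
  `com_method = "segments"`. The pelvis centroid was promoted to default
  because the trunk-dominant weighting makes the two nearly
  indistinguishable for horizontal path statistics while the pelvis
  estimate is robust to upper-body marker dropout; full inverse-kinematics
  COM reconstruction is out of scope.
* **Base-of-support reference.** Defined as the midpoint of the two feet's
  heel-toe midpoints at every frame. A stance-configuration-dependent
  definition (only the supporting feet) is discontinuous at every gait
  event, and those jumps interact badly with the zero-phase filter; the
  smooth two-feet midpoint is well defined from markers alone and differs
  from the support centroid by at most half the swing-foot displacement.

## The puppet simulator

Because no public dataset exists for this protocol, the package ships a
parameterised kinematic generator (`simulate_turn_trial()`): a body walks
a circular path about a cone, with footfalls laid down by the exact
perpendicular-decomposition geometry the feature extractors measure, legs
and arms driven by programmed sagittal joint-angle series through the same
segment-vector definitions, trunk yaw dissociation and whole-body lean
applied as explicit offsets, and Gaussian marker noise (default 1 mm, the
magnitude of optical capture). The puppet is *feature-consistent, not
skeleton-consistent*: marker groups are constructed so that each feature
definition recovers its programmed dial, which is sufficient because every
feature is geometric or temporal; no dynamics are simulated.

Ground truth comes in two kinds, recorded in `truth_kind`:

* **programmed** — equal to a dial by construction (step geometry, stance
  timing, clearance, hip/knee/shoulder/pelvis/thorax ROM = twice the
  amplitude, anti-phase = peak yaw offset, incline = lean);
* **emergent** — computed numerically from the noise-free construction
  (ankle ROM, the four $\Delta t$, COM path statistics, steps inside the
  window). Ankle ROM is emergent because the shank rotates over the
  planted foot; it responds to knee flexion amplitude far more than to the
  swing foot-pitch dial. The arm AP peak *leads* its matched leg peak at
  baseline (the shoulder yaw oscillation shifts it), so a *negative*
  `arm_leg_lag` lengthens the contralateral coordination parameters.

Two generator details exist purely to keep truth well defined under
noise: the heading completes its rotation half a step-period after the
final contact and overshoots 360 degrees by 3%, so neither gait events nor
the 360-degree crossing sit on a boundary where one millimetre of noise
could flip a frame.

Default parameters describe an unimpaired older adult: 12 steps at 1.8
steps/s (6.9 s rotation), inner/outer step lengths 40/45 cm, width 16 cm,
stance 65% of cycle, thorax ROM 34 deg, peak anti-phase 18 deg, lean 6.3
deg, toe clearance 3 cm. Group archetypes shift these in the directions
reported for turning impairment — the PD archetype shortens the inner
step, widens the base, lengthens double support, increases thorax ROM and
reduces lean; the freezer archetype additionally shortens the outer step,
increases inner-hip ROM, reduces inner knee/foot-pitch amplitudes (hence
ankle ROM), lengthens the COM path, reduces anti-phase and lengthens the
outer contralateral $\Delta t$. Between-subject standard deviations are a
few centimetres / degrees, chosen to give overlapping but separable
groups. Clinical scores are generated with planted linear links (UPDRS
total/III and PIGD on the outer contralateral $\Delta t$, NFOGQ negatively
on outer step length) whose coefficients are returned in `links`, so the
association stage is checkable.

What the simulator does **not** emulate: soft-tissue artifact and
systematic marker misplacement, freezing episodes, festination, true
dynamics (forces, balance), realistic marker-dropout patterns, and the
compact COM excursion of a tight clinical turn (the puppet's circular
footfall chain yields a wider path than a real cone turn, so COM distances
are larger than clinical values). A green parameter-recovery suite
therefore establishes that the measurement chain is correct, not that it
is robust to every artifact of real capture.

## Feature selection and ROC

The selection chain mirrors standard clinical practice: univariable
logistic screen at p < 0.05; iterative variance-inflation filter dropping
the largest VIF until all are at most 2.5; forward stepwise binary
logistic regression with backward removal on likelihood-ratio p-values
(enter 0.05, remove 0.10 — the classical stepwise defaults; the
likelihood-ratio criterion was chosen over Wald and is exposed), with age,
sex, height and BMI forced in; odds ratios with Wald 95% CIs and the
Nagelkerke $R^2$. Complete separation — routine in small toy examples —
is detected and the final estimates replaced by a Firth-penalized IRLS
refit (implemented in-package) with a warning.

ROC analysis is empirical: thresholds at midpoints between sorted unique
values, AUC by the trapezoid rule (exactly the normalized Mann-Whitney U,
which the tests assert), the cutoff maximising Youden's J with ties broken
toward the midpoint of the class medians, and a p-value against AUC = 0.5
from the normal approximation to U with tie correction. AUCs are reported
un-flipped with a direction flag, preserving the convention in which an
AUC below 0.5 signals that cases score lower.

A note on error control: with per-test entry at $\alpha=0.05$, stepwise
selection over $k$ noise candidates admits at least one with probability
$1-0.95^k$ (23% for five candidates). The suite asserts this near-nominal
behaviour; no claim of familywise control is made, and none should be —
users who need it should lower `p_enter` (e.g. Bonferroni $\alpha/k$).

## Classification harness

Seven classifiers run behind one fit/predict interface: L2-regularized
logistic regression (glmnet, with the inverse-regularization `C`
convention), k-nearest neighbours (FNN), Gaussian naive Bayes and
regularized QDA (implemented in-package; QDA covariances are shrunk as
$(1-r)\Sigma + rI$ on standardized features), LDA (MASS), an RBF-kernel
C-SVM solved as the dual quadratic program (quadprog), and a random
forest (Gini CART with bagging and $\sqrt p$ feature subsampling,
implemented in C++ for the 500-1500-tree grids). Features are z-scored
with training-fold parameters for the scale-sensitive models (LR, KNN,
SVM, QDA); NB, LDA and the forest are fed raw values.

`run_cv()` performs stratified k-fold cross-validation (default five
folds). Inside each training fold the minority class is randomly
oversampled to balance, hyperparameters are chosen by an inner stratified
3-fold grid search that also oversamples only within inner training
folds, and the refit model is evaluated on the untouched test fold — so an
oversampled duplicate can never appear in any test set. The permissive
alternative (oversample once before splitting), which inflates accuracy
estimates, is available behind `oversample_before_cv = TRUE` for
comparison only. Metrics are accuracy and support-weighted
precision/recall/F1 in percent (weighted recall is algebraically identical
to accuracy, which is asserted), plus pooled row-normalized confusion
matrices and a fold-paired t-test (`paired_fold_test()`) for comparing two
classifiers on the same folds. The default grids span the values reported
by grid search for this task: LR C in decades 0.1-1000; KNN k 2-6; QDA
reg\_param including 0.001/0.3/0.5; SVM C including 1e-5/7.6/29.6 crossed
with gamma 0.001-10; forest depth {10, 20, 30} by {500, 1500} trees.

## Association models

`stepwise_linear_blocks()` regresses a clinical score on two blocks:
physical covariates (age, sex as a 0/1 indicator, height, BMI) forced in,
turning features entered by forward stepwise selection with backward
removal on partial-F p-values (0.05/0.10). Covariates are never removed.
No multiple-testing correction is applied across clinical dependents,
mirroring common practice; the same nominal-error caveat as above
applies. `correlate()` wraps Pearson and Spearman tests; which coefficient
to use is left to the analyst rather than auto-chosen by normality tests.

## Numerical choices and degenerate inputs

* Sub-frame refinement applies to the 10/360-degree crossings only; gait
  events stay integer frames.
* Angle series are unwrapped before max-min; ROMs of constant poses are
  exactly zero.
* Small-amplitude ROMs sit at the optical noise floor: the max-min of a
  4-degree pelvis pitch carrying ~0.09 deg/frame of filtered marker noise
  over ~800 frames is inflated by roughly twice 3 sigma (~0.55 deg), so
  recovery of pelvis ROM is only meaningful to ~0.8 deg at 1 mm noise.
* Degenerate inputs fail loudly: zero-length segment vectors, missing
  ASIS samples, heading that never completes the turn, single-class
  labels, constant dependents, non-positive-definite correlation inputs.
* Trials with fewer than two contacts per foot flag the affected features
  as non-computable (`NA` plus a `flags` attribute) instead of guessing.

## Known limitations

* CSV (documented wide dialect) is the only trajectory carrier; the
  binary C3D container is not read or written in this environment.
* The main text of the clinical protocol this package models enumerates
  34 features; the full 36-item list lives in supplementary material that
  is not reproduced here, so the registry ships the 34 canonical names and
  leaves further slots to the user.
* The event detector is coordinate-based and tuned for turning gait at
  100 Hz; stair or shuffling gait would need different thresholds.
* The puppet's limitations listed above bound what simulation-based
  validation can establish.
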