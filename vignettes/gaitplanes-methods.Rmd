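---
title: "Body-axis plane projection and gait indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Body-axis plane projection and gait indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitplanes)
```

## The problem

Markerless smartphone motion capture estimates per-frame 3D positions of
24 body keypoints, each with a confidence score in [0, 1]. The
coordinates are *navel-relative*: the estimator pins the body center to
the origin of every frame and provides no ground plane. Classical gait
metrics (stride length in meters, stance/swing timing from floor
contact) are therefore unavailable. This package implements a
ground-free alternative built entirely from the body's own geometry: a
per-frame anatomical coordinate frame, projection onto body-axis planes,
tolerance-ellipse summaries of each keypoint's scatter, and scalar
indices that screen for three pathological gait patterns — shuffling
(diminished step height), short-stepped (reduced stride), and wide-based
(widened foot placement) — as encountered in parkinsonism and idiopathic
normal pressure hydrocephalus.

## The body-axis frame

Each frame with usable center, shoulder, and hip samples defines its own
orthonormal frame:

* `UF` = unit normal of the plane through the navel and both shoulders;
  `DF` = the same for the hips. Both are oriented anteriorly: the
  left-before-right cross order is anterior for anatomically labeled
  keypoints under the y-up convention, and whenever a nose sample is
  available its offset from the navel resolves the sign explicitly
  (this also makes mirrored recordings project correctly). `DF` is then
  aligned with `UF`.
* `c` (down) = unit vector from the navel to the hip midpoint.
* `f` (forward): the average `(UF + DF)/2` of the two unit normals is
  generally not orthogonal to `c`, so it is Gram–Schmidt orthogonalized
  against `c` and renormalized. Averaging the *unit* normals (rather
  than raw cross products) keeps the shoulder and hip planes equally
  weighted regardless of body proportions.
* `n` (lateral) = `c × f`, sign-fixed toward the labeled right shoulder.

The triple satisfies `f·c = f·n = n·c = 0` to machine precision and is
right-handed (`f × n = c`). Frames with collinear landmark triples (or
opposed shoulder/hip normals) are skipped with a counted reason rather
than interpolated — the estimator provides no basis for imputation.

A navel-relative point `d` projects orthogonally as sagittal
`(d·f, −d·c)`, coronal `(d·n, −d·c)`, axial `(d·n, d·f)`. These axis
conventions put "up" on the sagittal/coronal y axis (so the heel's
vertical amplitude is a sagittal y extent) and "forward" on the axial
y axis. Coronal projections are computed for completeness but no index
is defined on them: knee and ankle flexion is sagittal, and lateral foot
placement is easier to read on the axial plane.

Lower-limb keypoints (hips, knees, heels, toes) are normalized by the
mean leg length (navel→hip + hip→knee + knee→heel, averaged over sides
and frames); all other keypoints by the mean upper-body length
(navel→neck center + neck center→head center, with the neck center the
shoulder midpoint and the head center the ear midpoint). This makes the
outputs dimensionless (leg = 1) and invariant to the capture app's
arbitrary length unit: projected tracks are unchanged (to 1e-6) under
any rigid motion or global rescaling of the input, properties the test
suite asserts directly. Arm keypoints are projected but excluded from
every index.

## Tolerance ellipses

Each keypoint's 2D scatter on a plane is summarized by a tolerance
ellipse at level 0.75: center = sample mean, shape = unbiased sample
covariance `S`, boundary at Mahalanobis radius
`r = sqrt(2 · F⁻¹(0.75; 2, n − 1))`, semi-axes `r·sqrt(λᵢ)` from the
eigen-decomposition of `S`. This radius convention matches the classical
data-ellipse routine for bivariate samples (the test suite cross-checks
the fitted boundary against `car::dataEllipse`); the large-sample
chi-square convention `r = sqrt(χ²⁻¹(0.75; 2)) ≈ 1.665` is available via
`method = "chisq"`. Degenerate (collinear) clouds yield a flagged
ellipse with `b = 0` instead of an error. Exactly circular fits use
tilt 0 as a deterministic tie-break.

Two conventions are deliberately configurable because the field's usage
is ambiguous:

* **Area.** The default is `π·a·b` with `a`, `b` the semi-axes; the
  literal "major axis length × minor axis length × π" reading
  (`4π·a·b`) is available as `convention = "full"`. No published value
  depends on the choice.
* **Heel amplitude mode.** "y-axis width of the heel plots" can mean
  the ellipse's vertical extent (`2·r·sqrt(S_yy)`, outlier-robust,
  the default) or the raw max−min of the points (`mode = "raw"`).

## The seven indices

With per-side quantities averaged over left and right (per-side values
are always returned, so any other aggregation can be recomputed):

| index | plane | definition | cutoff (flag) |
|---|---|---|---|
| hip angle range | sagittal | angle at hip ellipse center subtended by knee-ellipse major-axis endpoints | < 30° |
| knee angle range | sagittal | same with knee center and heel ellipse | < 45° |
| heel vertical amplitude | sagittal | vertical extent of heel ellipse | < 0.1 |
| foot angle | axial | angle between right and left heel→toe center vectors | — |
| heel outward shift | axial | signed lateral heel-center offset from hip center | > −0.08 |
| toe outward shift | axial | signed lateral toe-center offset from heel center | > 0.18 |
| leg outward shift | axial | heel shift + toe shift (exact identity) | > 0.1 |

"Outward" is away from the midline: the per-side sign is +1 on the
right and −1 on the left, so a negative heel shift means the heels
track inside the hip keypoints (the usual normal-gait geometry — hence
the negative cutoff). Flags use strict inequalities in the printed
direction; values exactly at a cutoff do not flag, and an index that
cannot be computed yields an absent (`NA`) flag rather than `FALSE`.

Cohort-level detectability of each (gait feature, index) pair is
summarized by ROC AUC with a DeLong 95% CI (delegated to `pROC`;
the test suite verifies the AUC against an exhaustive pairwise-comparison
oracle), sensitivity and specificity at the cutoff, and the odds ratio
with a Woolf logit 95% CI, Haldane–Anscombe-corrected when a cell is
zero. For any 2×2 table the identity
`OR = [sens/(1−sens)]·[spec/(1−spec)]` holds exactly
(`or_from_sens_spec()`), which is also how the package's acceptance
script checks published screening tables for internal consistency.

## The gait simulator

No public recordings exist in the app's format, so the package includes
an articulated kinematic simulator used by every end-to-end test. It
reproduces the measurement protocol — two laps of a 1-m-diameter circle
per direction at 30 fps — with:

* pelvis traveling at `cadence · step_length / 60` m/s along the circle;
* feet alternating stance (fixed in the world) and swing, with a
  cycloidal forward ramp and sinusoidal vertical bump peaking at
  `step_height`; lateral offsets of `±stance_width/2`; toes placed by
  outward foot rotation plus a lateral toe offset;
* knees from two-link (thigh/shank) inverse kinematics, bending forward;
  hip height is 0.82 of thigh+shank, a slightly flexed posture
  consistent with walking a tight circle, which keeps the leg within
  reach over the whole cycle (violations raise an explicit error);
* a rigid upper body with sinusoidal lateral sway, and static hanging
  arms (arms are excluded from all indices);
* isotropic Gaussian positional noise and Beta-distributed confidence
  scores with a configurable sub-threshold dropout rate, exercising the
  0.7 score filter;
* full determinism under the `seed` parameter, without disturbing the
  caller's RNG state.

Baseline ("normal") magnitudes are engineering defaults, not
measurements: cadence 100 steps/min, step length 0.60 m, heel lift
0.15 m, stance width 0.10 m, foot rotation 10°, thigh = shank = 0.45 m.
The heel-lift default deserves a note: the *heel* rises substantially
during swing in normal gait (toward 15–25 cm as the knee flexes), unlike
the toe, whose clearance is a few centimeters — and the heel keypoint is
what the vertical-amplitude index tracks. The presets alter exactly the
defining feature of each pattern: shuffling divides heel lift by 10,
short-stepped divides step length by 2.5, wide-based triples the stance
width and increases foot rotation to 30° with a 0.10 m toe offset.
The hip keypoints sit 0.16 m from the midline — app "hip" estimates sit
wide of the true joint centers — which with the 0.12 m navel drop gives
a leg length of exactly 1.10 m, and places the normal preset's heel
shift near −0.10 (inside the −0.08 cutoff) and the wide-based preset's
near 0 (outside it), bracketing the published operating point.

`simulate_cohort()` adds between-subject variability as multiplicative
log-normal jitter (SD 0.06 on the log scale, truncated at ±2 SD to keep
every subject kinematically feasible) on step length, step height,
stance width, cadence, sway, and foot rotation. Case severity
interpolates geometrically between the normal and pathological presets
(`effect = 0` gives controls, `effect = 1` the full preset).

What the simulator does *not* emulate: perspective or camera effects
(coordinates are emitted body-relative, as the estimator outputs them),
arm swing, double-support weight shifts, pelvis vertical bounce,
estimator-correlated noise (noise here is white), and the freezing,
festination, spastic, or ataxic patterns, which lack a quantitative
definition. Tests passing on simulated data therefore validate the
geometry and statistics of the pipeline, not the clinical performance of
the cutoffs on real recordings.

## Numerical choices and problem sizes

* Frame skipping needs ≥ 2 usable frames; ellipse fitting needs ≥ 3
  points per keypoint and side.
* Degenerate distal ellipses in an angle-range computation give an
  angle of 0 with a warning; a proximal center coinciding with a
  major-axis endpoint gives 180°.
* The end-to-end test cohorts use 30 + 30 subjects per pathological
  pattern, at which size the matching index reaches sensitivity and
  specificity ≥ 0.9 at the published cutoff. The null-calibration
  cohort (`effect = 0`) instead uses 600 subjects per group with
  single-lap recordings: the null AUC's sampling SD is approximately
  `sqrt((n₁+n₂+1)/(12·n₁·n₂))`, so 600 per group (SD ≈ 0.017) makes the
  asserted |AUC − 0.5| < 0.05 band a three-sigma check rather than a
  coin flip, which it would be at 30 per group (SD ≈ 0.075).
* Ellipse coverage calibration uses 10,000 bivariate-normal draws,
  giving a binomial SE of 0.004 against the ±0.02 assertion band.

## Known limitations

* Left/right aggregation is the arithmetic mean of sides; the source
  clinical literature does not state its aggregation, so per-side values
  are always reported alongside.
* The confidence-score model is a stationary Beta distribution;
  real estimator confidence is motion- and occlusion-dependent.
* Recordings mixing both walking directions carry
  `direction = "unknown"` at the recording level; the simulator attaches
  its per-direction segment table as an attribute instead.
* Temporal gait parameters (cadence, cycle time) are estimable from the
  projected tracks in principle but are out of scope here, as are
  coronal-plane indices.
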