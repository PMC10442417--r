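---
title: "Monocular 3D mouse pose lifting: models, priors, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monocular 3D mouse pose lifting: models, priors, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouselift)
```

## The problem

A single fixed camera watches a laboratory mouse in its home cage. A 2D
detection stage (outside the scope of this package) produces, per video
frame, twenty named keypoints with confidences. The task of `mouselift` is
the *lifting* step: recover the full 3D posture — joint angles and bone
lengths of an articulated skeleton — from those 2D keypoints alone, and
downstream of it, gait measurements from the reconstructed trajectories.

Monocular lifting is ill-posed: any point may slide along its viewing ray
without changing its projection, and overall size trades off against
distance to the camera. The package resolves this the way model-based
human-pose systems do, with three ingredients:

1. a **kinematic chain** — 18 spherical joints, 54 joint angles `a`, 17
   bone lengths `l`; forward kinematics `T(a, l)` maps parameters to 3D
   joint positions;
2. **Gaussian-mixture priors** — a pose prior `p_p` over canonically
   normalized 3D poses (5 components) and a shape prior `p_s` over
   bone-length vectors (7 components), entering as negative log-likelihood
   penalties;
3. a **fixed-distance constraint** — the root joint is pinned to a known
   distance from the camera center, removing the scale/depth ambiguity.

The energy minimized per frame is

$$E(a, l) = \sum_i \lVert \mathrm{proj}(T(a, l))_i - k_i \rVert^2
  + \lambda_p\, p_p(a) + \lambda_s\, p_s(l),$$

the squared pixel distance between projected joints and the observed
keypoints $k_i$, plus the weighted priors.

## The skeleton

The chain has a spine (lower/middle/upper spine, nose), a two-point tail,
and four three-segment limbs; the root is the lower spine, the natural
pelvis anchor since it sits at the midpoint of the hips. The ears are
tracked keypoints but are deliberately not part of the chain: they are
reconstructed as fixed offsets on the head segment and never contribute
residuals to the optimizer. All joints are spherical and parameterized as
axis-angle rotation vectors — three parameters each, singularity-free near
the identity, with rotations composed down the tree. Units are millimetres
for 3D quantities, pixels for 2D, radians for angles.

```{r skeleton}
sk <- build_default_mouse_skeleton()
sk
count_dof(sk)
```

The rest pose runs the spine along +x (nose forward), dorsal side up (+z),
limbs splayed 45 degrees at the girdles and hanging vertically below —
matching the frame in which poses are normalized for the prior.

## Pose normalization and the priors

Poses entering the pose prior are canonically aligned: the base of the
neck (upper spine) is translated to the origin, the vector to the middle
of the spine is rotated onto +x and scaled to unit length, and the
residual roll about x is fixed by placing the hip midpoint in the y = 0
half-plane on the ventral (−z) side. Roll disambiguation is a design
choice the alignment rule itself leaves open; anchoring the hip midpoint
belly-down is stable because the hips sit below the spine line in every
physiological posture. Normalization is idempotent and invariant to rigid
motion and uniform scaling of the input, which the test suite checks
property-style.

Both priors are full-covariance Gaussian mixtures fit by
expectation–maximization: k-means++ initialization under a caller-supplied
seed, best of 5 restarts by log-likelihood, and a 1e-6 eigenvalue floor on
every covariance. The floor matters: normalized poses have six pinned
coordinates (the origin and the unit-spine constraint), so their sample
covariance is rank-deficient by construction; flooring keeps every density
evaluation finite without changing the informative directions. With a
fixed seed the fit is bit-reproducible.

The penalty is the mixture negative log-likelihood. Because Eq.-style
energies are additive, the optimizer reports the reprojection term and the
two weighted penalties separately, and the terms sum to the total exactly.

**Pose prior space.** The energy writes `p_p(a)` as a function of the
angles, but the prior is *constructed* from aligned and scaled 3D poses.
The package follows that construction: `p_p` is evaluated on the
normalized forward-kinematics coordinates of the current pose — a
deterministic function of the angles, so the energy is still a function of
`(a, l)`. The alternative (a mixture directly over angle vectors) was
considered and rejected because the normalization step is meaningful only
in coordinate space and the coordinate construction is what the prior's
training data (multiview reconstructions) naturally provides.

## The optimizer

The decision variables are the 54 angles, the 17 bone lengths in log space
(positivity for free), and two ray parameters that move the root on the
sphere of the configured radius (`fixed_distance`) about the camera
center — the literal reading of the fixed-distance constraint.

Minimizing a sum of squared pixel residuals plus mixture NLL penalties is
awkward for least-squares solvers: the NLL is a single scalar whose
square-root residual carries almost no curvature information. The package
instead uses the standard majorize–minimize treatment of mixture priors:
at each outer round the component responsibilities are frozen at the
current iterate, which bounds the NLL from above by a
responsibility-weighted sum of Mahalanobis quadratics (the EM bound, tight
at the current point). Each quadratic whitens into ordinary least-squares
residual rows, stacked under the pixel residuals with weight
$\sqrt{\lambda/2}$, and the inner problem goes to Levenberg–Marquardt
(`minpack.lm`). Every outer round can only decrease the true energy; the
recorded energy trace is the true energy at round boundaries and is
non-increasing. Eight outer rounds are the default; in the synthetic
harness the energy is stationary well before that.

Initialization is deliberately simple: rest-pose angles, the root placed
on the back-projected ray of the lower-spine observation at the fixed
distance, body yaw from a coarse-to-fine 1-D search about the optical
axis, bone lengths at the shape prior's mixture mean. Sequences warm-start
each frame from the previous solution. Keypoints below the confidence
floor (default 0.05) are excluded from the residual rather than
down-weighted — occluded detections carry confidence 0, and a binary
include/exclude contract is the simplest defensible one.

**Penalty weights.** The defaults are `lambda_pose = 1e-2` and
`lambda_shape = 1e-1`. The pose weight is kept small so the prior steers
the depth ambiguities without pinning the posture to the mixture; the
shape weight is larger because a single view constrains bone lengths only
weakly (a bone may lengthen while tilting out of the image plane with
little projected change, so without a firm length anchor the lengths drift
and take the depth estimates with them).

## What the synthetic harness shows — and what it cannot

Real evaluation data (multiview recordings with manual annotations) are
not shipped with the package, so correctness is established on synthetic
scenes where the ground truth is known exactly:

* **Cohort generator.** Bone-length tables emulate a CT-measured colony
  structured into four body-size groups (scale factors 0.8–1.2 around the
  stock adult skeleton, 3% within-group coefficient of variation) — the
  kind of spread a weight-by-sex grouping produces.
* **Gait pose generator.** A diagonal (trot-like) gait: sinusoidal
  limb-angle oscillation of ±30 degrees with fore/hind coupling, a phase
  parameter running the cycle, and optionally a small angle jitter. The
  pose-prior training set uses 200 poses across the cycle with 0.005 rad
  jitter: the jitter models measurement noise of a multiview
  reconstruction around the canonical cycle, and its scale sets the
  softness of the prior's off-manifold covariances.
* **Scene renderer.** Projects forward-kinematics keypoints through known
  pinhole cameras (a top-down and two side cameras, 350–450 mm from the
  cage center), adds i.i.d. Gaussian pixel noise, and occludes a chosen
  fraction of keypoints by zeroing their confidence.
* **Trace generator.** Sinusoid + drift + noise at a known stride
  frequency for the gait module.

All generators are pure functions of their parameters and a seed.

The recovery harness lifts 50 single-view scenes at the true camera
distance. Under noiseless observations the pooled median per-joint error
is around a millimetre; the error is strongly structured: spine joints
recover to a few tenths of a millimetre while distal limb joints (wrist,
ankle) carry several millimetres, because a distal joint's depth is fixed
only through the prior's correlations and the bone-length estimates, and a
small length error is amplified into depth error when a bone lies close to
the image plane. With 2 px pixel noise and 25% occlusion the median error
grows to a few millimetres with convergence above 90% — the regime the
method is actually designed for, where the priors carry more of the
weight. These numbers quantify the *intrinsic* monocular ambiguity left
by this prior family on this pose family; they say nothing about 2D
detector errors, real anatomy, or non-gait postures, which the synthetic
generators do not model.

Triangulation, by contrast, is essentially exact (sub-micrometre on
noiseless three-view scenes) — which is why multiview reconstruction
serves as the ground-truth source for the pose prior in the first place.

## Gait analysis choices

The foot trace is detrended with a centered 1 s moving average
(edge-padded) before any spectral step; the window is long against a
stride (3–10 Hz) and short against postural drift. The aggregate stride
frequency is the dominant magnitude-spectrum peak searched in [1, fps/2)
Hz with parabolic interpolation around the peak bin; restricting the band
at 1 Hz keeps residual drift out, and a peak is only accepted if it rises
at least 4x above the band's median magnitude (a flat or noise-only trace
raises a no-gait error instead of returning a number). Stride length is
belt speed divided by frequency. Individual strides are successive peak
times, with peaks required to clear a prominence of 0.25 trace standard
deviations and a separation of half the aggregate period — both defaults
exposed as arguments. Lengths are durations times belt speed, exactly, and
outliers beyond 2.3 standard deviations from the mean (computed in a
single pass, not iteratively) are flagged rather than deleted.

At 24 fps the 3–10 Hz physiological band sits below Nyquist, and the
harness checks that 3 and 10 Hz synthetic traces are both resolved
without aliasing at that rate.

## Numerical details and degenerate inputs

* Rotation vectors use a second-order series below 1e-8 radians, keeping
  the rotation map smooth through the identity.
* Triangulation refines the homogeneous DLT solution by damped
  Gauss–Newton and never accepts a step that increases the reprojection
  error; near-parallel viewing rays (under 1 degree) set an
  ill-conditioning flag.
* Coincident spine points make pose normalization (and hence the pose
  prior) undefined and raise a degenerate-pose error.
* A frame whose usable keypoints fall below 4 raises an error inside
  `optimize_pose`; `lift_sequence` converts that to a flagged failure and
  continues.
* `exclude_outliers` with zero variance excludes nothing.
* Calibration files are snapped to the nearest proper rotation on load
  (file precision leaves ~1e-9 residuals); reflections are rejected.

## Problem sizes

The shipped tests and the acceptance script use: 200 training poses for
the pose prior, an 80-specimen cohort for the shape prior, 50 recovery
scenes per noise condition, 10-second traces at 24–30 fps for gait, and
10–50 Monte-Carlo trials for the stochastic camera checks. These sizes
were chosen so the whole suite runs in minutes on a laptop while keeping
the Monte-Carlo noise on every reported quantity well inside its
acceptance margin.

## Known limitations

* Per-frame optimization with warm starts only; no temporal smoothness
  term, no multi-animal association.
* The pose prior is only as good as its training distribution; postures
  far from it (rearing, grooming) will be pulled toward the mixture.
* Distal-joint depth is the weak spot of single-view lifting here, as the
  error anatomy above shows.
* The 2D detection stage is out of scope: the package consumes keypoint
  files and never touches pixels.
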