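---
title: "Measuring sitting posture with a low-cost multi-camera rig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sitting posture with a low-cost multi-camera rig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posture3d)
```

## The measurement problem

Sitting posture in adolescents is usually quantified through a small set
of named angles between anatomical landmarks: head flexion (HF), neck
flexion (NF), the cranio-cervical angle (CC), the cervico-thoracic angle
(CT), trunk flexion (TF), head and neck lateral bending (HLB, NLB), and
head and trunk axial rotation (HR, TTR). Laboratory motion-capture
systems measure these well but are expensive and immobile. A portable
alternative is a small rig of synchronised low-cost CMOS cameras
(640x480 px) mounted on two cross-bars flanking the seated subject,
photographing reflective skin markers. `posture3d` implements the whole
measurement chain for such an instrument, together with the statistics
used to establish whether a new instrument of this kind is valid and
reliable, and a synthetic scene generator that plays the role of the
physical rig so every step can be tested without hardware.

## Camera model and calibration

Each camera is a projective pinhole: a 3x4 matrix $P$ mapping
homogeneous world coordinates (mm) to pixels,
$\lambda (u, v, 1)^\top = P\,(x, y, z, 1)^\top$. $P$ is estimated from a
calibration object — a board of 25 dowels of varying heights carrying
reflective spheres with known world coordinates — by the normalised
direct linear transformation (DLT): both point sets are centred and
isotropically scaled (mean distance $\sqrt{3}$ and $\sqrt{2}$
respectively), the stacked linear constraints are solved by SVD, and the
result is denormalised. There is no iterative refinement, so calibration
is deterministic; with 25 well-spread non-coplanar fiducials the linear
solution is already exact to floating-point precision on noiseless data,
and reprojection RMS at 0.5 px image noise settles near 0.45 px.

Two numerical conventions matter downstream:

* **Canonical storage.** $P$ is only defined up to scale, so it is
  stored with unit Frobenius norm and with the sign fixed so that a
  known in-front point has positive projective depth. Equality tests
  and round-trip checks are then well-defined.
* **Degeneracy guard.** If the two smallest singular values of the DLT
  design matrix are within a ratio of 0.99 the configuration does not
  determine a camera (coplanar fiducials being the canonical case) and
  calibration aborts with a degenerate-geometry error rather than
  returning garbage.

Pixel coordinates have their origin at the top-left, $u$ rightward, $v$
downward, pixel centres at integers. World units are millimetres with
$Z$ vertically upward.

## Triangulation

A marker seen by $k \ge 2$ calibrated cameras is reconstructed by
linear homogeneous triangulation: each observation contributes the two
rows $u\,p_3^\top - p_1^\top$ and $v\,p_3^\top - p_2^\top$, and the
point is the null-space vector of the stacked system (SVD). When more
than two cameras see a marker, all of them are used in one least-squares
problem. A marker seen by fewer than two cameras is reported
`untriangulated` and propagates as missing into the angle layer — a
trial is never aborted by partial visibility, mirroring how a practical
capture session must behave.

The accuracy of triangulation depends strongly on the angle between the
two lines of sight. Near 0 deg (two cameras on the same bar, marker far
away) and near 180 deg (a dorsal midline marker such as the T5 spinous
process seen from bars on either side) the component of the error along
a camera's viewing ray grows like $1/\sin\theta$. `line_of_sight_angle()`
exposes the diagnostic, and `make_los_pair()` builds two-camera scenes
at a prescribed angle so the effect can be measured: at 0.5 px noise the
median depth error of a 160 deg pair is about four times that of a
75 deg pair. Rays meeting below 0.5 deg attach an ill-conditioned flag
to the result rather than failing, since such captures can still carry
usable information in the other coordinates.

## Landmarks, local frame, and the nine angles

Three derived points are built from the raw markers: the *Cyclops*
(midpoint of the canthus markers), the *OCI* (midpoint of the tragus
markers) and the mid-trochanter point. The subject-local frame is
$\hat{X}$ from the left to the right greater trochanter projected onto
the horizontal plane, $\hat{Z}$ the world vertical, and
$\hat{Y} = \hat{Z} \times \hat{X}$ pointing anteriorly. All nine angles
are computed with normalised dot products (the dot-product-cosine rule),
with signs assigned from cross products against the frame axes; lateral
and rotational angles are negative to the subject's left.

Several of the classical verbal definitions are ambiguous about their
reference axis, and the package resolves them so that a neutral,
symmetric posture scores zero:

* **HLB** is measured against the horizontal through the OCI (a level
  head scores 0 deg). Reading the definition literally against the
  vertical would give 90 deg at neutral; that convention remains
  available via `hlb_reference = "vertical"`.
* **TTR** is measured against the posterior axis (a symmetric torso
  scores 0 deg); `ttr_reference = "anterior"` gives the 180-deg-neutral
  reading.
* **TF** is signed negative when C7 lies posterior to the
  mid-trochanter point, which places typical relaxed sitting around
  -13 to -22 deg, in line with the published range for this angle.

`nlb_sagittal_corrected()` addresses a genuine fault in the
frontal-projection definition of NLB: when lateral bending co-occurs
with sagittal neck flexion, projecting the C7-to-OCI segment onto the
frontal plane shortens the segment but not its lateral offset, so the
projected angle overstates the bend (5 deg of lateral bend at 30 deg of
flexion projects to about 5.8 deg). The corrected variant measures the
elevation of the segment out of the sagittal plane,
$\arcsin(v \cdot \hat{X} / \lVert v \rVert)$, which equals the projected
angle whenever there is no sagittal flexion and recovers the true bend
exactly otherwise.

Trial validation compares each computed angle against configurable
acceptable ranges (`acceptable_ranges()`). The defaults are wide
envelopes around published ranges for seated adolescents (HF 40-110,
CC 120-180, ...), wide on purpose: the gate exists to catch
reconstruction blunders, not to reject unusual posture. Missing angles
are reported distinctly from out-of-range ones.

## Agreement and reliability statistics

Validity of a new instrument against a reference and test-retest
reliability are quantified with four standard tools, all implemented at
full precision with rounding only at presentation:

* **Bland-Altman.** Bias $d$ = mean of paired differences, $s$ = their
  sample SD ($n-1$), limits of agreement $d \pm 1.96 s$, width, and
  $CV = s/d$ (undefined at $d = 0$). Published agreement tables round
  half away from zero to two decimals and difference the *rounded*
  limits to obtain the printed width; `format_agreement()` reproduces
  exactly that convention (an unrounded width can differ from the
  printed one by 0.01).
* **Lin's CCC**, $2 s_{xy} / (s_x^2 + s_y^2 + (\bar{x}-\bar{y})^2)$
  with $n$-denominator moments, penalising location and scale shift
  that Pearson's $r$ ignores; its 95% CI uses Lin's asymptotic standard
  error on Fisher's $z$ scale.
* **One-way random-effects ICC.** Table-style reliability data report
  exactly two variance components — between-subject and error — so the
  one-way model is the natural choice. The ANOVA estimator is used,
  with the unbalanced-data effective group size
  $n_0 = (N - \sum n_i^2/N)/(a-1)$, negative component estimates
  truncated at zero, and the F-distribution confidence interval. On
  balanced data it coincides with REML (verified against `lme4` in the
  test suite). Coefficients are labelled with the Landis-Koch bands,
  boundary values belonging to the lower band.
* **Pearson's r** via `stats::cor()` behind precondition checks.

## The synthetic scene generator

The generator stands in for the physical world and defines the study
conditions under which the pipeline is validated:

* **Rig.** Five cameras on two cross-bars at $x = \pm 2400$ mm (three
  right, two left), heights near 1.3 m, all aimed at the trunk centre
  $(0, 0, 850)$; focal length 1000 px, the value implied by a 6 mm lens
  on a 6 um-pixel 640x480 sensor. The exact bar geometry of any
  particular physical rig is not published; this layout satisfies the
  constraints that matter — side-flanking bars, every default-scene
  marker visible to at least two cameras, a dorsal midline point
  subtending more than 150 deg across the bars and a frontal point
  60-90 deg within one bar.
* **Calibration object.** A 5x5 grid at 150 mm pitch with dowel heights
  drawn uniformly in 50-400 mm (deterministic per seed); the height
  spread makes the plane-fit residual ~100 mm, far from coplanarity.
* **Mannequin.** A rigid 14-marker torso template placed in seven poses
  (rotations about the vertical and 15 deg tilts about horizontal axes
  through the hip centre), so inter-marker distances are invariant by
  construction.
* **Student postures.** Forward kinematics build the 9-marker set so
  that the sagittal angles equal the requested targets exactly; lateral
  bend, head rotation and trunk rotation are applied as forward
  rotations whose resulting frontal/transverse angles are returned as
  ground truth. Default anthropometry (trunk 450 mm, neck 120 mm, head
  110 mm, inter-tragus 140 mm, inter-canthus 62 mm, inter-trochanter
  300 mm) sets the scale of the scene; only angle recovery is ever
  asserted.
* **Capture.** Projection plus i.i.d. Gaussian pixel noise, the
  simplest model of manual marker-clicking uncertainty; occlusion is a
  per-marker visibility mask, and out-of-frame projections are emitted
  as missing. A single frame per trial is modelled (analysis of a real
  capture selects one frame from the synchronised burst).
* **Marker images.** `render_frame()` draws anti-aliased disks on a
  dark background and `detect_centroids()` recovers them by threshold,
  connected components (EBImage) and intensity-weighted centroids —
  sub-0.1 px on isolated disks, within 0.25 px across a full 9-marker
  view from an oblique camera. From a straight-side camera the two
  canthi nearly superimpose and merge into one blob; detection flags
  these ambiguous rather than guessing.
* **Repeated measures.** `simulate_repeated_measures()` draws
  $y_{ij} = \mu + b_i + e_{ij}$ from specified variance components.

What the generator does **not** emulate: lens distortion, skin-motion
artefact, soft-tissue palpation error, imperfect synchronisation,
lighting variation, or postural sway between repeated trials. Passing
the synthetic suite therefore demonstrates the correctness of the
algorithms and the internal error budget of the geometry, not the
field accuracy of any physical instrument.

## Problem sizes and observed behaviour

The validation suite and the acceptance script rerun the pipeline at
these scales, chosen to keep Monte-Carlo error well below the asserted
margins: 1000 randomised noiseless scenes for geometric
self-consistency (worst-case 3D error stays below $10^{-9}$ mm and all
nine angles match an independently coded oracle to $10^{-9}$ deg); 50
noisy captures at 0.5 px for end-to-end recovery (median absolute
errors near 0.19, 0.26 and 0.06 deg for HF, NF and TF — comfortably
inside half a degree); 500 replicates of 24 subjects x 3 occasions at
variance components 56.75 and 8.86 for ICC recovery (mean estimate
~0.85 against a generating ratio of 0.865, the small downward shift
being the known truncation bias of the ANOVA estimator at this design
size); and 100 noise draws per line-of-sight condition.

## Known limitations

* The one-way ICC is the only reliability model offered; two-way models
  are out of scope because the target reporting format carries exactly
  two variance components. Published coefficients computed on
  unbalanced data may differ from the two-component ratio by ~0.02.
* The DLT estimates a single projective matrix per camera; intrinsics
  are not separated from extrinsics and no distortion terms exist, so
  accuracy with strongly distorting optics would be limited by the
  model, not the implementation.
* Marker identity is given by the placement model, never solved;
  temporal tracking across frames is out of scope.
* `cv = s/d` is reported signed by default; tables that print positive
  CVs for negative biases can be reproduced with `cv_absolute = TRUE`.

## A worked example

```{r, eval = FALSE}
td <- tempfile(); dir.create(td)
sim <- run_simulate(td, n_trials = 3, noise_px = 0.5, seed = 7)
cal <- run_calibration(file.path(td, "calibration_object.csv"),
                       file.path(td, paste0("calib_cam", 1:5, ".csv")),
                       out_dir = file.path(td, "out"),
                       camera_ids = paste0("cam", 1:5))
angles <- run_pipeline(sim$trial_paths,
                       file.path(td, "out", "cameras.csv"),
                       file.path(td, "placement_student.yaml"),
                       out_dir = file.path(td, "out"))
angles[, c("trial", "HF", "NF", "TF", "pass")]
```
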