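---
title: "Frame-localisation OPT: models, algorithms and design choices"
author: "flopt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-localisation OPT: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flopt)
```

# The problem

Optical projection tomography (OPT) images translucent biological samples in
the 1–10 mm range by acquiring projection images while the sample rotates
through a full turn, and classically inverts the projections with the
inverse Radon transform (filtered back-projection, FBP). That inverse
assumes perfect, uniform circular motion about a fixed axis. Real OPT stages
— especially inexpensive ones, or samples embedded in slippery gels — drift
laterally, precess, and jitter, and the Radon reconstruction develops severe
ghosting under even slight systematic drift.

This package implements a frame-localisation reconstruction: bright
fiducial beads embedded in the sample are tracked across frames, the actual
rigid pose (rotation $R$ and translation $T$) of the sample at every frame
is recovered from two-view epipolar geometry, and the volume is
reconstructed by back-projecting every frame along its pose-corrected rays.
The package also contains the geometric acquisition simulator and the
evaluation protocol used to validate the method against the FBP baseline.

# Geometry and camera model

All modules share one convention, stated in `?flopt`:
the world frame is right-handed with $Z$ the vertical nominal rotation
axis; the camera sits at $(0, d, 0)$ (stand-off $d$) looking down $-Y$,
with image $u$ along $+X$ and $v$ along $+Z$; pixels are 0-based with
centres at integer coordinates; a pose maps sample coordinates to world
coordinates, $X = R s + T$.

OPT optics are approximately telecentric, but the two-view relations
$p'^T E p = 0$ and $E = K^T F K$ need a pinhole model to be well posed. The
compromise is a *weak-perspective* pinhole: the default focal length (and
stand-off) is 50 sample diameters (`defaultCamera()`), used consistently for
rendering *and* pose recovery. With a 64-voxel phantom this means
$f = d = 3200$ world units and a field of view of about $0.7^\circ$ — the
relations stay exact while the perspective distortion across the sample is
below 2%.

# The simulator

`makeTestcardVolume()` embeds two orthogonal grayscale testcards in a cubic
volume — one in the horizontal mid-plane (the plane all quantitative
metrics are computed on) and one in the orthogonal vertical plane,
superposed by maximum along their shared line. The built-in procedural
testcards (`testcardEllipses()`, a nested-ellipse phantom, and
`testcardGrid()`, a checker/grating card) mean nothing has to be
downloaded; any two grayscale images can be substituted to reproduce other
test scenes.

`motionSequence()` generates per-frame poses
$\mathrm{jitter} \circ \mathrm{drift}(k) \circ \mathrm{precession}(k)
\circ R_\mathrm{axis}(k\,\Delta\theta)$: $n$ equal nominal steps over
$2\pi$ (128 by default), constant-velocity lateral drift in world units per
frame, a rotation-axis tip of `precessionRate` radians per frame about the
camera's horizontal axis, and optional Gaussian per-frame jitter. With all
corruption terms zero the sequence is exactly the ideal Radon geometry, so
both reconstructions then operate on literally the same data.

`renderProjection()` computes pinhole line integrals of the posed volume by
ray casting with trilinear sampling (compiled code; sampling interval 0.5
voxel by default), and adds the beads as analytic Gaussian spots of
$\sigma = 1.5$ px. Ground-truth poses and exact projected bead centres are
attached to every simulated stack.

Bead placement (`placeBeads()`) matters more than it looks. Under rotation
about the vertical axis a bead's image height is nearly constant, so two
beads at similar heights will inevitably cross in the image plane at some
angle, merging their spots and corrupting any tracker that has no
appearance cues. The default placement therefore stratifies bead heights
(one bead per $Z$ stratum, at least 3 bead sigmas apart) — standard
practice in marker-based tomographic alignment — besides the 4-sigma
minimum 3D separation; `minAxialSep = 0` restores plain uniform-in-ball
rejection sampling. An optional bead-free slab around the measured
mid-plane (`excludeSlab`) keeps bead streaks out of the quantitative
comparison plane; the evaluation pipelines use a 4-voxel half-width. Bead
amplitude defaults to 100 with testcard projections peaking near 45, i.e.
"bright punctate" fiducials that dominate their local background.

What the simulator does *not* emulate: physical optics (depth of field,
scattering, absorption), detector noise by default (Poisson and read noise
are available but off), refractive-index effects, and non-rigid sample
deformation. Passing tests therefore demonstrate geometric correctness and
noise-robustness of the pipeline down to tracking noise of a few
hundredths of a pixel, not photometric realism.

# Bead tracking

`detectBeads()` finds $3\times3$ local maxima above
$\mathrm{median} + 8\,\mathrm{MAD}$ of a high-pass filtered frame (the
broad box-blur background removes the smooth testcard projection), then
refines each candidate by least squares against a Gaussian spot on a
*locally linear background* within a window of half-width $3\sigma$. The
linear background term is essential on textured frames: a constant-offset
model lets the local intensity gradient drag the centre by several tenths
of a pixel. Pixels nearer to a different candidate peak are excluded from
each fit, so neighbouring spots do not bias one another. Fits whose sigma
leaves $[0.75, 1.5]\times$ the expected value are rejected (this removes
texture maxima), and duplicates within $2\sigma$ are merged keeping the
lower residual. On noise-free renders the detector is accurate to
0.01–0.1 px (worst cases are beads passing over sharp texture edges).

`linkTracks()` links detections frame-to-frame by greedy mutual nearest
neighbours with constant-velocity prediction; links beyond `maxStep` (10 px
default) are rejected, a missed bead may be re-acquired within twice that
for up to 2 frames, and tracks covering less than 80% of frames are flagged
unusable (`usableBeadIds()`). Global assignment is unnecessary because
rotation steps are small ($2\pi/128$) and bead heights are distinct.

# Pose recovery

For every adjacent frame pair the pipeline is: correspondences $\to$
normalised eight-point fundamental matrix (Hartley conditioning, rank-2
enforcement) $\to$ essential matrix $E = K^T F K$ with singular values
projected to $(s, s, 0)$ $\to$ SVD decomposition into the four candidate
$(R, \pm T)$ pairs $\to$ continuity selection: the candidate minimising the
element-wise squared difference of the augmented $[R\,|\,T]$ matrices
against the previous pair's pose (the first pair is compared against an
ideal step composed from a-priori knowledge of the nominal rotation angle),
with positive-depth counts only breaking near-ties. With 5–7 shared beads
the linear eight-point system is under-determined, and the essential matrix
is instead estimated by Levenberg–Marquardt least squares on the Sampson
residuals over the 5-DOF $(R, \hat t)$ parameterisation, initialised from
the reference pose — an approximation documented as such; 8+ beads are the
recommended operating point.

## The narrow-field degeneracies, and what the package does about them

Two structural problems dominate this geometry and drove the design:

**Bas-relief ambiguity.** With a $0.7^\circ$ field of view, a small camera
tilt and a lateral translation produce almost identical image motion. With
exact correspondences the eight-point solution is exact; with realistic
tracking noise (0.02–0.1 px) it is strongly perturbed. The package
therefore refines each selected candidate as a *sample step*
$dP = (dR, dT)$ with the camera orbit built in: the camera-relative
transform is $M = G\,dP\,G^{-1}$, whose translation is the large,
calibration-determined orbit of the camera about the rotation axis plus
the small sample translation. Camera tilt can then no longer trade against
an arbitrary baseline. The refinement minimises pixel-unit Sampson
residuals plus weak anchors of the step rotation to the a-priori nominal
step and of the step translation to the previous estimate. Anchor weights
scale with the measured residual noise (so they vanish for noise-free
tracks and act as a Bayes-consistent smoothness prior otherwise); the
assumed priors are ~1.5 mrad of step-rotation deviation and ~1 world unit
of translation change between consecutive steps — the latter deliberately
loose so stage drifts of a few pixels per frame remain recoverable.

**Baseline-parallel drift.** A constant lateral drift along world $X$ is
parallel to the camera baseline at *every* rotation angle, so it is
invisible to the epipolar constraint per pair — it is exactly the scale
direction. Two mechanisms recover it. `fixTranslationScale()` pins relative
per-pair scales through rigidity of the triangulated bead cloud and the
absolute gauge through the full-turn trajectory: accumulated translations
are affine in the global scale, and an erroneous scale leaks the camera
orbit into the trajectory as a circular component that is orthogonal to a
linear drift over a full turn (gauges based on the nominal step baseline or
on triangulated depth are retained as alternatives). For noisy tracks,
`refineTranslations()` uses the absolute information the relative chain
never touches — where the bead constellation is imaged: with rotations held
fixed and the bead map triangulated, the whole translation trajectory
(constant-velocity model, plus a rigid map-offset gauge that a quarter-turn
separates from drift) is re-estimated from the bead reprojection residuals
by a small global least squares. This is deliberately *not* bundle
adjustment: structure and rotations are never jointly re-optimised.

`smoothChain()` finally regresses the recovered chain onto the smooth
acquisition model (per-step rotation vectors linear in the frame index;
translations proportional to it), removing the random-walk accumulation of
per-pair noise. It erases recovered per-frame jitter, so it is applied by
the reconstruction pipelines (where sub-pixel absolute pose matters) and
not by `recoverPoseChain()` itself.

## Recovery-error metric

`matrixRecoveryError()` implements the element-wise percentage difference
$|x - y| / (2(|x| + |y|)) \times 100$, averaged over the 9 rotation or 3
translation elements, with $0/0 := 0$. The measure is *relative per
element*: an element whose true value is exactly zero scores 50% for any
non-zero recovered value, however tiny. `poseRecoveryGrid()` therefore
evaluates the quantities the factorisation actually produces — the
camera-relative relative rotation and the unit translation direction — and
its grid uses non-zero precession and drift everywhere so that matrix
elements are structurally non-zero (the remaining first-pair artefact,
where two elements of the very first step are exactly zero by
construction, contributes about 0.04% to a 127-pair mean). By default the
grid feeds exact projected bead centres, testing the decomposition
machinery directly; `tracks = "detected"` runs the full detection pipeline
instead.

# Reconstruction

`backprojectFrame()` is a voxel-driven gather (compiled): every grid voxel
is carried through the frame's pose and the camera to a pixel position and
gathers its bilinearly interpolated intensity — algebraically equivalent to
smearing each pixel along its ray realigned by the inverse pose, without
ray-spacing artifacts. `floptReconstruct()` optionally Ram-Lak filters each
frame along the detector axis first (frequency-domain $|\omega|$,
zero-padded to the next power of two at least twice the width) and scales
the sum by $\pi / (2n)$ — angles cover $2\pi$, so every line is measured
twice. The default grid is a centred cube of side 1.5 detector widths at
one-pixel voxels. `radonReconstruct()` is the standard parallel-beam FBP
over the nominal equal-step angles — deliberately ignorant of the true
motion, because that is the baseline being compared against.

# Evaluation protocol and problem sizes

All quantitative comparisons happen on the phantom's testcard mid-plane
versus the matching reconstructed slice: `msePercent()` (images jointly
normalised to $[0,1]$ by the reference's range, mean squared difference
$\times 100$), `absDiffHistogram()` (50 bins over $[0,1]$, with a
low-deviance mass utility) and `correlation2d()` (Pearson on flattened
pixels). `comparePipelines()` runs one acquisition end to end through both
reconstructions; `driftSweep()` iterates it over drift magnitudes and
seeds; `poseRecoveryGrid()` measures R/T recovery over a precession × drift
grid.

The package's standard desk-scale study conditions, chosen once:

* **Pose-recovery grid**: 128 frames over $2\pi$, 8 beads in a 20-unit
  radius, $64^2$ detector; precession rates equal to total axis tips of
  1°, 2° and 4° per acquisition; drift velocities equal to total drifts
  of 2, 4 and 6 px (larger drifts would carry beads off the 64-px
  detector); 5 bead-placement seeds per cell.
* **Zero-drift parity**: the $64^3$ procedural testcard, 8 beads
  (4-voxel bead-free slab), 128 frames, full detect–link–recover–
  reconstruct pipeline, $96^3$ reconstruction grid.
* **Drift sweep**: drift magnitudes 0, 0.5, 1 and 2 px/frame. At 128
  frames these would mean up to 256 px of total drift — no realistic
  detector accommodates that — so the sweep protocol uses 32 frames over
  $2\pi$ on a 160 × 64 detector with the camera aimed at the drift
  midpoint (total drifts up to 62 px). That is ample to collapse the
  Radon baseline while the frame-localised reconstruction tracks the
  motion.

These sizes keep a full acceptance run in minutes on one CPU while leaving
every effect being measured far above its numerical noise floor.

# Numerical choices

* Orthonormality tolerance $10^{-6}$ on every pose; nearest-rotation
  re-orthonormalisation (polar decomposition via SVD) after decomposition
  and composition chains.
* Rank-2 and equal-singular-value enforcement by SVD projection; Hartley
  conditioning before the linear eight-point solve; degeneracy declared
  when the design matrix's 8th singular value falls below $10^{-12}$ of
  the largest.
* Ties in candidate selection broken by cheirality only within $10^{-9}$
  of the objective.
* TIFF round-tripping quantises to the 32-bit integer grid centre so that
  write → read → write is byte-identical.
* Ray casting at 0.5-voxel steps, trilinear volume interpolation,
  bilinear frame interpolation in the gather.

# Known limitations

* Per-frame jitter translations/rotations are recovered only up to the
  smoothing filter: reconstruction-grade chains assume smooth motion.
* The 5–7 bead path depends on a good a-priori initialisation; with a
  badly wrong nominal step it can converge to the twisted pair.
* Absolute depth (stand-off direction) rests on the calibrated camera
  geometry; an error in the calibrated stand-off rescales recovered
  translations proportionally.
* Texture-based (feature-descriptor) correspondence is intentionally out
  of scope; only bead-like fiducials are supported.
* The comparison metrics assume the reconstruction is already registered
  to the phantom (no registration is performed).
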