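# flopt — frame-localisation reconstruction for optical projection tomography

Optical projection tomography (OPT) images translucent biological samples
(1–10 mm: embryos, organoids, cleared tissue, expanded gels) by acquiring
projection images while the sample rotates through a full turn, then
inverting them with the inverse Radon transform (filtered back-projection,
FBP). FBP assumes perfect, uniform circular motion; real stages drift,
precess and jitter, and the reconstruction fills with ghosting artefacts —
worst in inexpensive OPT rigs and in soft, slippery gel-embedded samples.

`flopt` reconstructs such acquisitions robustly by *recovering the actual
pose of every frame* from 5+ bright fiducial beads tracked across the
image stack, and back-projecting each frame along its pose-corrected rays.
It is aimed at OPT instrument builders and imaging methodologists who need
motion-robust reconstructions or a fully controlled simulation bench for
tomographic alignment algorithms.

## The method

Corresponding bead positions $p$, $p'$ in two adjacent frames of a rigid
scene satisfy the epipolar constraint

$$p'^{\,T} E\, p = 0, \qquad E = K^T F K,$$

with $F$ the fundamental matrix, $E$ the essential matrix and $K$ the
camera intrinsics. For each adjacent frame pair the package estimates $F$
by the normalised eight-point algorithm (a Sampson least-squares path
covers 5–7 beads), calibrates it to $E$, and factorises $E = [T]_\times R$
into the four candidate transformation pairs $(R, \pm T)$. The physical
candidate is chosen by continuity,

$$\min_n \left\| [R_n \,|\, T_n] - [R_{n-1} \,|\, T_{n-1}] \right\|^2,$$

against the previously selected pose (the first pair is compared against
an ideal step composed from a-priori knowledge of the nominal rotation
angle). Candidates are then polished in a turntable-aware
parameterisation that removes the narrow-field bas-relief degeneracy,
translation scale is fixed through the rigidity of the triangulated bead
cloud plus the full-turn trajectory, and the chained per-frame poses drive
a voxel-driven filtered back-projection. The classical FBP baseline
(`radonReconstruct()`) and a complete geometric acquisition simulator
(testcard phantoms, bead placement, drift/precession/jitter motion models,
sinograms) are included, along with the evaluation suite (MSE,
pixel-difference histograms, image correlation, drift sweeps, pose
recovery error grids).

See the methods vignette (`vignettes/flopt-methods.Rmd`) for the models,
the degeneracy analysis and every numerical design choice.

## Worked example

A drifting acquisition (128 frames over $2\pi$, 0.05 px/frame lateral
drift — about 6 px over the scan), reconstructed both ways and compared
against the phantom's testcard plane:

```r
library(flopt)

volume <- makeTestcardVolume(64)                    # procedural testcard phantom
cam    <- defaultCamera(64)                         # weak-perspective OPT camera
beads  <- placeBeads(8, sampleRadius = 24, seed = 3, excludeSlab = 4)
model  <- motionModel(nFrames = 128, driftVelocity = c(0.05, 0, 0))

result <- comparePipelines(volume, beads, model, cam)
cat(sprintf("flOPT  correlation: %.3f   MSE: %.2f%%\n", result$corrFlopt, result$mseFlopt))
cat(sprintf("Radon  correlation: %.3f   MSE: %.2f%%\n", result$corrRadon, result$mseRadon))
```

```
flOPT  correlation: 0.970   MSE: 1.46%
Radon  correlation: 0.705   MSE: 5.75%
```

`comparePipelines()` simulated the acquisition, detected and linked the
beads with sub-pixel Gaussian fitting, recovered the per-frame pose chain
from the epipolar decomposition, and reconstructed. The frame-localised
reconstruction correlates at 0.97 with the ground-truth testcard — the
same quality it reaches with zero drift — while the drift-blind Radon
baseline has already degraded to 0.70 after only 6 px of cumulative drift.
The MSE is the mean squared pixel difference (in percent of the reference
dynamic range) on the same plane.

The step-by-step interface does the same thing explicitly:
`simulateAcquisition()` → `detectBeads()`/`linkTracks()` →
`recoverPoseChain()` (+ `smoothChain()`, `refineTranslations()`) →
`floptReconstruct()`. A thin command-line front-end over YAML configs is
in `inst/scripts/flopt-cli.R` (`simulate`, `reconstruct`, `sweep`).

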