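---
title: "ctbiopsim: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctbiopsim: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctbiopsim)
```

`ctbiopsim` is a headless simulator of CT-guided needle biopsy training. A
real trainer of this kind couples a torso phantom, a tracked biopsy needle
and a head-mounted display; this package implements everything in that
pipeline that is computation rather than hardware: the CT volume and its
geometry, fiducial-marker pose estimation, synthesis of a CT slice
containing the virtual needle, the procedure command loop, and the Likert
analytics used to assess face validity. This vignette documents the models,
the parameters that matter, and what the tests do and do not demonstrate.

## Coordinate conventions

The world frame is LPS (left–posterior–superior) in millimetres, the
native frame of DICOM patient coordinates. Voxel indices are 0-based and
continuous; `origin` is the world position of the centre of voxel
(0,0,0), and the voxel-to-world map is the exact affine
`world = origin + axes %*% (index * spacing)`. Axial slices are planes of
constant world z, which requires an identity direction matrix for scan
simulation (the phantom generator always produces one; oblique volumes are
rejected by the scan layer rather than silently resliced).

Hounsfield sampling is trilinear, with points beyond the outermost voxel
centres returning −1024 HU (air) — the natural fill for CT background.
Labels are never interpolated: hit detection uses the label of the voxel
containing the tip (nearest-neighbour), so a label can never bleed half a
voxel outward.

## The synthetic torso phantom

The canonical input is a synthetic phantom rather than a real scan, so
every test is reproducible from code. It emulates a contrast-enhanced
abdominal CT with geometric primitives: an elliptic-cylinder body
(semi-axes 170 × 120 mm) with a subcutaneous fat shell, a posterior
midline spine column and 6 mm rib bands every 30 mm of z, two kidney
ellipsoids, a 10 mm-radius aorta cylinder anterior-left of the spine, and
spherical soft-tissue lesions that carry integer labels. Tissue plateaus
are air −1000, fat −90, soft tissue 40, bone 700, contrast blood 200 and
lesion 60 HU; Gaussian noise of 10 HU SD (a typical abdominal-CT noise
magnitude) is added under the configured seed, so generation is
bit-reproducible.

The default grid is 128 × 128 × 96 voxels at 3 mm isotropic spacing —
torso-scale coverage (384 × 384 × 288 mm) at a resolution where the full
generation-and-session cycle stays interactive. The two default targets
encode the two difficulty levels of the training task: a **beginner**
pararenal node (world (70, 20, 0) mm, radius 8 mm) reachable by a straight
anterior path crossing only fat and soft tissue, and an **expert**
para-aortic node ((27, 35, 0) mm, radius 6 mm) whose surface touches the
aorta, so an approach must respect an adjacent critical vessel. The rib
bands deliberately leave the mid-plane (z ≈ 0) clear so the canonical
approach plane is not shadowed by bone.

What the phantom does *not* emulate: organ texture and anatomical
variability, respiratory motion, beam hardening or any reconstruction
artifact. Tests passing on the phantom therefore demonstrate geometric and
bookkeeping correctness, not clinical realism of the imagery.

## Fiducial pose estimation

The tracked quantity is the pose of a planar chessboard fiducial. Real
corner *detection* is out of scope — the package's
`simulate_observation()` replaces it, projecting the board's interior
corners through an ideal pinhole camera, dropping a configurable occluded
fraction, and adding isotropic Gaussian pixel noise under a seed. What the
package does implement is the *estimation* math:

1. a Hartley-normalized DLT homography from board (x, y) to image points;
2. decomposition `K⁻¹H = λ[r₁ r₂ t]`, with the nearest rotation (SVD) to
   `[r₁ r₂ r₁×r₂]` and the sign of λ fixed so the board sits in front of
   the camera;
3. Gauss–Newton refinement over an axis-angle rotation delta and the
   translation, minimizing reprojection RMSE, at most 50 iterations,
   stopping when the improvement falls below 1e-10 px. The Jacobian is
   numeric (forward differences, step 1e-6); with at most a few dozen
   corners the cost is negligible and the refined pose matches the
   generating pose to well below 1e-6 in the noise-free case.

Estimation needs at least 4 visible non-collinear corners; collinearity is
detected from the singular values of the centred board points. Lens
distortion is omitted (no calibration data to model), and there is no
temporal filtering — each frame is solved independently.

Defaults: needle marker 5 × 7 squares of 10 mm, phantom reference board
8 × 10 squares of 15 mm, camera 1920 × 1080 px with fx = fy = 1400 px —
plausible for a headset RGB camera at roughly 0.5 m working distance. At
that range, with 64 corners and 0.5 px corner noise, the Monte-Carlo
median errors are about 0.5° rotation and 0.5 mm translation, comfortably
inside the 1° / 2 mm envelope the accuracy tests assert.

The needle is rigidly calibrated to its marker: the tip frame has +z along
the shaft toward the tip, and the default `marker_to_tip` is a pure
translation of the shaft length along −z (marker on the hub). Shaft
defaults are 150 mm length and 3 mm diameter — introducer-scale rather
than fine-needle-scale, chosen so the rendered needle is resolvable at the
default 1 mm rendering pixel.

## Simulated CT slices

`render_slice()` resamples an axial slab onto a pixel grid covering the
volume footprint. Each output pixel is the mean over an s × s × s midpoint
grid of sample points spanning the pixel footprint and slab thickness
(s = 3 by default), which models the partial-volume effect: a pixel
half-filled by metal reports an intermediate HU. Sample points inside the
needle capsule — the cylinder of the shaft diameter with a hemispherical
tip cap, extending from the tip back along −axis for the *inserted*
length — take the needle HU (3071, the 12-bit metal clamp). Only the
inserted segment is rendered: the inserted length is found by marching
from the tip toward the hub in 0.5 mm steps until the sampled HU crosses
−500 (the body surface); a needle held in air renders nothing. No
beam-hardening or streak artifacts are modeled — the needle is a clean
metal-density object.

Slabs are contiguous 3 mm by default (thickness = spacing), indexed from
the first voxel plane; `slice_for_needle()` returns the slab whose centre
is nearest the tip z, with exact ties broken toward the lower index — an
arbitrary but fixed and documented rule. The laser-line z is the slab
centre, mirroring a scanner's positional light guide. The default
rendering pixel is 1 mm (typical of abdominal CT reconstructions) even on
the 3 mm phantom grid.

Discretization: the midpoint rule quantises a boundary pixel's capsule
fraction to multiples of 1/s³. At s = 3 a refinement to s = 6 can still
move a capsule-boundary pixel by a few hundred HU (a ~1/27 fraction jump
spans ~112 HU of the 3031 HU tissue-to-metal contrast, and boundary pixels
can shift by 2–3 samples); from s = 6 to s = 12 the largest observed
change on the fixture scene is ~30 HU. The test suite asserts this
convergence behaviour. For quantitative boundary work use s ≥ 6; s = 3 is
a speed/fidelity compromise adequate for training imagery.

## The procedure session

The session state machine mirrors the trainer's command set: `select`
arms the needle tool, `move_needle` (only after `select`, mirroring the
device's own ordering) updates the tracked pose, `scan` selects the slab
under the tip, renders the slice, and evaluates the hit rule, and
`next`/`previous` navigate slabs. Sessions are driven either step-by-step
or from a plain-text script; replay is a pure function of its inputs, so
reports are byte-identical across runs.

The hit rule is deliberately strict by default: the tip's containing voxel
must carry the target label (tolerance 0 = inside the lesion); a
configurable tolerance in millimetres relaxes it. When a target is hit the
next configured target becomes active (beginner then expert, matching the
training progression); hitting the last target completes and closes the
session.

Time and dose are recorded as *step count* and *scan count* —
deterministic proxies chosen because wall-clock timing would make replays
irreproducible. A scan issued while the needle is outside the volume still
counts: a real scanner irradiates regardless of where the needle is.
Between `move_needle` commands the pose is held constant; no jitter or
drift model is applied at session level.

## Questionnaire analytics

Face-validity studies of simulators summarise 5-level Likert items as
per-level counts with percentages and a mean (SD) column. `ctbiopsim`
computes the mean as `Σ i·cᵢ / n` and the SD with the sample (n − 1)
denominator — the convention that exactly reproduces the packaged tables'
printed values, where the population (n) denominator does not (it yields
0.39 rather than 0.40 on the unanimous-agreement enjoyment item).
Rounding is half-up: means to 1 decimal, SDs to 2, percentages to
integers. Percentages are always recomputed from the counts; the packaged
full-cohort fixture contains one cell whose source printing (8% for 6/16)
is internally inconsistent, and the expert-subgroup fixture's printed
percentages use the full-cohort denominator — both are reported
recomputed (38%, and /4 respectively) rather than transcribed.

The analytics are descriptive only: no inferential statistics are
computed, matching the underlying study design (a 16-respondent
face-validity questionnaire, 12 trainees and 4 experts).

## Problem sizes used in the tests

The test suite favours many small, exactly-checkable cases: random
volumes of 6³–32³ voxels against brute-force oracles; 100 noise-free and
100 noisy poses for recovery properties; 200 randomized scripts for
scan-count conservation on a 48 × 48 × 24 phantom at 8 mm spacing; and the
full 128 × 128 × 96 default phantom for the scripted beginner session
(rendered at 3 mm pixels). `scripts/acceptance.R` re-runs the same
computations from the installed package and writes the resulting
quantities as JSON.

## Known limitations

- No real-image processing: corner detection, and hence detector failure
  modes (blur, lighting, perspective foreshortening of far corners), are
  outside the model.
- The phantom is piecewise-constant geometry plus white noise; it cannot
  exercise segmentation, registration or artifact-robustness.
- DICOM support is a minimal explicit-VR little-endian single-frame CT
  reader/writer — sufficient for round-tripping the package's own series
  and simple scanner exports, not a general DICOM implementation
  (sequences and compressed transfer syntaxes are rejected).
- The needle is rendered without bending; a real 150 mm needle flexes.
- Session metrics (scan/step counts) proxy dose and time but are not
  calibrated to either.
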