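# ctbiopsim

A headless simulator of CT-guided needle biopsy training, plus the
questionnaire analytics used to assess such a trainer's face validity.

CT-guided interventions are traditionally taught on real patients. A
low-cost alternative is a mixed-reality trainer: a torso phantom and a
biopsy needle each carry a planar chessboard fiducial, a head-mounted
camera tracks both, and software synthesizes the CT slice a scanner would
produce at the needle's position — so a trainee can iterate the familiar
*align with the laser line → advance → scan → adjust* loop without a
patient or radiation. `ctbiopsim` implements the computational core of
such a trainer, with every hardware-bound stage (camera capture, display,
speech input) replaced by a simulated or scripted equivalent:

- **CT volume** — Hounsfield-unit grid with affine voxel-to-world geometry
  (LPS, mm), trilinear sampling, NIfTI and DICOM-series I/O, and a
  synthetic labeled torso phantom: body and fat ellipse, spine and rib
  bone, kidneys, contrast-filled aorta, and two labeled retroperitoneal
  lymph-node targets — a beginner pararenal node with a direct path and an
  expert para-aortic node.
- **Fiducial pose** — chessboard board/camera models, pinhole projection,
  and planar pose estimation: a normalized-DLT homography decomposed into
  an initial rigid pose (SVD nearest-rotation), refined by Gauss–Newton on
  the reprojection error. A synthetic observation generator (projection +
  occlusion + pixel noise) stands in for the real corner detector.
- **Scan simulator** — axial slab resampling with supersampled
  partial-volume averaging, compositing the tracked needle as a
  metal-density capsule (cylinder + hemispherical tip cap) over the
  inserted length; slice navigation and the laser-line z position.
- **Procedure session** — a state machine over the trainer's command set
  (`select`, `scan`, `next`, `previous`, plus `move_needle`/`end`), with
  label-mask hit detection, per-scan tip-to-target distances, and scan /
  step counts as deterministic proxies for dose and time.
- **Study analytics** — 5-level Likert item summaries (per-level
  percentages, mean to 1 decimal, sample SD to 2 decimals, agreement
  counts) reproducing published face-validity tables from packaged
  response-count fixtures.

For a Likert item with level counts `c₁…c₅` and `n = Σcᵢ`, the summary is
`mean = Σ i·cᵢ / n` and the sample standard deviation
`sd = √( Σ cᵢ (i − mean)² / (n − 1) )`, both rounded half-up.

## Worked example

```r
library(ctbiopsim)

# 1. A labeled torso phantom
ph <- generate_phantom(phantom_config())
ph$volume
#> <ct_volume> 128 x 128 x 96 voxels @ 3 x 3 x 3 mm
#>   origin (mm): -190.5 -190.5 -142.5
#>   HU range: [-1024, 737]; labels: 1, 2

# 2. Track the needle marker and derive the needle state
board <- board_model(5, 7, 10); cam <- camera_model()
true_pose <- rigid_transform(diag(3), c(-20, -30, 500))
obs <- simulate_observation(board, cam, true_pose, noise_sigma = 0.5, seed = 1)
est <- estimate_pose(board, cam, obs)
round(est$rmse, 2)
#> [1] 1.02

# 3. Replay a scripted biopsy attempt on the beginner target
rep <- run_script(system.file("extdata", "beginner_success.txt", package = "ctbiopsim"),
                  ph$volume, list(target_by_difficulty(ph$targets, "beginner")),
                  scan_params(in_plane_pixel_size = 3))
rep
#> <session_report>
#>   difficulty attempted: beginner
#>   scans: 5  steps: 11  targets hit: 1
#>   hit: TRUE  final tip-to-target distance: 0 mm
round(rep$per_scan_distance_mm, 1)
#> [1] 113.5  73.5  33.5  13.6   0.0

# 4. Questionnaire analytics
tab <- summarize_table(read_responses(
  system.file("extdata", "table1_counts.csv", package = "ctbiopsim")))
tab$mean_sd[1]
#> [1] "4.8 (0.40)"
```

The per-scan distances show the monotone approach of the scripted descent;
the hit is registered when the tip's voxel carries the target label. The
`"4.8 (0.40)"` is the mean (SD) of the "I enjoyed this training method"
item: 3 of 16 respondents agreed and 13 strongly agreed.

A command-line front end wraps the same functions:

```sh
exec/ctbiopsim generate-phantom --out phantom
exec/ctbiopsim run-session --volume phantom.nii.gz \
    --script inst/extdata/beginner_success.txt --target beginner \
    --out report.json --emit-slices slices/
exec/ctbiopsim pose-demo --n-poses 100 --noise 0.5 --out pose.json
exec/ctbiopsim analyze-questionnaire --in inst/extdata/table1_counts.csv \
    --out summary.csv
```

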