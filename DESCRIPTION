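Package: ctbiopsim
Title: Headless Simulator for CT-Guided Needle Biopsy Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless simulator of CT-guided needle biopsy training.
    Provides a synthetic labeled torso phantom and NIfTI/DICOM CT volume I/O,
    planar chessboard-fiducial pose estimation from simulated camera
    observations, synthesis of axial CT slices containing a virtual metal
    needle rendered in Hounsfield units with partial-volume averaging, a
    scripted scan/advance procedure state machine with beginner and expert
    lymph-node targets and per-session metrics, and Likert-scale questionnaire
    summarisation for face-validity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
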