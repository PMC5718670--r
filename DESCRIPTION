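Package: cbctmotion
Title: Fiducial Marker Tracking and Respiratory Motion Correction for
    Cone-Beam CT Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts three-dimensional motion trajectories of radio-opaque
    seed markers from kV cone-beam CT projection stacks and removes that
    motion from the projections prior to reconstruction. Markers are located
    in every projection by normalized cross-correlation template matching
    with subpixel refinement; the stationary component of the marker
    sinogram is recovered by nonlinear least-squares fitting of the
    cone-beam projection equations; detector-frame residuals are decomposed
    into patient-frame displacements and parameterized as sinusoids
    (amplitude, frequency, phase); per-frame shifts are then applied to the
    projections and the corrected stack is reconstructed with a small-scale
    Feldkamp (FDK) filtered back-projection. A synthetic cone-beam
    acquisition simulator with programmable marker trajectories provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
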