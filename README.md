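# cbctmotion

Respiratory motion is the dominant source of image artifact in cone-beam CT
(CBCT) acquired with a linac-mounted on-board imager: one full gantry
rotation takes about a minute, spanning 10–20 breathing cycles, so every
projection sees the anatomy in a different position and the reconstruction
blurs and distorts. `cbctmotion` implements, in R, a complete
projection-domain answer for scans that contain radio-opaque seed markers
(implanted fiducials or skin-attached beads):

1. **Track** the marker in every kV projection by zero-normalized
   cross-correlation (ZNCC) template matching with subpixel refinement,
   outlier rejection and gap interpolation.
2. **Fit** the stationary component of the marker's sinogram — its detector
   trace over gantry angle — with the cone-beam projection equations, by
   Levenberg–Marquardt over the spherical rest coordinates (r, α, β).
3. **Decompose** the detector-frame residuals (Δj, Δk) into patient-frame
   displacements (Δx′, Δy′, Δz′) and parameterize each axis as a sinusoid
   A·sin(2πf·t − δ).
4. **Correct** the projections by shifting every pixel of each frame by that
   frame's (u, v) = (Δj, Δk), and **reconstruct** with a small-scale
   Feldkamp (FDK) filtered back-projection to quantify the artifact
   reduction.

A synthetic cone-beam acquisition simulator (programmable 3D marker
trajectories, exact ground truth per frame) makes every stage testable with
no external data. The package is aimed at medical-physics and image-analysis
researchers prototyping marker-based motion management for CBCT; it is not a
clinical reconstruction tool.

## The model

With the source at source–axis distance SAD rotating at gantry angle θ, and
a detector at source–imager distance SID, a patient point at in-plane radius
ρ = √(x²+y²), polar angle α = atan2(x, y) and height z projects to detector
coordinates (origin on the central ray)

    j = SID · ρ sin(α − θ) / d,   k = SID · z / d,   d = SAD − ρ cos(α − θ).

For a stationary point this traces a closed loop in (j, k) over a rotation —
the stationary sinogram (js, ks). A moving marker's measured track
(jm, km) superimposes its motion on that loop; fitting (r, α, β) of the
stationary model to (jm, km) and subtracting isolates the motion:
Δj = jm − js, Δk = km − ks. Because a single monoscopic view cannot resolve
depth, the inversion to patient coordinates holds α at its fitted value and
uses the fitted stationary depth, so the superior–inferior component is

    Δz′ = c · Δk · (1 − ρs cos(α − θ)/SAD),   c = SAD/SID,

computed per frame, and in-plane motion is recovered over the rotation. Each
axis is then summarized by a sinusoid fit A·sin(2πf·t − δ). Corrected
projections I′(j, k) = I(j + u, k + v) feed a Hann-apodized FDK
reconstruction.

At the clinical geometry (SAD 100 cm, SID 150 cm, 40 cm/1024 px panel) one
detector pixel demagnifies to 0.26 mm at isocenter, so the tracker's
half-pixel localization precision corresponds to about 0.13 mm.

## Worked example

Simulate the standard moving-platform protocol — a seed marker at
(r = 10 cm, α = 40°, β = 90°) driven along the superior–inferior axis at
1.75 cm amplitude and 15 cycles/min — on the reduced 256 × 192 test
geometry, then recover the motion from the projections alone:

```r
library(cbctmotion)

geom   <- reduced_geometry()                       # 360 frames / 60 s / 360 deg
marker <- marker_spec(patient_point_spherical(10, 40 * pi / 180, pi / 2),
                      motion_waveform(a_z = 1.75, f_z = 15),  # cm, cycles/min
                      id = "seed1")
scan   <- generate_scan(list(marker), geom, noise_sd = 20, seed = 1)
scan
#> <projection_stack> 360 frames of 192 x 256 px, ground truth for 1 marker(s)

res <- extract_marker_motion(scan)   # track -> fit -> decompose -> sinusoids
res$fit
#> <stationary_fit> r = 10 cm, alpha = 40 deg, beta = 90 deg
#>   residual RMS 8.463 px over 360 points (359 deg span, 3 LM iterations)
res$sinusoids$z
#> <sinusoid_fit> A = 1.75 cm, f = 0.25 Hz (15 cycles/min), delta = 7.798e-05 rad, RMS 0.00177 cm (n = 360)

tidy_motion_fits(res$sinusoids)
#> # A tibble: 3 x 7
#>   axis   a_cm   f_hz f_cpm  phase_rad   rms_cm flat
#>   <chr> <dbl>  <dbl> <dbl>      <dbl>    <dbl> <lgl>
#> 1 x      0    NA      NA   NA         NA       TRUE
#> 2 y      0    NA      NA   NA         NA       TRUE
#> 3 z      1.75  0.250  15.0  0.0000780 0.00177  FALSE
```

The stationary fit lands on the marker's rest position; its residual RMS
(~8.5 px) is the motion itself, which the decomposition turns into a clean
1.75 cm / 15 cycles-per-minute superior–inferior trace; the injected
cross-axis amplitudes are zero and come back flat. `autoplot()` methods
exist for tracks, traces, shift maps and volume slices, and
`tidy()`/`glance()` for the fitted objects.

Motion correction and reconstruction continue from the same objects:

```r
sm        <- shiftmap_from_residuals(detector_residuals(res$track, res$fit), scan$meta)
corrected <- correct_stack(scan, sm)
vol       <- fdk_reconstruct(corrected, n = 64, voxel_cm = 0.25)
blur_metric(vol, axis = 3)    # 20-80% edge-spread width, mm
```

A command-line workflow (`simulate`, `track`, `extract`, `correct`,
`reconstruct`, `report`) is available through `inst/scripts/cbctmotion`,
driven by a YAML run configuration (`read_config()`); all stage outputs are
plain CSV/JSON/TIFF/NIfTI files.

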