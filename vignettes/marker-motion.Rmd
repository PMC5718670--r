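---
title: "Marker-based motion extraction and correction for cone-beam CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based motion extraction and correction for cone-beam CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbctmotion)
```

This vignette is the package's own account of the science it implements:
the projection model and its conventions, the estimation stages and their
assumptions, what the synthetic simulator does and does not emulate, and
the numerical choices that were genuinely open.

## Projection model and conventions

A circular cone-beam acquisition is described by `scan_geometry()`: the
source–axis distance SAD (default 100 cm), source–imager distance SID
(default 150 cm), the flat-panel size and matrix, and a per-frame
(time, gantry angle) schedule — by default about 650 projections over 360°
in one minute, matching a clinical on-board imager; `reduced_geometry()`
(256 × 192 px, 360 frames) is the package's test scale.

Conventions, fixed once and shared by every stage:

* Patient frame: Z is superior–inferior; at θ = 0 the source lies on +Y;
  rotation is counter-clockwise seen from +Z. Any fixed convention works —
  all stages share this one.
* In-plane polar angle α = atan2(x, y), which is quadrant-safe everywhere
  (a plain arctangent of x/y is not).
* Detector coordinates are continuous cm with origin on the central ray;
  pixel indices are 0-based with centers at (index + 0.5)·pitch − half-width.
  Files store pixels; configs store cm; angles are degrees in files and
  radians internally; times are seconds.

With ρ = √(x² + y²) and depth denominator d = SAD − ρ·cos(α − θ), a point
projects to

$$j = \mathrm{SID}\,\rho\sin(\alpha-\theta)/d, \qquad
  k = \mathrm{SID}\,z/d .$$

Both equations carry the same denominator — the one self-consistent pinhole
form: a single ray through the source cannot have different effective
depths for its two detector components. The isocenter maps to (0, 0) at
every angle; a point displaced only along Z keeps a constant k; off-axis
points trace closed elliptical loops whose size grows with distance from
the axis. These limiting cases are asserted in the tests, together with a
closed-form two-view inversion oracle that recovers arbitrary points to
10⁻⁹ cm from two projections 90° apart.

## Tracking

Markers are located per frame by zero-normalized cross-correlation (ZNCC)
against a user-selected template. Design points:

* **Normalization.** Zero-mean normalization was chosen (scores invariant
  under affine intensity rescaling to 10⁻⁹, asserted); plain correlation is
  not intensity-invariant.
* **Fast path and oracle.** The production ZNCC map uses FFT
  cross-correlation plus integral-image window statistics; the test suite
  compares it to a literal per-offset double loop on small frames to
  10⁻¹⁰, so the fast path is never its own referee.
* **Subpixel refinement.** A quadratic surface is fit to the 3 × 3 score
  neighborhood of the integer peak; the offset is clamped to ±0.5 px (the
  true peak cannot be farther from the integer maximum) and skipped when
  the peak sits on the window border. Half-pixel precision is the method's
  published operating point; the refinement mainly smooths the motion
  traces.
* **Template centering.** The ROI is drawn on the pixel grid but the marker
  rarely sits on it; the blob's intensity centroid inside the template is
  estimated once and added to every match, otherwise all positions inherit
  a constant bias of up to half a pixel.
* **Window propagation.** The search window (default ~4× the template
  area) is centered on the previous accepted position; the first frame
  searches the whole image or a user seed. Frames whose best score falls
  below `min_score` (default 0.5), whose window is flat, or whose peak is
  on the border are recorded `missing` — this is exactly how a marker that
  leaves the panel in half-fan-style scans appears.
* **Outliers.** Tracking fails occasionally on shadows that mimic the
  marker; detected points whose running-median residual exceeds 5 robust
  deviations are relabeled. The robust scale is the larger of the MAD and a
  90th-percentile estimate with a 0.5 px physical floor: on noise-free
  tracks the running median reproduces most samples exactly, the MAD
  degenerates to zero, and without the backup scale the extremes of every
  breathing cycle would be flagged.
* **Gaps.** Interior gaps are filled on jm(t), km(t) by a natural cubic
  spline through detected points — cyclic respiration interpolates well.
  Leading/trailing gaps are never extrapolated and gaps longer than
  `max_gap_s` (default 5 s) stay missing: sudden non-cyclic motion cannot
  be predicted this way.

## Stationary fit and motion decomposition

The stationary spherical coordinates (r, α, β) minimize
Σ (jm − js)² + (km − ks)² over usable frames, in pixel units, by
Levenberg–Marquardt (`minpack.lm`). Choices:

* **Initialization.** A coarse grid (α every 10°, β 10–170° every 10°,
  r 1–25 cm every 2 cm) precedes the descent; the returned optimum is never
  allowed to score worse than the best grid node (asserted in the fit).
  This avoids the mirror local minima the sinogram cost has.
* **Usable points.** Detected and interpolated points both enter;
  interpolated ones at weight 0.5 — they carry real information about the
  cycle but are model output, not measurements. The weight is a choice, not
  something the method dictates.
* **Identifiability.** At least 10 usable points spanning ≥ 90° of gantry
  arc are required; below that the loop geometry does not constrain all
  three coordinates (the degenerate isocenter track fits r = 0 with α, β
  arbitrary, which is accepted).

Per-frame residuals Δj = jm − js, Δk = km − ks are the detector-frame
motion. Inverting them to the patient frame is underdetermined from one
monoscopic view, so the package adopts the only per-frame-computable
reading: hold α at its fitted stationary value when inverting j → (x, y),
and use the fitted stationary radial depth in the k → z denominator,

$$\Delta z' = c\,(k_m - k_s)\,(1 - \rho_s\cos(\alpha-\theta)/\mathrm{SAD}),
  \qquad c = \mathrm{SAD}/\mathrm{SID}.$$

For purely superior–inferior motion this inversion is exact (the
denominator does not depend on z), which is why the Z axis — the dominant
respiratory direction and the one the method is designed around — is
recovered to a fraction of a percent. In-plane inversion is ill-conditioned
where the marker lies near the source–isocenter axis
(sin(α − θ) ≈ 0): frames within 5° of that blind spot get `NA` in-plane
displacements and a `blind_spot` flag, while Δz′ is computed everywhere.
In-plane motion is therefore recovered over the rotation, not per frame,
and the per-frame in-plane components are radial by construction.

Each axis is then fit with A·sin(2πf·t − δ): frequency seeded at the
dominant periodogram peak of a uniform resampling, amplitude and phase by
the quadrature regression at that frequency, then joint Levenberg–Marquardt
refinement; the result is canonicalized to A ≥ 0, δ ∈ [0, 2π). At least two
full periods are required; a flat signal returns A = 0 with a flag rather
than a spurious frequency. `correlate_tracks()` compares two traces
(internal vs external markers) by zero-lag Pearson correlation on a common
timebase, the cross-correlation lag, and the fitted phase difference —
internal and external markers often share frequency while differing in
amplitude and phase, which is precisely what this quantifies. A measured
gantry-sag table, when available, is subtracted from the sinogram before
fitting (`subtract_sag()`); measuring sag itself is out of scope.

## Correction and reconstruction

The tracked marker's (Δj, Δk) become per-frame rigid shifts (u, v):
corrected frames take I′(j, k) = I(j + u, k + v) with bilinear resampling
and edge padding (the borders carry no object in the intended use; edge
values avoid manufacturing zeros). Frames without an estimate are filled by
linear interpolation in time with endpoints held, and flagged. The whole
frame moves with one marker — the rigid-body reading: the neighborhood of
the marker and lesion moves with it, which is where the correction is
claimed to be accurate. Differential, per-region correction is explicitly
future work.

Reconstruction is a deliberately small Feldkamp filtered back-projection
for quantifying artifact reduction, not a clinical tool: intensities are
converted to line integrals with −log(I/I₀), cosine-weighted, ramp-filtered
along detector rows with a Hann-apodized kernel (any standard FDK
apodization is admissible; Hann suppresses the noise amplification of the
bare ramp), and back-projected with SAD²/d² weighting. Full-fan geometry
only; offset-detector (half-fan) reconstruction, scatter, bowtie and beam
hardening are out of scope. Blur is quantified as the 20–80% edge-spread
width of a profile through the object (validated against the closed-form
Gaussian answer (q₀.₈ − q₀.₂)·σ ≈ 1.683 σ), and localization by the
intensity-weighted centroid error.

## The synthetic simulator

`generate_scan()` emulates the acquisition the pipeline is built for:
650-ish frames over ~360° in ~60 s on a 1024 × 768 panel (reduced test
default 256 × 192 / 360 frames), high-contrast seed shadows on a uniform
noisy background, markers on programmable per-axis sinusoids
A·sin(2πf·t − δ) with optional drift and breath-hold dropout. Defaults
follow the moving-platform protocol: 1.75 cm amplitude at 15 cycles/min
(frequencies are accepted in cycles/min or Hz explicitly, because breathing
rates quoted in Hz are a recurring source of confusion). Markers render as
anisotropic Gaussian attenuation blobs — σ from physical size ×
magnification, with a 1 px floor so footprints stay resolvable on coarse
test detectors — rather than ray-traced cylinders: sufficient for NCC
tracking and reconstruction surrogates, and vastly simpler. Ground-truth
detector positions are computed from the projection equations exactly, and
identical inputs plus seed give bit-identical stacks (asserted).

What it does **not** emulate — and hence what passing tests do not show
about clinical data: anatomical background texture and confusable shadows
(tracking failure rates here are optimistic), scatter/bowtie/beam-hardening
physics, detector lag, gantry sag (injectable only through the sag table),
irregular breathing beyond frozen-interval dropout, and deformable motion —
the simulator moves markers rigidly, matching the correction's own
assumption rather than testing it.

## Problem sizes and runtime

The test suite and the acceptance script run at the reduced scale: 360-frame
256 × 192 scans for pipeline checks (seconds each), 128 × 96 or smaller
detectors and 24³–64³ volumes for reconstruction checks; the three-way
stationary/moving/corrected FDK comparison uses 64³ voxels of 0.25 cm.
These sizes were chosen so a full check runs on a laptop in minutes while
every quantity asserted (subpixel tracking error, percent-level amplitude
recovery, blur-width ordering) is already stable at that scale; the full
clinical geometry remains available through `scan_geometry()` defaults.

## Known limitations

* Per-frame in-plane displacements are radial projections under the
  monoscopic depth assumption; quantitative in-plane amplitudes should be
  read from the rotation as a whole, and the blind-spot frames are flagged,
  not fixed.
* One template per marker for all views: strongly anisotropic markers seen
  edge-on vs face-on would need multi-template appearance models, which are
  out of scope.
* The rigid-shift correction is exact only for the tracked marker's
  neighborhood; structures moving differently acquire residual artifact.
* The FDK module trades fidelity for size; it quantifies relative blur and
  centroid shifts, and its absolute gray values are not calibrated CT
  numbers.
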