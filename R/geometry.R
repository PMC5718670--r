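#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: source-to-axis distance (SAD),
#' source-to-imager distance (SID), flat-panel detector size, and the
#' per-frame (time, gantry angle) schedule. The patient frame is fixed with Z
#' along the superior--inferior axis; at `theta = 0` the source lies on the +Y
#' patient axis and the gantry rotates counter-clockwise viewed from +Z.
#'
#' Detector coordinates are continuous centimetres with origin on the central
#' ray (the ray through isocenter); pixel indices are 0-based with pixel
#' centers at `(index + 0.5) * pitch - half_width`.
#'
#' @param sad Source-to-axis distance in cm (default 100).
#' @param sid Source-to-imager distance in cm (default 150).
#' @param det_width_cm,det_height_cm Physical detector size in cm
#'   (default 40 x 30, the effective area of a clinical flat panel).
#' @param det_cols,det_rows Detector matrix size in pixels (default
#'   1024 x 768; use [reduced_geometry()] for a fast test-scale setup).
#' @param schedule Tibble with columns `frame`, `time_s`, `theta_deg`
#'   (strictly increasing times). Defaults to [make_schedule()] with
#'   `n_frames` frames over `duration_s` seconds and `arc_deg` degrees.
#' @param n_frames,duration_s,arc_deg Used to build the default schedule:
#'   about 650 frames over ~360 degrees in ~60 s for a clinical scan.
#' @param scan_mode `"full_fan"` or `"half_fan"`; metadata only.
#'
#' @return An object of class `scan_geometry`: a list with the fields above
#'   plus derived `pitch_w_cm`, `pitch_h_cm` (pixel pitch) and the scaling
#'   factor `c = SAD/SID` mapping detector lengths to isocenter.
#' @examples
#' geom <- scan_geometry()
#' geom$c            # 2/3
#' isocenter_pixel_pitch(geom)  # 0.26 mm
#' @export
scan_geometry <- function(sad = 100, sid = 150,
                          det_width_cm = 40, det_height_cm = 30,
                          det_cols = 1024, det_rows = 768,
                          schedule = NULL,
                          n_frames = 650, duration_s = 60, arc_deg = 360,
                          scan_mode = c("full_fan", "half_fan")) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(sid > sad, sad > 0, det_width_cm > 0, det_height_cm > 0,
            det_cols >= 1, det_rows >= 1)
  if (is.null(schedule)) {
    schedule <- make_schedule(n_frames, duration_s, arc_deg)
  }
  schedule <- validate_schedule(schedule)
  g <- structure(list(
    sad = sad, sid = sid,
    det_width_cm = det_width_cm, det_height_cm = det_height_cm,
    det_cols = as.integer(det_cols), det_rows = as.integer(det_rows),
    pitch_w_cm = det_width_cm / det_cols,
    pitch_h_cm = det_height_cm / det_rows,
    c = sad / sid,
    schedule = schedule,
    scan_mode = scan_mode
  ), class = "scan_geometry")
  g
}

#' Reduced test-scale geometry
#'
#' Same distances and panel area as the clinical default but a 256 x 192
#' detector matrix and 360 frames over 360 degrees in 60 s, so full pipelines
#' run in seconds. Pixel pitch is coarser (about 1.6 mm at the panel).
#'
#' @inheritParams scan_geometry
#' @return A `scan_geometry`.
#' @export
reduced_geometry <- function(n_frames = 360, duration_s = 60, arc_deg = 360,
                             det_cols = 256, det_rows = 192) {
  scan_geometry(det_cols = det_cols, det_rows = det_rows,
                n_frames = n_frames, duration_s = duration_s,
                arc_deg = arc_deg)
}

#' Build a uniform acquisition schedule
#'
#' @param n_frames Number of projections.
#' @param duration_s Total scan time in seconds.
#' @param arc_deg Gantry arc covered, degrees.
#' @param start_deg Angle of the first frame, degrees.
#' @return Tibble with columns `frame` (1-based), `time_s`, `theta_deg`.
#' @export
make_schedule <- function(n_frames, duration_s = 60, arc_deg = 360,
                          start_deg = 0) {
  i <- seq_len(n_frames) - 1L
  tibble::tibble(
    frame = i + 1L,
    time_s = i * duration_s / n_frames,
    theta_deg = start_deg + i * arc_deg / n_frames
  )
}

validate_schedule <- function(schedule) {
  schedule <- tibble::as_tibble(schedule)
  need <- c("frame", "time_s", "theta_deg")
  if (!all(need %in% names(schedule))) {
    stop("schedule must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(schedule) > 1 && any(diff(schedule$time_s) <= 0)) {
    stop("schedule times must be strictly increasing")
  }
  if (anyDuplicated(schedule$frame)) stop("schedule frame indices must be unique")
  schedule
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> SAD %.4g cm, SID %.4g cm (c = %.4f)\n", x$sad, x$sid, x$c))
  cat(sprintf("  detector: %d x %d px, %.4g x %.4g cm (pitch %.4g mm)\n",
              x$det_cols, x$det_rows, x$det_width_cm, x$det_height_cm,
              x$pitch_w_cm * 10))
  cat(sprintf("  schedule: %d frames, %.3g s, theta %.4g..%.4g deg, %s\n",
              nrow(x$schedule), max(x$schedule$time_s),
              min(x$schedule$theta_deg), max(x$schedule$theta_deg),
              x$scan_mode))
  invisible(x)
}

#' Point in the fixed patient frame
#'
#' @param x,y,z Coordinates in cm; Z is the superior--inferior axis.
#' @return A `patient_point`: a named list with the Cartesian coordinates
#'   plus derived spherical ones: `r` (radial distance), `rho` (in-plane
#'   radial distance, \eqn{\sqrt{x^2+y^2}}), `alpha = atan2(x, y)` (in-plane
#'   polar angle, radians) and `beta` (angle from the Z axis, radians).
#' @examples
#' patient_point_spherical(10, 40 * pi / 180, 40 * pi / 180)
#' @export
patient_point <- function(x, y, z) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z))
  rho <- sqrt(x^2 + y^2)
  r <- sqrt(rho^2 + z^2)
  structure(list(
    x = x, y = y, z = z,
    r = r, rho = rho,
    alpha = atan2(x, y),
    beta = if (r > 0) acos(z / r) else 0
  ), class = "patient_point")
}

#' @rdname patient_point
#' @param r Radial distance cm; `alpha` polar angle in the X--Y plane
#'   (radians, from +Y toward +X); `beta` azimuthal angle from the Z axis
#'   (radians).
#' @param alpha,beta Angles in radians.
#' @export
patient_point_spherical <- function(r, alpha, beta) {
  patient_point(x = r * sin(beta) * sin(alpha),
                y = r * sin(beta) * cos(alpha),
                z = r * cos(beta))
}

as_patient_point <- function(p) {
  if (inherits(p, "patient_point")) return(p)
  if (is.numeric(p) && length(p) == 3) return(patient_point(p[1], p[2], p[3]))
  stop("cannot interpret object as a patient point")
}

#' Project a patient point onto the detector
#'
#' Pinhole cone-beam projection. With in-plane radius
#' \eqn{\rho = \sqrt{x^2+y^2}}, polar angle \eqn{\alpha = atan2(x, y)} and
#' depth denominator \eqn{d = SAD - \rho\cos(\alpha-\theta)}, the detector
#' coordinates are
#' \deqn{j = SID\,\rho\sin(\alpha-\theta)/d, \qquad k = SID\,z/d.}
#' A point at isocenter maps to (0, 0) for every gantry angle; a point
#' displaced only along Z keeps a constant `k` over the whole rotation.
#'
#' @param p A [patient_point()] (or numeric `c(x, y, z)` in cm).
#' @param theta_deg Gantry angle(s) in degrees; vectorized.
#' @param geom A [scan_geometry()].
#' @return Tibble with `theta_deg`, `j_cm`, `k_cm` (detector cm, origin at
#'   the central ray) and `in_fov` (inside the physical panel).
#' @export
project_point <- function(p, theta_deg, geom) {
  p <- as_patient_point(p)
  th <- theta_deg * pi / 180
  d <- geom$sad - p$rho * cos(p$alpha - th)
  if (any(d <= 0)) {
    stop("point projects from behind the source plane (SAD - rho*cos(alpha-theta) <= 0)")
  }
  j <- geom$sid * p$rho * sin(p$alpha - th) / d
  k <- geom$sid * p$z / d
  tibble::tibble(
    theta_deg = theta_deg, j_cm = j, k_cm = k,
    in_fov = abs(j) <= geom$det_width_cm / 2 & abs(k) <= geom$det_height_cm / 2
  )
}

#' Stationary sinogram track of a patient point
#'
#' Applies [project_point()] over the whole acquisition schedule. For a
#' stationary point the (j, k) locus over a full rotation is a closed curve
#' (an ellipse-like loop whose size grows with distance from isocenter);
#' a point on the rotation axis keeps j = 0.
#'
#' @inheritParams project_point
#' @return Tibble with one row per scheduled frame: `frame`, `time_s`,
#'   `theta_deg`, `j_cm`, `k_cm`, `j_px`, `k_px`, `in_fov`.
#' @export
stationary_track <- function(p, geom) {
  sch <- geom$schedule
  pr <- project_point(p, sch$theta_deg, geom)
  px <- cm_to_px(pr$j_cm, pr$k_cm, geom)
  tibble::tibble(
    frame = sch$frame, time_s = sch$time_s, theta_deg = sch$theta_deg,
    j_cm = pr$j_cm, k_cm = pr$k_cm,
    j_px = px$j_px, k_px = px$k_px,
    in_fov = pr$in_fov
  )
}

#' Detector pixel size demagnified to isocenter
#'
#' A detector pixel of pitch `p` subtends `p * SAD/SID` at the rotation
#' axis; this is the in-plane size of the voxels that one detector pixel
#' resolves, and the natural unit for quoting tracking precision (a 0.5 px
#' localization error maps to 0.5 of this value).
#'
#' @param geom A [scan_geometry()].
#' @return Pixel pitch at isocenter in **mm**.
#' @examples
#' isocenter_pixel_pitch(scan_geometry())  # 0.26 mm for 40 cm / 1024 px
#' @export
isocenter_pixel_pitch <- function(geom) {
  10 * geom$pitch_w_cm * geom$sad / geom$sid
}

#' Convert between detector pixels and centimetres
#'
#' Affine and exactly invertible: pixel indices are 0-based and pixel
#' centers sit at `(index + 0.5) * pitch - half_width`.
#'
#' @param j_px,k_px 0-based pixel coordinates (may be fractional).
#' @param j_cm,k_cm Detector coordinates in cm, origin at the central ray.
#' @param geom A [scan_geometry()].
#' @return `px_to_cm`: tibble with `j_cm`, `k_cm`; `cm_to_px`: tibble with
#'   `j_px`, `k_px`.
#' @export
px_to_cm <- function(j_px, k_px, geom) {
  tibble::tibble(
    j_cm = (j_px + 0.5) * geom$pitch_w_cm - geom$det_width_cm / 2,
    k_cm = (k_px + 0.5) * geom$pitch_h_cm - geom$det_height_cm / 2
  )
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(j_cm, k_cm, geom) {
  tibble::tibble(
    j_px = (j_cm + geom$det_width_cm / 2) / geom$pitch_w_cm - 0.5,
    k_px = (k_cm + geom$det_height_cm / 2) / geom$pitch_h_cm - 0.5
  )
}

#' Read/write scan geometry as YAML
#'
#' The schedule travels with the geometry. `read_geometry()` also accepts a
#' metadata CSV path via `schedule_csv` to override the stored schedule.
#'
#' @param geom A [scan_geometry()].
#' @param path File path.
#' @param schedule_csv Optional CSV (`frame,time_s,theta_deg`) replacing the
#'   stored schedule.
#' @return `read_geometry()` returns a `scan_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path) {
  out <- list(
    sad = geom$sad, sid = geom$sid,
    det_width_cm = geom$det_width_cm, det_height_cm = geom$det_height_cm,
    det_cols = geom$det_cols, det_rows = geom$det_rows,
    scan_mode = geom$scan_mode,
    schedule = lapply(seq_len(nrow(geom$schedule)), function(i) {
      as.list(geom$schedule[i, c("frame", "time_s", "theta_deg")])
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path, schedule_csv = NULL) {
  y <- yaml::read_yaml(path)
  sch <- if (!is.null(schedule_csv)) {
    utils::read.csv(schedule_csv)
  } else {
    dplyr::bind_rows(lapply(y$schedule, tibble::as_tibble))
  }
  scan_geometry(sad = y$sad, sid = y$sid,
                det_width_cm = y$det_width_cm, det_height_cm = y$det_height_cm,
                det_cols = y$det_cols, det_rows = y$det_rows,
                schedule = sch, scan_mode = y$scan_mode)
}
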