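#' Sinusoidal marker motion waveform
#'
#' Per-axis displacement model \eqn{\Delta(t) = A \sin(2\pi f t - \delta)},
#' optionally with a linear baseline drift and breath-hold dropout
#' intervals during which the displacement is frozen at its value at the
#' start of the interval (irregular breathing).
#'
#' The clinical phantom protocol this emulates drives the platform at
#' 15 cycles/min with 1.75 cm amplitude along the superior--inferior axis.
#' Frequencies may be given in cycles/min (the usual clinical unit) or Hz;
#' they are stored in Hz.
#'
#' @param a_x,a_y,a_z Amplitudes in cm (non-negative).
#' @param f_x,f_y,f_z Frequencies, in the unit named by `unit`.
#' @param phase_x,phase_y,phase_z Phases \eqn{\delta} in radians.
#' @param unit `"cpm"` (cycles per minute, default) or `"hz"`.
#' @param drift_x,drift_y,drift_z Linear drift in cm/s (default 0).
#' @param dropout Optional list of `c(t0, t1)` second intervals during which
#'   the waveform is frozen at its `t0` value.
#' @return A `motion_waveform` object.
#' @examples
#' w <- motion_waveform(a_z = 1.75, f_z = 15)   # phantom protocol
#' waveform_displacement(w, t = c(0, 1))
#' @export
motion_waveform <- function(a_x = 0, a_y = 0, a_z = 0,
                            f_x = 0, f_y = 0, f_z = 0,
                            phase_x = 0, phase_y = 0, phase_z = 0,
                            unit = c("cpm", "hz"),
                            drift_x = 0, drift_y = 0, drift_z = 0,
                            dropout = NULL) {
  unit <- match.arg(unit)
  conv <- if (unit == "cpm") 1 / 60 else 1
  stopifnot(a_x >= 0, a_y >= 0, a_z >= 0, f_x >= 0, f_y >= 0, f_z >= 0)
  structure(list(
    a = c(x = a_x, y = a_y, z = a_z),
    f_hz = c(x = f_x, y = f_y, z = f_z) * conv,
    phase = c(x = phase_x, y = phase_y, z = phase_z),
    drift = c(x = drift_x, y = drift_y, z = drift_z),
    dropout = dropout
  ), class = "motion_waveform")
}

#' Evaluate a motion waveform
#'
#' @param w A [motion_waveform()].
#' @param t Time(s) in seconds (vectorized, `t >= 0`).
#' @return Tibble with `time_s`, `dx_cm`, `dy_cm`, `dz_cm`.
#' @export
waveform_displacement <- function(w, t) {
  stopifnot(inherits(w, "motion_waveform"), all(t >= 0))
  t_eff <- t
  if (!is.null(w$dropout)) {
    for (iv in w$dropout) {
      held <- t >= iv[1] & t < iv[2]
      t_eff[held] <- iv[1]
      # time after the hold continues from where the hold started
      after <- t >= iv[2]
      t_eff[after] <- t_eff[after] - (iv[2] - iv[1])
    }
  }
  ax1 <- function(axis) {
    unname(w$a[axis] * sin(2 * pi * w$f_hz[axis] * t_eff - w$phase[axis]) +
             w$drift[axis] * t)
  }
  tibble::tibble(time_s = t, dx_cm = ax1("x"), dy_cm = ax1("y"),
                 dz_cm = ax1("z"))
}

#' Marker specification for the simulator
#'
#' A radio-opaque seed marker (clinical seeds are ~1 mm diameter, 2 mm
#' length) at a rest position, driven by a motion waveform. Markers are
#' rendered as anisotropic Gaussian attenuation blobs whose footprint scales
#' with physical size and cone-beam magnification; larger `diameter_mm`
#' values model ball-like objects for reconstruction tests.
#'
#' @param position A [patient_point()] rest position (cm).
#' @param waveform A [motion_waveform()]; default stationary.
#' @param diameter_mm,length_mm Physical size (mm): diameter sets the
#'   footprint along the detector j axis, length along k.
#' @param contrast Attenuation depth of the blob center relative to the
#'   background level, in (0, 1].
#' @param label `"internal"` or `"external"` (metadata).
#' @param id Marker identifier (string).
#' @return A `marker_spec`.
#' @export
marker_spec <- function(position, waveform = motion_waveform(),
                        diameter_mm = 1, length_mm = 2, contrast = 0.5,
                        label = c("internal", "external"), id = "m1") {
  label <- match.arg(label)
  stopifnot(diameter_mm > 0, length_mm > 0, contrast > 0, contrast <= 1)
  structure(list(
    position = as_patient_point(position), waveform = waveform,
    diameter_mm = diameter_mm, length_mm = length_mm,
    contrast = contrast, label = label, id = id
  ), class = "marker_spec")
}

# Displaced patient point of a marker at time t (cm).
marker_position_at <- function(m, t) {
  d <- waveform_displacement(m$waveform, t)
  patient_point(m$position$x + d$dx_cm[1],
                m$position$y + d$dy_cm[1],
                m$position$z + d$dz_cm[1])
}

#' Render one synthetic projection frame
#'
#' Draws every marker as a dark anisotropic Gaussian blob on a uniform
#' background, at its exact projected detector position for the given time
#' and gantry angle, then adds Gaussian read-out noise. Markers whose
#' projection falls off the panel are simply absent (this is what produces
#' the half-fan style partial visibility downstream).
#'
#' The Gaussian sigma is `size * magnification / 2.355` (FWHM = physical
#' size scaled to the panel) with a floor of `sigma_floor_px` pixels so that
#' the footprint stays resolvable on coarse test detectors.
#'
#' @param markers List of [marker_spec()] (a single spec is accepted).
#' @param t Acquisition time of the frame (s).
#' @param theta_deg Gantry angle (degrees).
#' @param geom A [scan_geometry()].
#' @param background Background intensity level (16-bit counts, default 3000).
#' @param noise_sd Additive Gaussian noise sigma in counts (default 0).
#' @param sigma_floor_px Minimum rendered blob sigma in pixels (default 1).
#' @param seed Optional integer; if given, the frame's noise is drawn from a
#'   local RNG stream with this seed and the caller's RNG state is restored.
#' @return Numeric matrix `det_rows x det_cols` (row = k, column = j),
#'   values clipped to [0, 65535].
#' @export
render_projection <- function(markers, t, theta_deg, geom,
                              background = 3000, noise_sd = 0,
                              sigma_floor_px = 1, seed = NULL) {
  if (inherits(markers, "marker_spec")) markers <- list(markers)
  frame <- matrix(background, nrow = geom$det_rows, ncol = geom$det_cols)
  for (m in markers) {
    p <- marker_position_at(m, t)
    th <- theta_deg * pi / 180
    d <- geom$sad - p$rho * cos(p$alpha - th)
    if (d <= 0) next
    pr <- project_point(p, theta_deg, geom)
    px <- cm_to_px(pr$j_cm, pr$k_cm, geom)
    mag <- geom$sid / d
    sig_j <- max(sigma_floor_px, m$diameter_mm / 10 * mag / 2.355 / geom$pitch_w_cm)
    sig_k <- max(sigma_floor_px, m$length_mm / 10 * mag / 2.355 / geom$pitch_h_cm)
    frame <- subtract_blob(frame, px$j_px, px$k_px, sig_j, sig_k,
                           depth = m$contrast * background)
  }
  if (noise_sd > 0) {
    add_noise <- function() {
      frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                     nrow = nrow(frame))
    }
    frame <- if (is.null(seed)) add_noise() else with_local_seed(seed, add_noise())
  }
  pmin(pmax(frame, 0), 65535)
}

# Subtract a Gaussian blob centered at continuous 0-based pixel (j0, k0).
# Only a +-4 sigma patch is touched.
subtract_blob <- function(frame, j0, k0, sig_j, sig_k, depth) {
  nr <- nrow(frame); nc <- ncol(frame)
  jr <- floor(j0 - 4 * sig_j):ceiling(j0 + 4 * sig_j)
  kr <- floor(k0 - 4 * sig_k):ceiling(k0 + 4 * sig_k)
  jr <- jr[jr >= 0 & jr < nc]
  kr <- kr[kr >= 0 & kr < nr]
  if (!length(jr) || !length(kr)) return(frame)
  gj <- exp(-((jr - j0)^2) / (2 * sig_j^2))
  gk <- exp(-((kr - k0)^2) / (2 * sig_k^2))
  frame[kr + 1, jr + 1] <- frame[kr + 1, jr + 1] - depth * outer(gk, gj)
  frame
}

# Evaluate expr with a local RNG stream; caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a full synthetic cone-beam scan
#'
#' Renders every frame of the acquisition schedule and tabulates the exact
#' projected detector position of every marker per frame (the ground-truth
#' table used by the tracking and motion tests). Bit-identical output for
#' identical inputs and seed.
#'
#' @inheritParams render_projection
#' @param seed Integer seed driving all noise (mandatory when
#'   `noise_sd > 0`).
#' @return A `projection_stack`: list with `frames` (list of matrices),
#'   `meta` (the schedule tibble), `geom`, `background`, and `truth` — a
#'   tibble with `frame`, `marker_id`, `time_s`, `theta_deg`, `j_px`,
#'   `k_px`, `in_fov` and the injected displacements `dx_cm`, `dy_cm`,
#'   `dz_cm`.
#' @examples
#' geom <- reduced_geometry(n_frames = 24)
#' mk <- marker_spec(patient_point(0, 0, 0))
#' st <- generate_scan(list(mk), geom, seed = 1)
#' @export
generate_scan <- function(markers, geom, background = 3000, noise_sd = 0,
                          sigma_floor_px = 1, seed = NULL) {
  if (inherits(markers, "marker_spec")) markers <- list(markers)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0")
  }
  sch <- geom$schedule
  body <- function() {
    frames <- vector("list", nrow(sch))
    truth <- vector("list", nrow(sch))
    for (i in seq_len(nrow(sch))) {
      frames[[i]] <- render_projection(markers, sch$time_s[i],
                                       sch$theta_deg[i], geom,
                                       background = background,
                                       noise_sd = noise_sd,
                                       sigma_floor_px = sigma_floor_px)
      truth[[i]] <- dplyr::bind_rows(lapply(markers, function(m) {
        disp <- waveform_displacement(m$waveform, sch$time_s[i])
        p <- patient_point(m$position$x + disp$dx_cm,
                           m$position$y + disp$dy_cm,
                           m$position$z + disp$dz_cm)
        pr <- project_point(p, sch$theta_deg[i], geom)
        px <- cm_to_px(pr$j_cm, pr$k_cm, geom)
        tibble::tibble(frame = sch$frame[i], marker_id = m$id,
                       time_s = sch$time_s[i], theta_deg = sch$theta_deg[i],
                       j_px = px$j_px, k_px = px$k_px, in_fov = pr$in_fov,
                       dx_cm = disp$dx_cm, dy_cm = disp$dy_cm,
                       dz_cm = disp$dz_cm)
      }))
    }
    list(frames = frames, truth = dplyr::bind_rows(truth))
  }
  out <- if (is.null(seed)) body() else with_local_seed(seed, body())
  projection_stack(out$frames, sch, geom, background = background,
                   truth = out$truth)
}

#' Projection stack container
#'
#' Ordered 2D frames plus per-frame metadata and the geometry they were
#' acquired (or simulated) with; the unit of I/O for simulate / track /
#' correct / reconstruct.
#'
#' @param frames List of equal-size numeric matrices (row = detector row k,
#'   column = detector column j).
#' @param meta Tibble `frame`, `time_s`, `theta_deg`, one row per frame.
#' @param geom A [scan_geometry()].
#' @param background Scalar background level (counts), if known.
#' @param truth Optional ground-truth tibble (see [generate_scan()]).
#' @return A `projection_stack`.
#' @export
projection_stack <- function(frames, meta, geom, background = NULL,
                             truth = NULL) {
  meta <- validate_schedule(meta)
  if (length(frames) != nrow(meta)) {
    stop("frame count (", length(frames), ") != metadata rows (", nrow(meta), ")")
  }
  if (length(frames)) {
    dm <- vapply(frames, dim, integer(2))
    if (any(dm[1, ] != dm[1, 1]) || any(dm[2, ] != dm[2, 1])) {
      stop("all frames must have the same dimensions")
    }
  }
  structure(list(frames = frames, meta = meta, geom = geom,
                 background = background, truth = truth),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0L, 0L)
  cat(sprintf("<projection_stack> %d frames of %d x %d px", length(x$frames),
              d[1], d[2]))
  if (!is.null(x$truth)) {
    cat(sprintf(", ground truth for %d marker(s)",
                length(unique(x$truth$marker_id))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.projection_stack <- function(x) length(x$frames)
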