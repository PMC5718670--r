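# Run configuration: a single YAML file drives the CLI workflow. Angles are
# degrees and lengths cm in configs; detector positions in files are 0-based
# pixels; times are seconds. Unknown keys are rejected so typos fail loudly.

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
  }
  block
}

#' Read and validate a run configuration
#'
#' Schema (all blocks optional except `seed` when noise is requested):
#' `geometry` (sad, sid, det_width_cm, det_height_cm, det_cols, det_rows,
#' n_frames, duration_s, arc_deg, scan_mode), `phantom` (background,
#' noise_sd, sigma_floor_px, markers: list of id, label, position
#' (x/y/z or r/alpha_deg/beta_deg), diameter_mm, length_mm, contrast,
#' waveform (a_x..a_z, f_x..f_z, unit, phase_x..phase_z)), `tracking`
#' (template_frame, roi (j_px, k_px, half_w, half_h), marker, min_score,
#' outlier_window, outlier_n_mad, max_gap_s), `fit` (interp_weight),
#' `recon` (n, voxel_cm), `seed`, `output_dir`.
#'
#' @param path YAML file.
#' @return Validated config list of class `cbct_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("geometry", "phantom", "tracking", "fit", "correction",
                    "recon", "seed", "output_dir"), "config")
  if (!is.null(cfg$geometry)) {
    check_keys(cfg$geometry,
               c("sad", "sid", "det_width_cm", "det_height_cm", "det_cols",
                 "det_rows", "n_frames", "duration_s", "arc_deg", "scan_mode"),
               "geometry")
  }
  if (!is.null(cfg$phantom)) {
    check_keys(cfg$phantom,
               c("background", "noise_sd", "sigma_floor_px", "markers"),
               "phantom")
    if ((cfg$phantom$noise_sd %||% 0) > 0 && is.null(cfg$seed)) {
      stop("config requests noise but has no seed; a seed is mandatory for stochastic stages")
    }
    for (m in cfg$phantom$markers) {
      check_keys(m, c("id", "label", "position", "diameter_mm", "length_mm",
                      "contrast", "waveform"), "marker")
      check_keys(m$position, c("x", "y", "z", "r", "alpha_deg", "beta_deg"),
                 "marker position")
      if (!is.null(m$waveform)) {
        check_keys(m$waveform,
                   c("a_x", "a_y", "a_z", "f_x", "f_y", "f_z", "unit",
                     "phase_x", "phase_y", "phase_z"), "waveform")
      }
    }
  }
  if (!is.null(cfg$tracking)) {
    check_keys(cfg$tracking,
               c("template_frame", "roi", "marker", "min_score",
                 "outlier_window", "outlier_n_mad", "max_gap_s"), "tracking")
  }
  if (!is.null(cfg$fit)) check_keys(cfg$fit, c("interp_weight"), "fit")
  if (!is.null(cfg$recon)) check_keys(cfg$recon, c("n", "voxel_cm"), "recon")
  structure(cfg, class = "cbct_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_geometry <- function(cfg) {
  g <- cfg$geometry %||% list()
  scan_geometry(sad = g$sad %||% 100, sid = g$sid %||% 150,
                det_width_cm = g$det_width_cm %||% 40,
                det_height_cm = g$det_height_cm %||% 30,
                det_cols = g$det_cols %||% 256,
                det_rows = g$det_rows %||% 192,
                n_frames = g$n_frames %||% 360,
                duration_s = g$duration_s %||% 60,
                arc_deg = g$arc_deg %||% 360,
                scan_mode = g$scan_mode %||% "full_fan")
}

config_markers <- function(cfg) {
  ms <- cfg$phantom$markers
  if (is.null(ms)) stop("config has no phantom markers")
  lapply(seq_along(ms), function(i) {
    m <- ms[[i]]
    pos <- m$position
    p <- if (!is.null(pos$r)) {
      patient_point_spherical(pos$r, (pos$alpha_deg %||% 0) * pi / 180,
                              (pos$beta_deg %||% 90) * pi / 180)
    } else {
      patient_point(pos$x %||% 0, pos$y %||% 0, pos$z %||% 0)
    }
    w <- m$waveform
    wf <- if (is.null(w)) motion_waveform() else {
      motion_waveform(a_x = w$a_x %||% 0, a_y = w$a_y %||% 0,
                      a_z = w$a_z %||% 0,
                      f_x = w$f_x %||% 0, f_y = w$f_y %||% 0,
                      f_z = w$f_z %||% 0,
                      phase_x = w$phase_x %||% 0, phase_y = w$phase_y %||% 0,
                      phase_z = w$phase_z %||% 0,
                      unit = w$unit %||% "cpm")
    }
    marker_spec(p, wf, diameter_mm = m$diameter_mm %||% 1,
                length_mm = m$length_mm %||% 2,
                contrast = m$contrast %||% 0.5,
                label = m$label %||% "internal",
                id = m$id %||% paste0("m", i))
  })
}
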