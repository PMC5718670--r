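#' One-shot marker motion extraction
#'
#' Convenience wrapper chaining the full per-marker pipeline: template
#' extraction, NCC tracking, outlier flagging, gap interpolation,
#' stationary-track fitting, patient-frame displacement decomposition and
#' per-axis sinusoid fits.
#'
#' @param stack A [projection_stack()].
#' @param roi Template ROI (`j_px`, `k_px`, `half_w`, `half_h`); if `NULL`
#'   and the stack has a ground-truth table, the ROI is centered on
#'   `marker`'s true position in `template_frame`.
#' @param template_frame Frame the template is cut from (default 1).
#' @param marker Marker id used for the auto-ROI (default first in truth).
#' @param roi_half Auto-ROI half-size in px (default 6).
#' @param min_score,outlier_window,outlier_n_mad,max_gap_s,interp_weight
#'   Stage parameters (see the stage functions).
#' @return List with `track` (after outlier/gap passes), `fit`
#'   (`stationary_fit`), `trace` (`motion_trace`) and `sinusoids`
#'   (list of per-axis `sinusoid_fit`).
#' @export
extract_marker_motion <- function(stack, roi = NULL, template_frame = 1,
                                  marker = NULL, roi_half = 6,
                                  min_score = 0.5, outlier_window = 11,
                                  outlier_n_mad = 5, max_gap_s = 5,
                                  interp_weight = 0.5) {
  if (is.null(roi)) {
    if (is.null(stack$truth)) {
      stop("no ROI given and the stack carries no ground-truth table")
    }
    tr <- stack$truth
    if (is.null(marker)) marker <- tr$marker_id[1]
    row <- dplyr::filter(tr, .data$marker_id == !!marker,
                         .data$frame == stack$meta$frame[template_frame])
    if (nrow(row) != 1 || !row$in_fov) {
      stop("marker not visible in the template frame; give an explicit ROI")
    }
    roi <- list(j_px = round(row$j_px), k_px = round(row$k_px),
                half_w = roi_half, half_h = roi_half)
  }
  template <- extract_template(stack, template_frame, roi)
  track <- track_stack(stack, template, min_score = min_score)
  track <- flag_outliers(track, window = outlier_window, n_mad = outlier_n_mad)
  track <- interpolate_gaps(track, max_gap_s = max_gap_s)
  fit <- fit_stationary(track, stack$geom, interp_weight = interp_weight)
  trace <- to_patient_displacements(track, fit, stack$geom)
  sinusoids <- fit_motion_sinusoids(trace)
  list(track = track, fit = fit, trace = trace, sinusoids = sinusoids)
}
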