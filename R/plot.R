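#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a marker track
#'
#' Detector positions against gantry angle, colored by tracking status —
#' the measured sinogram of the marker.
#'
#' @param object A `marker_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_track <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("theta_deg", "jm_px", "km_px", "status")],
    c("jm_px", "km_px"), names_to = "axis", values_to = "px")
  ggplot2::ggplot(d, ggplot2::aes(.data$theta_deg, .data$px,
                                  color = .data$status)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "gantry angle (deg)", y = "detector position (px)",
                  color = NULL)
}

#' Plot a patient-frame motion trace
#'
#' @param object A `motion_trace`.
#' @param ... Unused.
#' @return A ggplot with one facet per axis.
#' @export
autoplot.motion_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", "dx_cm", "dy_cm", "dz_cm")],
    c("dx_cm", "dy_cm", "dz_cm"), names_to = "axis", values_to = "cm")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$cm)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "displacement (cm)")
}

#' Plot a shift map
#'
#' @param object A `shift_map`.
#' @param ... Unused.
#' @return A ggplot of the per-frame (u, v) correction shifts.
#' @export
autoplot.shift_map <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", "u_px", "v_px", "filled")],
    c("u_px", "v_px"), names_to = "axis", values_to = "px")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$px,
                                  color = .data$filled)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "shift (px)", color = "interpolated")
}

#' Plot a central slice of a reconstructed volume
#'
#' @param object A `cbct_volume`.
#' @param axis Slice normal: 1 (x), 2 (y) or 3 (z, default — axial).
#' @param index Slice index; default the central slice.
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @export
autoplot.cbct_volume <- function(object, axis = 3, index = NULL, ...) {
  d <- dim(object)
  if (is.null(index)) index <- ceiling(d[axis] / 2)
  sl <- switch(axis, object[index, , ], object[, index, ],
               object[, , index])
  ax <- setdiff(1:3, axis)
  g1 <- volume_axis_cm(object, ax[1])
  g2 <- volume_axis_cm(object, ax[2])
  df <- tibble::tibble(
    a = rep(g1, times = length(g2)),
    b = rep(g2, each = length(g1)),
    v = as.vector(sl))
  lab <- c("x (cm)", "y (cm)", "z (cm)")
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = lab[ax[1]], y = lab[ax[2]], fill = NULL)
}
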