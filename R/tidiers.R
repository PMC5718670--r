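#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per parameter with its estimate; `glance()` a
#' one-row fit summary.
#'
#' @param x A `stationary_fit` or `sinusoid_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name cbct-tidiers
NULL

#' @rdname cbct-tidiers
#' @export
tidy.stationary_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_cm", "alpha_deg", "beta_deg"),
    estimate = c(x$r_cm, x$alpha_rad * 180 / pi, x$beta_rad * 180 / pi))
}

#' @rdname cbct-tidiers
#' @export
glance.stationary_fit <- function(x, ...) {
  tibble::tibble(residual_rms_px = x$residual_rms_px, n_points = x$n_points,
                 span_deg = x$span_deg, iterations = x$iterations,
                 cost = x$cost)
}

#' @rdname cbct-tidiers
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude_cm", "frequency_hz", "frequency_cpm", "phase_rad"),
    estimate = c(x$a_cm, x$f_hz, x$f_hz * 60, x$phase_rad))
}

#' @rdname cbct-tidiers
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble::tibble(rms_cm = x$rms_cm, n = x$n, flat = x$flat)
}

#' Tidy a set of per-axis sinusoid fits
#'
#' @param fits Named list (`x`, `y`, `z`) from [fit_motion_sinusoids()].
#' @return Tibble with one row per axis: amplitude (cm), frequency (Hz and
#'   cycles/min), phase (rad), fit RMS.
#' @export
tidy_motion_fits <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(ax) {
    f <- fits[[ax]]
    tibble::tibble(axis = ax, a_cm = f$a_cm, f_hz = f$f_hz,
                   f_cpm = f$f_hz * 60, phase_rad = f$phase_rad,
                   rms_cm = f$rms_cm, flat = f$flat)
  }))
}
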