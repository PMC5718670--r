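#' Build a per-frame shift map from detector residuals
#'
#' The tracked marker's detector-frame motion offsets (dj, dk) become the
#' transformation vector (u, v) applied to every pixel of the corresponding
#' frame. Frames without an estimate (marker out of view, tracking failure)
#' are filled by linear interpolation in time with endpoints held, and
#' flagged.
#'
#' @param residuals Tibble from [detector_residuals()] (`frame`, `time_s`,
#'   `dj_px`, `dk_px`).
#' @param schedule The full acquisition schedule tibble (`frame`, `time_s`,
#'   `theta_deg`).
#' @return A `shift_map` tibble: `frame`, `time_s`, `theta_deg`, `u_px`,
#'   `v_px`, `filled`.
#' @export
shiftmap_from_residuals <- function(residuals, schedule) {
  schedule <- validate_schedule(schedule)
  res <- dplyr::filter(residuals, is.finite(.data$dj_px), is.finite(.data$dk_px))
  if (nrow(res) < nrow(schedule) / 2) {
    stop("residual estimates cover fewer than half the frames")
  }
  u <- stats::approx(res$time_s, res$dj_px, xout = schedule$time_s,
                     rule = 2)$y
  v <- stats::approx(res$time_s, res$dk_px, xout = schedule$time_s,
                     rule = 2)$y
  out <- tibble::tibble(
    frame = schedule$frame, time_s = schedule$time_s,
    theta_deg = schedule$theta_deg,
    u_px = u, v_px = v,
    filled = !(schedule$frame %in% res$frame))
  class(out) <- c("shift_map", class(out))
  out
}

#' Shift one projection frame by its motion offset
#'
#' Resamples the frame so that content seen at the mobile position
#' `(jm, km)` moves to the stationary position `(jm - u, km - v)`:
#' output pixel `(j, k)` takes the input value at `(j + u, k + v)` by
#' bilinear interpolation. Out-of-support samples take edge values; an
#' integer `(u, v)` is an exact pixel shift.
#'
#' @param frame Numeric matrix (row = k, column = j).
#' @param u,v Shift in pixels along j (columns) and k (rows).
#' @return The remapped frame, same dimensions.
#' @export
remap_projection <- function(frame, u, v) {
  stopifnot(is.finite(u), is.finite(v))
  nr <- nrow(frame); nc <- ncol(frame)
  if (abs(u) > nc || abs(v) > nr) {
    stop("shift exceeds the frame size")
  }
  if (u == 0 && v == 0) return(frame)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  jj <- seq_len(nc) + u          # source column coordinate (1-based)
  kk <- seq_len(nr) + v
  j0 <- floor(jj); fj <- jj - j0
  k0 <- floor(kk); fk <- kk - k0
  j0c <- clamp(j0, nc); j1c <- clamp(j0 + 1L, nc)
  k0c <- clamp(k0, nr); k1c <- clamp(k0 + 1L, nr)
  wj0 <- 1 - fj; wj1 <- fj
  wk0 <- 1 - fk; wk1 <- fk
  # separable bilinear gather: rows then columns
  a <- frame[k0c, , drop = FALSE] * wk0 + frame[k1c, , drop = FALSE] * wk1
  out <- a[, j0c, drop = FALSE] * rep(wj0, each = nr) +
    a[, j1c, drop = FALSE] * rep(wj1, each = nr)
  out
}

#' Apply a shift map to a whole projection stack
#'
#' Shifts every pixel of each frame by that frame's (u, v) — the rigid-body
#' assumption: the region around the tracked marker moves with it, so one
#' marker's offsets correct the full frame. Metadata and geometry are
#' preserved; the ground-truth table (if any) is dropped because it refers
#' to the uncorrected positions.
#'
#' @param stack A [projection_stack()].
#' @param shiftmap A `shift_map` with one row per frame of `stack`.
#' @return The corrected `projection_stack` (provenance recorded in the
#'   `"correction"` attribute).
#' @export
correct_stack <- function(stack, shiftmap) {
  stopifnot(inherits(stack, "projection_stack"))
  if (nrow(shiftmap) != length(stack$frames) ||
      !all(shiftmap$frame == stack$meta$frame)) {
    stop("shift map does not match the stack's frames")
  }
  frames <- lapply(seq_along(stack$frames), function(i) {
    remap_projection(stack$frames[[i]], shiftmap$u_px[i], shiftmap$v_px[i])
  })
  out <- projection_stack(frames, stack$meta, stack$geom,
                          background = stack$background, truth = NULL)
  attr(out, "correction") <- list(applied = TRUE,
                                  n_filled = sum(shiftmap$filled))
  out
}

#' Read/write a shift map as CSV
#'
#' Columns `frame,u_px,v_px,flag` (`flag` 1 = interpolated entry).
#'
#' @param shiftmap A `shift_map`.
#' @param path File path.
#' @param schedule Schedule tibble to rebuild time/angle columns on read.
#' @return `read_shiftmap()` returns a `shift_map`; `write_shiftmap()` the
#'   path, invisibly.
#' @export
write_shiftmap <- function(shiftmap, path) {
  utils::write.csv(
    data.frame(frame = shiftmap$frame, u_px = shiftmap$u_px,
               v_px = shiftmap$v_px, flag = as.integer(shiftmap$filled)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shiftmap
#' @export
read_shiftmap <- function(path, schedule) {
  schedule <- validate_schedule(schedule)
  d <- utils::read.csv(path)
  out <- dplyr::left_join(schedule, tibble::as_tibble(d), by = "frame")
  out <- dplyr::mutate(out, filled = .data$flag == 1, flag = NULL)
  class(out) <- c("shift_map", class(out))
  out
}
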