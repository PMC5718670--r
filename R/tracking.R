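#' Extract a marker template from a projection frame
#'
#' Crops a region of interest around a marker from one frame and returns it
#' mean-subtracted, ready for zero-normalized cross-correlation (ZNCC)
#' matching. The ROI is given by its center pixel and half-sizes, so the
#' patch always has odd dimensions.
#'
#' @param stack A [projection_stack()].
#' @param frame Frame index (1-based) to cut the template from.
#' @param roi List/vector with `j_px`, `k_px` (0-based center pixel) and
#'   `half_w`, `half_h` (half-extent in pixels); the patch is
#'   `(2*half_h+1) x (2*half_w+1)`.
#' @param center `"blob"` (default): estimate the marker's subpixel offset
#'   from the patch center by the intensity-weighted centroid of the dark
#'   blob, so matched positions report the marker center rather than the
#'   integer ROI center (the ROI is drawn on a pixel grid, but the marker
#'   rarely sits exactly on it); `"patch"`: no offset correction.
#' @return A `ncc_template`: list with `patch` (mean-subtracted matrix),
#'   `source_frame`, `center` (the nominal `c(j_px, k_px)`) and `offset`
#'   (subpixel `c(dj, dk)` of the marker inside the patch).
#' @export
extract_template <- function(stack, frame, roi, center = c("blob", "patch")) {
  center <- match.arg(center)
  stopifnot(inherits(stack, "projection_stack"),
            frame >= 1, frame <= length(stack$frames))
  roi <- as.list(roi)
  j0 <- roi$j_px; k0 <- roi$k_px; hw <- roi$half_w; hh <- roi$half_h
  f <- stack$frames[[frame]]
  jr <- (j0 - hw):(j0 + hw)
  kr <- (k0 - hh):(k0 + hh)
  if (min(jr) < 0 || max(jr) >= ncol(f) || min(kr) < 0 || max(kr) >= nrow(f)) {
    stop("ROI extends outside the frame")
  }
  patch <- f[kr + 1, jr + 1, drop = FALSE]
  if (stats::sd(patch) == 0) {
    stop("ROI has zero intensity variance; NCC is undefined for a flat template")
  }
  patch <- patch - mean(patch)
  offset <- c(dj = 0, dk = 0)
  if (center == "blob") {
    w <- pmax(-patch, 0)   # markers are attenuators: the blob is the dark part
    if (sum(w) > 0) {
      offset <- c(
        dj = sum(w * rep(jr - j0, each = length(kr))) / sum(w),
        dk = sum(w * rep(kr - k0, times = length(jr))) / sum(w))
    }
  }
  structure(list(patch = patch, source_frame = frame,
                 center = c(j_px = j0, k_px = k0), offset = offset),
            class = "ncc_template")
}

# 2D box sums of all tr x tc windows of W (integral-image based).
box_sum <- function(w, tr, tc) {
  cs <- apply(rbind(0, w), 2, cumsum)
  s_rows <- cs[(tr + 1):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - tr), , drop = FALSE]
  cs2 <- t(apply(cbind(0, s_rows), 1, cumsum))
  cs2[, (tc + 1):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - tc), drop = FALSE]
}

#' Zero-normalized cross-correlation map
#'
#' Scores every full placement of the (mean-subtracted) template inside the
#' window. The numerator is computed by FFT cross-correlation and the local
#' window statistics by integral images (fast normalized cross-correlation);
#' flat windows (zero local variance) score `NA`.
#'
#' @param window Numeric matrix (search region).
#' @param patch Numeric matrix, mean-subtracted template, dims not exceeding
#'   `window`.
#' @return Matrix of ZNCC scores in `[-1, 1]`, one entry per valid top-left
#'   placement (dims `nrow(window)-nrow(patch)+1` by
#'   `ncol(window)-ncol(patch)+1`).
#' @export
zncc_map <- function(window, patch) {
  tr <- nrow(patch); tc <- ncol(patch)
  nr <- nrow(window); nc <- ncol(window)
  stopifnot(tr <= nr, tc <= nc)
  t0 <- patch - mean(patch)
  t_norm <- sqrt(sum(t0^2))
  if (t_norm == 0) stop("template has zero variance")
  pr <- nr + tr - 1; pc <- nc + tc - 1
  wp <- matrix(0, pr, pc); wp[1:nr, 1:nc] <- window
  tp <- matrix(0, pr, pc); tp[1:tr, 1:tc] <- t0
  num_full <- Re(stats::fft(stats::fft(wp) * Conj(stats::fft(tp)),
                            inverse = TRUE)) / (pr * pc)
  num <- num_full[1:(nr - tr + 1), 1:(nc - tc + 1), drop = FALSE]
  n <- tr * tc
  s1 <- box_sum(window, tr, tc)
  s2 <- box_sum(window^2, tr, tc)
  var_w <- pmax(s2 - s1^2 / n, 0)
  denom <- sqrt(var_w) * t_norm
  out <- num / denom
  out[denom < 1e-12 * t_norm] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Locate a template in a frame by NCC
#'
#' Finds the ZNCC maximum of the template inside a search window and refines
#' it to subpixel precision by fitting a quadratic surface to the 3x3 score
#' neighborhood of the integer peak (skipped, with a flag, when the peak
#' lies on the window border). The returned score is the integer-peak ZNCC
#' value.
#'
#' @param frame Numeric matrix (a projection frame).
#' @param template A `ncc_template` from [extract_template()].
#' @param search_window List/vector `j_px`, `k_px` (0-based window center)
#'   and `half_w`, `half_h`; `NULL` searches the whole frame.
#' @return List with `j_px`, `k_px` (0-based, subpixel, corrected by the
#'   template's internal blob offset so they locate the marker center),
#'   `score` (`NA` if the window is flat), and `border` (logical: peak on
#'   window border, refinement skipped).
#' @export
ncc_match <- function(frame, template, search_window = NULL) {
  patch <- template$patch
  tr <- nrow(patch); tc <- ncol(patch)
  hh <- (tr - 1) / 2; hw <- (tc - 1) / 2
  if (is.null(search_window)) {
    j_lo <- 0; k_lo <- 0
    win <- frame
  } else {
    sw <- as.list(search_window)
    j_lo <- sw$j_px - sw$half_w; j_hi <- sw$j_px + sw$half_w
    k_lo <- sw$k_px - sw$half_h; k_hi <- sw$k_px + sw$half_h
    if (j_lo < 0 || k_lo < 0 || j_hi >= ncol(frame) || k_hi >= nrow(frame)) {
      stop("search window extends outside the frame")
    }
    if (j_hi - j_lo + 1 < tc || k_hi - k_lo + 1 < tr) {
      stop("search window smaller than the template")
    }
    win <- frame[(k_lo:k_hi) + 1, (j_lo:j_hi) + 1, drop = FALSE]
  }
  sc <- zncc_map(win, patch)
  if (all(is.na(sc))) {
    return(list(j_px = NA_real_, k_px = NA_real_, score = NA_real_,
                border = FALSE))
  }
  pk <- which(sc == max(sc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  a <- pk[1]; b <- pk[2]
  border <- a == 1 || b == 1 || a == nrow(sc) || b == ncol(sc)
  dj <- dk <- 0
  if (!border) {
    nb <- sc[(a - 1):(a + 1), (b - 1):(b + 1)]
    if (!anyNA(nb)) {
      off <- quad_peak_offset(nb)
      dk <- off[1]; dj <- off[2]
    }
  }
  off <- template$offset
  if (is.null(off)) off <- c(0, 0)
  list(j_px = unname(j_lo + (b - 1) + hw + dj + off[[1]]),
       k_px = unname(k_lo + (a - 1) + hh + dk + off[[2]]),
       score = unname(sc[a, b]), border = border)
}

# Subpixel offset (row, col) of the peak of a quadratic fit to a 3x3 patch.
# Least-squares fit of c0+c1x+c2y+c3x^2+c4y^2+c5xy; offsets clamped to
# +-0.5 px (the true peak cannot be farther from the integer maximum).
quad_peak_offset <- function(s) {
  grid <- expand.grid(y = c(-1, 0, 1), x = c(-1, 0, 1))
  z <- as.vector(s)                 # column-major: rows (y) fastest
  X <- cbind(1, grid$x, grid$y, grid$x^2, grid$y^2, grid$x * grid$y)
  cf <- qr.solve(X, z)
  h <- matrix(c(2 * cf[4], cf[6], cf[6], 2 * cf[5]), 2)
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev >= 0)) return(c(0, 0))  # not a maximum; keep integer peak
  d <- solve(h, -c(cf[2], cf[3]))    # (dx, dy)
  c(max(-0.5, min(0.5, d[2])), max(-0.5, min(0.5, d[1])))
}

new_marker_track <- function(tbl, geom = NULL) {
  tbl <- tibble::as_tibble(tbl)
  class(tbl) <- c("marker_track", class(tbl))
  attr(tbl, "geom") <- geom
  tbl
}

#' Track a marker through a projection stack
#'
#' Runs [ncc_match()] frame by frame. The search window is centered on the
#' previous accepted position (first frame: the whole image, or `seed_px`);
#' frames whose best score falls below `min_score`, whose window is flat, or
#' whose peak sits on the window border are recorded with status
#' `"missing"` — this is how a marker that leaves the field of view in
#' half-fan style scans shows up.
#'
#' @param stack A [projection_stack()].
#' @param template A `ncc_template`.
#' @param min_score Minimum accepted ZNCC score (default 0.5).
#' @param search_half Half-size `c(j, k)` of the search window in px;
#'   default 1.5x the template size (window ~4x template area).
#' @param seed_px Optional `c(j_px, k_px)` starting position for frame 1.
#' @return A `marker_track` tibble: `frame`, `time_s`, `theta_deg`,
#'   `jm_px`, `km_px`, `score`, `status` (`detected`/`missing`).
#' @export
track_stack <- function(stack, template, min_score = 0.5,
                        search_half = NULL, seed_px = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  n <- length(stack$frames)
  if (n == 0) {
    return(new_marker_track(tibble::tibble(
      frame = integer(), time_s = double(), theta_deg = double(),
      jm_px = double(), km_px = double(), score = double(),
      status = character()), stack$geom))
  }
  tr <- nrow(template$patch); tc <- ncol(template$patch)
  if (is.null(search_half)) {
    search_half <- c(j = ceiling(1.5 * tc), k = ceiling(1.5 * tr))
  }
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  last <- seed_px
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- stack$frames[[i]]
    win <- NULL
    if (!is.null(last)) {
      jc <- round(last[1]); kc <- round(last[2])
      hw <- search_half[1]; hh <- search_half[2]
      # clamp the window inside the frame, keeping its size
      jc <- min(max(jc, hw), nc - 1 - hw)
      kc <- min(max(kc, hh), nr - 1 - hh)
      win <- list(j_px = jc, k_px = kc, half_w = hw, half_h = hh)
    }
    m <- ncc_match(f, template, win)
    ok <- !is.na(m$score) && m$score >= min_score && !m$border
    if (ok) last <- c(m$j_px, m$k_px)
    out[[i]] <- tibble::tibble(
      frame = stack$meta$frame[i], time_s = stack$meta$time_s[i],
      theta_deg = stack$meta$theta_deg[i],
      jm_px = if (ok) m$j_px else NA_real_,
      km_px = if (ok) m$k_px else NA_real_,
      score = m$score,
      status = if (ok) "detected" else "missing")
  }
  new_marker_track(dplyr::bind_rows(out), stack$geom)
}

#' Flag tracking outliers
#'
#' Detected points whose residual from a running median of `jm_px` or
#' `km_px` exceeds `n_mad` robust deviations are relabeled `"outlier"`
#' (tracking failures on shadows that mimic the marker). The robust scale
#' is the MAD of the running-median residuals with a physical floor of
#' `floor_px` so that smooth noise-free tracks are never flagged.
#'
#' @param track A `marker_track`.
#' @param window Running-median window in frames (odd, default 11).
#' @param n_mad Threshold in robust deviations (default 5).
#' @param floor_px Minimum scale in px (default 0.5, the tracking precision).
#' @return The track with outliers relabeled (`jm_px`/`km_px` kept for
#'   inspection but status `"outlier"`).
#' @export
flag_outliers <- function(track, window = 11, n_mad = 5, floor_px = 0.5) {
  det <- which(track$status == "detected")
  if (length(det) < 5) {
    warning("fewer than 5 detected points; outlier pass skipped")
    return(track)
  }
  window <- min(window, length(det) - (1 - length(det) %% 2))
  if (window %% 2 == 0) window <- window - 1
  bad <- rep(FALSE, length(det))
  for (col in c("jm_px", "km_px")) {
    v <- track[[col]][det]
    res <- v - stats::runmed(v, window, endrule = "median")
    # robust scale: MAD degenerates to 0 on noise-free tracks (the running
    # median reproduces most samples exactly), so back it up with a
    # quantile-based estimate that still sees the smooth-motion residuals
    scale <- max(stats::mad(res),
                 stats::quantile(abs(res), 0.9, names = FALSE) / 1.645,
                 floor_px)
    bad <- bad | abs(res) > n_mad * scale
  }
  track$status[det[bad]] <- "outlier"
  track
}

#' Fill tracking gaps by piecewise-cubic interpolation
#'
#' Missing and outlier frames strictly inside the detected support are
#' filled on `jm_px(t)` and `km_px(t)` with a natural cubic spline through
#' the detected points, and relabeled `"interpolated"` (score cleared).
#' Leading and trailing gaps are never extrapolated, and gaps longer than
#' `max_gap_s` are left missing — cyclic respiration interpolates well, but
#' sudden non-cyclic motion cannot be predicted this way.
#'
#' @param track A `marker_track`.
#' @param max_gap_s Longest bracketed gap to fill, seconds (default 5).
#' @return The track with fillable rows interpolated.
#' @export
interpolate_gaps <- function(track, max_gap_s = 5) {
  det <- which(track$status == "detected")
  fill <- which(track$status %in% c("missing", "outlier"))
  if (length(det) < 2 || length(fill) == 0) return(track)
  t_det <- track$time_s[det]
  fill <- fill[track$time_s[fill] > min(t_det) &
               track$time_s[fill] < max(t_det)]
  if (!length(fill)) return(track)
  # bracketing gap length per candidate
  idx_prev <- findInterval(track$time_s[fill], t_det)
  gap <- t_det[idx_prev + 1] - t_det[idx_prev]
  fill <- fill[gap <= max_gap_s]
  if (!length(fill)) return(track)
  sj <- stats::splinefun(t_det, track$jm_px[det], method = "natural")
  sk <- stats::splinefun(t_det, track$km_px[det], method = "natural")
  track$jm_px[fill] <- sj(track$time_s[fill])
  track$km_px[fill] <- sk(track$time_s[fill])
  track$score[fill] <- NA_real_
  track$status[fill] <- "interpolated"
  track
}

#' Read/write a marker track as CSV
#'
#' Columns `frame,time_s,theta_deg,jm_px,km_px,score,status`; pixel
#' positions are 0-based.
#'
#' @param track A `marker_track`.
#' @param path File path.
#' @return `read_track()` returns a `marker_track`; `write_track()` the
#'   path, invisibly.
#' @export
write_track <- function(track, path) {
  utils::write.csv(
    as.data.frame(track)[, c("frame", "time_s", "theta_deg", "jm_px",
                             "km_px", "score", "status")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  new_marker_track(tibble::as_tibble(utils::read.csv(path)))
}
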