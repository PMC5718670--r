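# Detector-model helper: stationary track (in px) of spherical (r, alpha,
# beta) over a vector of gantry angles. Shared by the fitting cost and the
# fitted-values table so they agree exactly.
stationary_model_px <- function(r, alpha, beta, theta_deg, geom) {
  rho <- r * sin(beta)
  z <- r * cos(beta)
  th <- theta_deg * pi / 180
  d <- geom$sad - rho * cos(alpha - th)
  j_cm <- geom$sid * rho * sin(alpha - th) / d
  k_cm <- geom$sid * z / d
  cm_to_px(j_cm, k_cm, geom)
}

usable_rows <- function(track, interp_weight = 0.5) {
  idx <- which(track$status %in% c("detected", "interpolated"))
  w <- ifelse(track$status[idx] == "interpolated", interp_weight, 1)
  list(idx = idx, w = w)
}

#' Fit the stationary sinogram track of a marker
#'
#' Recovers the stationary spherical coordinates (r, alpha, beta) of a
#' marker from its measured detector track by damped least squares
#' (Levenberg--Marquardt), minimizing the summed squared detector residuals
#' \eqn{\sum (j_m - j_s)^2 + (k_m - k_s)^2} over usable (detected or
#' interpolated) frames. For a marker oscillating about a rest position the
#' fit converges to (approximately) the rest position, and the residuals
#' isolate the motion.
#'
#' Initialization is a coarse grid search over alpha (0..350 deg, step 10),
#' beta (10..170 deg, step 10) and r (1..25 cm, step 2) to avoid local
#' minima; the returned optimum never scores worse than the best grid node.
#' Interpolated points enter the cost with weight `interp_weight`.
#'
#' @param track A `marker_track` (pixel coordinates).
#' @param geom The [scan_geometry()] of the acquisition.
#' @param init Optional `c(r_cm, alpha_rad, beta_rad)` overriding the grid
#'   search.
#' @param interp_weight Weight of interpolated points (default 0.5).
#' @param max_iter Levenberg--Marquardt iteration cap (default 200).
#' @return A `stationary_fit`: `r_cm`, `alpha_rad`, `beta_rad`, the implied
#'   [patient_point()], `fitted` (per-frame `js_px`, `ks_px`), residual RMS
#'   in px, iterations, final and grid costs.
#' @export
fit_stationary <- function(track, geom, init = NULL, interp_weight = 0.5,
                           max_iter = 200) {
  u <- usable_rows(track, interp_weight)
  if (length(u$idx) < 10) stop("need at least 10 usable track points")
  th <- track$theta_deg[u$idx]
  span <- diff(range(th))
  if (span < 90) {
    stop(sprintf("angular span of usable points (%.1f deg) is below 90 deg; the stationary fit is ill-conditioned", span))
  }
  jm <- track$jm_px[u$idx]; km <- track$km_px[u$idx]
  sw <- sqrt(u$w)
  resid_fun <- function(par) {
    m <- stationary_model_px(par[1], par[2], par[3], th, geom)
    c(sw * (jm - m$j_px), sw * (km - m$k_px))
  }
  cost_fun <- function(par) sum(resid_fun(par)^2)

  grid_cost_min <- Inf
  if (is.null(init)) {
    grid <- expand.grid(r = seq(1, 25, by = 2),
                        alpha = seq(0, 350, by = 10) * pi / 180,
                        beta = seq(10, 170, by = 10) * pi / 180)
    costs <- vapply(seq_len(nrow(grid)), function(i) {
      cost_fun(c(grid$r[i], grid$alpha[i], grid$beta[i]))
    }, numeric(1))
    best <- which.min(costs)
    grid_cost_min <- costs[best]
    init <- c(grid$r[best], grid$alpha[best], grid$beta[best])
  }
  fit <- minpack.lm::nls.lm(
    par = init, fn = resid_fun,
    lower = c(0, -Inf, 0), upper = c(Inf, Inf, pi),
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-14, ptol = 1e-14))
  if (!(fit$info %in% 1:4)) {
    cond <- structure(
      class = c("cbct_nonconvergence", "error", "condition"),
      list(message = paste0("stationary fit did not converge (", fit$message, ")"),
           call = sys.call(), best = fit$par))
    stop(cond)
  }
  par <- fit$par
  if (cost_fun(par) > grid_cost_min) par <- init  # never worse than the grid
  r <- par[1]; alpha <- par[2] %% (2 * pi); beta <- par[3]
  m_all <- stationary_model_px(r, alpha, beta, track$theta_deg, geom)
  res <- resid_fun(c(r, alpha, beta))
  structure(list(
    r_cm = r, alpha_rad = alpha, beta_rad = beta,
    point = patient_point_spherical(r, alpha, beta),
    fitted = tibble::tibble(frame = track$frame, time_s = track$time_s,
                            theta_deg = track$theta_deg,
                            js_px = m_all$j_px, ks_px = m_all$k_px),
    residual_rms_px = sqrt(mean(res^2)),
    n_points = length(u$idx), span_deg = span,
    iterations = fit$niter, cost = sum(res^2),
    grid_cost_min = grid_cost_min,
    geom = geom
  ), class = "stationary_fit")
}

#' @export
print.stationary_fit <- function(x, ...) {
  cat(sprintf(
    "<stationary_fit> r = %.4g cm, alpha = %.4g deg, beta = %.4g deg\n",
    x$r_cm, x$alpha_rad * 180 / pi, x$beta_rad * 180 / pi))
  cat(sprintf("  residual RMS %.4g px over %d points (%.0f deg span, %d LM iterations)\n",
              x$residual_rms_px, x$n_points, x$span_deg, x$iterations))
  invisible(x)
}

#' Detector-frame motion residuals
#'
#' Subtracts the fitted stationary track from the measured track:
#' `dj = jm - js`, `dk = km - ks` per usable frame. These are the per-frame
#' (u, v) shifts consumed by the projection-correction stage.
#'
#' @param track A `marker_track`.
#' @param fit A `stationary_fit` for the same track.
#' @return Tibble `frame`, `time_s`, `theta_deg`, `dj_px`, `dk_px`,
#'   `status`, restricted to usable frames.
#' @export
detector_residuals <- function(track, fit) {
  u <- usable_rows(track)
  idx <- u$idx
  tibble::tibble(
    frame = track$frame[idx], time_s = track$time_s[idx],
    theta_deg = track$theta_deg[idx],
    dj_px = track$jm_px[idx] - fit$fitted$js_px[idx],
    dk_px = track$km_px[idx] - fit$fitted$ks_px[idx],
    status = track$status[idx])
}

#' Patient-frame displacement trace
#'
#' Inverts the projection equations per frame to express marker motion in
#' the fixed patient frame. A single monoscopic view cannot determine a full
#' 3D displacement, so the inversion holds the in-plane polar angle at its
#' fitted stationary value when mapping `j` to (x, y), and uses the fitted
#' stationary radial depth in the denominator when mapping `k` to z:
#' \deqn{\Delta z' = c\,(k_m - k_s)\,(1 - \rho_s\cos(\alpha-\theta)/SAD).}
#' In-plane inversion is ill-conditioned near the blind spot where the
#' marker lies on the source--isocenter axis (\eqn{\sin(\alpha-\theta)
#' \approx 0}); frames within `blind_deg` of it get `NA` in-plane
#' displacements (flag `blind_spot`) while the superior--inferior component
#' is computed everywhere.
#'
#' @param track A `marker_track`.
#' @param fit Its `stationary_fit`.
#' @param geom The [scan_geometry()].
#' @param blind_deg Half-width of the in-plane blind zone in degrees
#'   (default 5).
#' @return A `motion_trace` tibble: `frame`, `time_s`, `theta_deg`,
#'   `dx_cm`, `dy_cm`, `dz_cm`, `flag` (`ok`/`blind_spot`/`dropped`).
#' @export
to_patient_displacements <- function(track, fit, geom, blind_deg = 5) {
  u <- usable_rows(track)
  idx <- u$idx
  th <- track$theta_deg[idx] * pi / 180
  alpha <- fit$alpha_rad
  rho_s <- fit$r_cm * sin(fit$beta_rad)
  jm <- px_to_cm(track$jm_px[idx], track$km_px[idx], geom)
  js <- px_to_cm(fit$fitted$js_px[idx], fit$fitted$ks_px[idx], geom)
  s <- sin(alpha - th); cth <- cos(alpha - th)
  # in-plane: invert j -> rho at fixed alpha, for mobile and stationary
  inv_rho <- function(j_cm) geom$sad * j_cm / (geom$sid * s + j_cm * cth)
  rho_m <- inv_rho(jm$j_cm)
  rho_s_inv <- inv_rho(js$j_cm)
  dx <- (rho_m - rho_s_inv) * sin(alpha)
  dy <- (rho_m - rho_s_inv) * cos(alpha)
  blind <- abs(s) < sin(blind_deg * pi / 180)
  dx[blind] <- NA_real_; dy[blind] <- NA_real_
  # superior-inferior: stationary depth denominator
  d_s <- geom$sad - rho_s * cth
  dz <- geom$c * (jm$k_cm - js$k_cm) * d_s / geom$sad
  dropped <- d_s <= 0 | (!blind & (rho_m >= geom$sad | rho_m < -geom$sad))
  dz[dropped] <- NA_real_
  dx[dropped] <- NA_real_; dy[dropped] <- NA_real_
  out <- tibble::tibble(
    frame = track$frame[idx], time_s = track$time_s[idx],
    theta_deg = track$theta_deg[idx],
    dx_cm = dx, dy_cm = dy, dz_cm = dz,
    flag = dplyr::case_when(dropped ~ "dropped",
                            blind ~ "blind_spot",
                            TRUE ~ "ok"))
  class(out) <- c("motion_trace", class(out))
  attr(out, "fit") <- fit
  out
}

#' Fit a sinusoid to one displacement axis
#'
#' Least-squares fit of \eqn{d(t) = A \sin(2\pi f t - \delta)} by
#' Levenberg--Marquardt. The frequency is initialized at the dominant peak
#' of the discrete spectrum (uniformly resampled periodogram), amplitude
#' and phase by linear regression on the quadrature pair at that frequency.
#' The result is canonicalized to `A >= 0`, `delta` in `[0, 2pi)`.
#'
#' @param time_s Sample times (s).
#' @param d_cm Displacements (cm); `NA`s are dropped.
#' @param min_periods Minimum number of full periods required (default 2).
#' @return A `sinusoid_fit`: `a_cm`, `f_hz`, `phase_rad`, `rms_cm`, `n`,
#'   `flat` (TRUE when the signal has no usable oscillation, in which case
#'   `a_cm = 0` and `f_hz` is `NA`).
#' @export
fit_sinusoid <- function(time_s, d_cm, min_periods = 2) {
  keep <- is.finite(time_s) & is.finite(d_cm)
  t <- time_s[keep]; d <- d_cm[keep]
  n <- length(t)
  if (n < 8) stop("need at least 8 finite samples")
  d0 <- d - mean(d)
  flat_fit <- function() {
    structure(list(a_cm = 0, f_hz = NA_real_, phase_rad = NA_real_,
                   rms_cm = stats::sd(d), n = n, flat = TRUE),
              class = "sinusoid_fit")
  }
  if (stats::sd(d) < 1e-12) return(flat_fit())
  # frequency seed from the periodogram of a uniform resampling
  ng <- 2^ceiling(log2(max(n, 64)))
  tg <- seq(min(t), max(t), length.out = ng)
  dg <- stats::approx(t, d0, xout = tg)$y
  sp <- Mod(stats::fft(dg))[2:(ng %/% 2)]
  f0 <- (which.max(sp)) / (ng * (tg[2] - tg[1]))
  span <- max(t) - min(t)
  if (span * f0 < min_periods) {
    stop(sprintf("signal spans %.2f periods at the dominant frequency; need >= %g",
                 span * f0, min_periods))
  }
  quad_init <- function(f) {
    X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
    cf <- unname(stats::lm.fit(X, d0)$coefficients)
    c(a = sqrt(sum(cf^2)), delta = atan2(-cf[2], cf[1]))
  }
  q <- quad_init(f0)
  resid_fun <- function(par) par[1] * sin(2 * pi * par[2] * t - par[3]) - d
  fit <- minpack.lm::nls.lm(
    par = c(q[["a"]], f0, q[["delta"]]), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  a <- fit$par[1]; f <- fit$par[2]; delta <- fit$par[3]
  if (a < 0) { a <- -a; delta <- delta + pi }
  delta <- delta %% (2 * pi)
  structure(list(a_cm = a, f_hz = f, phase_rad = delta,
                 rms_cm = sqrt(mean(resid_fun(c(a, f, delta))^2)),
                 n = n, flat = FALSE),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  if (x$flat) {
    cat("<sinusoid_fit> flat signal (A = 0)\n")
  } else {
    cat(sprintf(
      "<sinusoid_fit> A = %.4g cm, f = %.4g Hz (%.4g cycles/min), delta = %.4g rad, RMS %.3g cm (n = %d)\n",
      x$a_cm, x$f_hz, x$f_hz * 60, x$phase_rad, x$rms_cm, x$n))
  }
  invisible(x)
}

#' Fit sinusoids to all three axes of a motion trace
#'
#' @param trace A `motion_trace` from [to_patient_displacements()].
#' @param min_periods Passed to [fit_sinusoid()].
#' @return Named list of `sinusoid_fit` objects (`x`, `y`, `z`). Axes whose
#'   signal is flat (or too short) come back with `a_cm = 0` / an error is
#'   avoided by returning the flat fit.
#' @export
fit_motion_sinusoids <- function(trace, min_periods = 2) {
  one <- function(col) {
    tryCatch(fit_sinusoid(trace$time_s, trace[[col]], min_periods),
             error = function(e) {
               structure(list(a_cm = 0, f_hz = NA_real_, phase_rad = NA_real_,
                              rms_cm = NA_real_,
                              n = sum(is.finite(trace[[col]])), flat = TRUE),
                         class = "sinusoid_fit")
             })
  }
  list(x = one("dx_cm"), y = one("dy_cm"), z = one("dz_cm"))
}

#' Correlate two motion traces
#'
#' Quantifies the agreement of (for example) an internal implanted and an
#' external skin marker: both traces are resampled onto a common uniform
#' timebase by linear interpolation; the zero-lag Pearson correlation, the
#' lag maximizing the cross-correlation, and the sinusoid phase difference
#' are returned. Internal and external markers often share the respiratory
#' frequency while differing in amplitude and phase.
#'
#' @param a,b `motion_trace` objects with overlapping time support.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param min_periods Minimum overlap, in periods of trace `a`'s dominant
#'   frequency (default 2).
#' @return List: `pearson_r` (zero lag), `lag_s` (lag of `b` relative to `a`
#'   maximizing cross-correlation), `phase_diff_rad` (`delta_a - delta_b`,
#'   wrapped to (-pi, pi]), `amplitude_ratio` (`A_a / A_b`), and the two
#'   `sinusoid_fit`s.
#' @export
correlate_tracks <- function(a, b, axis = c("z", "x", "y"),
                             min_periods = 2) {
  axis <- match.arg(axis)
  col <- paste0("d", axis, "_cm")
  ka <- is.finite(a[[col]]); kb <- is.finite(b[[col]])
  t0 <- max(min(a$time_s[ka]), min(b$time_s[kb]))
  t1 <- min(max(a$time_s[ka]), max(b$time_s[kb]))
  fa <- fit_sinusoid(a$time_s[ka], a[[col]][ka])
  fb <- fit_sinusoid(b$time_s[kb], b[[col]][kb])
  if (!is.finite(t1 - t0) || is.na(fa$f_hz) ||
      (t1 - t0) * fa$f_hz < min_periods) {
    stop("insufficient overlapping support between the traces")
  }
  dt <- stats::median(diff(a$time_s[ka]))
  tg <- seq(t0, t1, by = dt)
  ga <- stats::approx(a$time_s[ka], a[[col]][ka], xout = tg)$y
  gb <- stats::approx(b$time_s[kb], b[[col]][kb], xout = tg)$y
  r0 <- stats::cor(ga, gb)
  max_lag <- min(length(tg) - 2, ceiling(1 / (fa$f_hz * dt)))
  cc <- stats::ccf(ga, gb, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)
  lag_s <- cc$lag[which.max(cc$acf)] * dt
  dphi <- (fa$phase_rad - fb$phase_rad + pi) %% (2 * pi) - pi
  list(pearson_r = r0, lag_s = lag_s, phase_diff_rad = dphi,
       amplitude_ratio = fa$a_cm / fb$a_cm, fit_a = fa, fit_b = fb)
}

#' Subtract gantry-sag shifts from a marker track
#'
#' Gantry sag adds small angle-dependent detector shifts to every marker
#' sinogram; given a measured sag table they are removed before fitting.
#' Table values are linearly interpolated in gantry angle.
#'
#' @param track A `marker_track`.
#' @param sag_table Tibble `theta_deg`, `dj_px`, `dk_px`; must cover the
#'   track's angular range.
#' @return The track with `jm_px`/`km_px` corrected.
#' @export
subtract_sag <- function(track, sag_table) {
  sag_table <- tibble::as_tibble(sag_table)
  stopifnot(all(c("theta_deg", "dj_px", "dk_px") %in% names(sag_table)))
  rng <- range(track$theta_deg)
  if (min(sag_table$theta_deg) > rng[1] || max(sag_table$theta_deg) < rng[2]) {
    stop("sag table does not cover the schedule's angular range")
  }
  dj <- stats::approx(sag_table$theta_deg, sag_table$dj_px,
                      xout = track$theta_deg)$y
  dk <- stats::approx(sag_table$theta_deg, sag_table$dk_px,
                      xout = track$theta_deg)$y
  track$jm_px <- track$jm_px - dj
  track$km_px <- track$km_px - dk
  track
}

#' Write a motion trace / fit summary
#'
#' @param trace A `motion_trace`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    as.data.frame(trace)[, c("time_s", "dx_cm", "dy_cm", "dz_cm")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param fits Named list of `sinusoid_fit` (from [fit_motion_sinusoids()]).
#' @export
write_fit_summary <- function(fits, path) {
  out <- lapply(fits, function(f) {
    list(a_cm = f$a_cm, f_hz = f$f_hz, f_cpm = if (is.na(f$f_hz)) NA else f$f_hz * 60,
         phase_rad = f$phase_rad, rms_cm = f$rms_cm, n = f$n, flat = f$flat)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
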