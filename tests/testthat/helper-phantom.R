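# Shared synthetic fixtures. Heavy stacks are memoised so several test files
# can reuse the same simulated scan without re-rendering it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Moving-platform protocol: one seed marker at (r = 10 cm, alpha = 40 deg,
# beta = 90 deg) driven at 1.75 cm / 15 cycles per min along Z; reduced
# geometry, 360 frames over 360 deg in 60 s.
protocol_marker <- function() {
  marker_spec(patient_point_spherical(10, 40 * pi / 180, pi / 2),
              motion_waveform(a_z = 1.75, f_z = 15), id = "m1")
}

protocol_stack <- function(noise_sd = 0, seed = 1) {
  key <- sprintf("protocol_%g_%d", noise_sd, seed)
  cached(key, generate_scan(list(protocol_marker()), reduced_geometry(),
                            noise_sd = noise_sd, seed = seed))
}

protocol_result <- function(noise_sd = 0, seed = 1) {
  key <- sprintf("protocol_res_%g_%d", noise_sd, seed)
  cached(key, extract_marker_motion(protocol_stack(noise_sd, seed)))
}

# Exact (noiseless, analytic) marker track built from the projection model.
exact_track <- function(p, geom) {
  tr <- stationary_track(p, geom)
  new_track_tbl(tr$frame, tr$time_s, tr$theta_deg, tr$j_px, tr$k_px)
}

new_track_tbl <- function(frame, time_s, theta_deg, jm_px, km_px,
                          status = "detected") {
  tibble::tibble(frame = frame, time_s = time_s, theta_deg = theta_deg,
                 jm_px = jm_px, km_px = km_px, score = 1, status = status)
}

# Exact track of a marker moving along Z (uses the projection equations
# directly, no rendering / NCC involved).
exact_moving_track_z <- function(p_rest, wave, geom) {
  sch <- geom$schedule
  disp <- waveform_displacement(wave, sch$time_s)
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    p <- patient_point(p_rest$x + disp$dx_cm[i], p_rest$y + disp$dy_cm[i],
                       p_rest$z + disp$dz_cm[i])
    pr <- project_point(p, sch$theta_deg[i], geom)
    cm_to_px(pr$j_cm, pr$k_cm, geom)
  })
  px <- dplyr::bind_rows(rows)
  new_track_tbl(sch$frame, sch$time_s, sch$theta_deg, px$j_px, px$k_px)
}

# Brute-force per-offset zero-normalized cross-correlation (independent
# oracle for zncc_map): plain double loop, no FFT, no integral images.
zncc_loops <- function(window, patch) {
  tr <- nrow(patch); tc <- ncol(patch)
  t0 <- patch - mean(patch)
  tn <- sqrt(sum(t0^2))
  nr <- nrow(window) - tr + 1
  nc <- ncol(window) - tc + 1
  out <- matrix(NA_real_, nr, nc)
  for (a in seq_len(nr)) {
    for (b in seq_len(nc)) {
      w <- window[a:(a + tr - 1), b:(b + tc - 1)]
      wc <- w - mean(w)
      denom <- sqrt(sum(wc^2)) * tn
      if (denom > 0) out[a, b] <- sum(wc * t0) / denom
    }
  }
  out
}

# Closed-form two-view inversion of the projection equations (theta and
# theta + 90 deg): independent oracle for the fitting machinery.
two_view_invert <- function(j1, k1, j2, theta1_deg, geom) {
  sad <- geom$sad; sid <- geom$sid
  lat1 <- j1 * sad * (1 + j2 / sid) / (sid + j1 * j2 / sid)
  dep1 <- -j2 * (sad - lat1) / sid
  th1 <- theta1_deg * pi / 180
  # lat = rho*sin(alpha - theta), dep = rho*cos(alpha - theta)
  u <- atan2(lat1, dep1)
  alpha <- u + th1
  rho <- sqrt(lat1^2 + dep1^2)
  z <- k1 * (sad - dep1) / sid
  patient_point(rho * sin(alpha), rho * cos(alpha), z)
}
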