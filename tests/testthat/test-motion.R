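test_that("stationary fit recovers exact spherical coordinates from clean tracks", {
  geom <- reduced_geometry()
  for (cfg in list(c(10, 40, 40), c(20, 30, 30), c(30, 20, 20))) {
    p <- patient_point_spherical(cfg[1], cfg[2] * pi / 180, cfg[3] * pi / 180)
    fit <- fit_stationary(exact_track(p, geom), geom)
    expect_lt(fit$residual_rms_px, 1e-6)
    expect_equal(fit$r_cm, cfg[1], tolerance = 1e-6)
    expect_equal(fit$alpha_rad * 180 / pi, cfg[2], tolerance = 1e-5)
    expect_equal(fit$beta_rad * 180 / pi, cfg[3], tolerance = 1e-5)
    # optimum never worse than the initialization grid
    expect_lte(fit$cost, fit$grid_cost_min + 1e-9)
    # fitted values equal the model track of the implied point exactly
    mt <- stationary_track(fit$point, geom)
    expect_equal(fit$fitted$js_px, mt$j_px, tolerance = 1e-9)
  }
})

test_that("degenerate isocenter track fits to r = 0 and span checks guard identifiability", {
  geom <- reduced_geometry()
  fit <- fit_stationary(exact_track(patient_point(0, 0, 0), geom), geom)
  expect_lt(fit$r_cm, 1e-6)
  expect_lt(fit$residual_rms_px, 1e-9)

  p <- patient_point_spherical(10, 0.5, 1.0)
  narrow <- exact_track(p, reduced_geometry(n_frames = 40, arc_deg = 60))
  expect_error(fit_stationary(narrow, geom), "below 90 deg")
  expect_error(fit_stationary(exact_track(p, geom)[1:5, ], geom),
               "at least 10")
})

test_that("a moving marker's stationary fit lands on the rest position", {
  geom <- reduced_geometry()
  p <- patient_point_spherical(10, 40 * pi / 180, pi / 2)
  tr <- exact_moving_track_z(p, motion_waveform(a_z = 1.75, f_z = 15), geom)
  fit <- fit_stationary(tr, geom)
  # oracle: dense grid refinement of the identical cost around the optimum
  cost <- function(r, a, b) {
    m <- cbctmotion:::stationary_model_px(r, a, b, tr$theta_deg, geom)
    sum((tr$jm_px - m$j_px)^2 + (tr$km_px - m$k_px)^2)
  }
  g <- expand.grid(r = seq(9.5, 10.5, by = 0.05),
                   a = (40 + seq(-2, 2, by = 0.2)) * pi / 180,
                   b = (90 + seq(-2, 2, by = 0.2)) * pi / 180)
  cg <- mapply(cost, g$r, g$a, g$b)
  best <- g[which.min(cg), ]
  step <- c(0.05, 0.2 * pi / 180, 0.2 * pi / 180)
  expect_lt(abs(fit$r_cm - best$r), step[1] + 1e-9)
  expect_lt(abs(fit$alpha_rad - best$a), step[2] + 1e-9)
  expect_lt(abs(fit$beta_rad - best$b), step[3] + 1e-9)
  expect_lte(cost(fit$r_cm, fit$alpha_rad, fit$beta_rad), min(cg) + 1e-9)
})

test_that("detector residuals vanish for stationary markers and separate axes for Z motion", {
  geom <- reduced_geometry()
  p <- patient_point_spherical(10, 40 * pi / 180, pi / 2)
  fit0 <- fit_stationary(exact_track(p, geom), geom)
  res0 <- detector_residuals(exact_track(p, geom), fit0)
  expect_lt(max(abs(res0$dj_px)), 1e-8)
  expect_lt(max(abs(res0$dk_px)), 1e-8)

  tr <- exact_moving_track_z(p, motion_waveform(a_z = 1.75, f_z = 15), geom)
  fit <- fit_stationary(tr, geom)
  res <- detector_residuals(tr, fit)
  expect_lt(max(abs(res$dj_px)), 0.1)        # pure Z: no j residual
  expect_gt(diff(range(res$dk_px)), 10)      # strong sinusoidal k residual
})

test_that("patient-frame decomposition reproduces the injected waveform", {
  res <- protocol_result()
  st <- protocol_stack()
  truth <- st$truth
  trace <- res$trace
  ok <- trace$flag != "dropped"
  dev <- abs(trace$dz_cm[ok] - truth$dz_cm[trace$frame[ok]])
  expect_lt(max(dev), 0.026)  # < 2 x (0.5 px at isocenter) = 0.26 mm
  # stationary marker: zero displacement everywhere
  geom <- reduced_geometry()
  p <- patient_point_spherical(10, 40 * pi / 180, pi / 2)
  tr0 <- exact_track(p, geom)
  fit0 <- fit_stationary(tr0, geom)
  tr_zero <- to_patient_displacements(tr0, fit0, geom)
  expect_lt(max(abs(tr_zero$dz_cm)), 1e-8)
  expect_lt(max(abs(tr_zero$dx_cm), na.rm = TRUE), 1e-6)
})

test_that("sinusoid fitting is exact on clean samples and canonicalizes parameters", {
  t <- seq(0, 60, by = 1 / 6)
  d <- 1.75 * sin(2 * pi * 0.25 * t)
  f <- fit_sinusoid(t, d)
  expect_equal(f$a_cm, 1.75, tolerance = 1e-6)
  expect_equal(f$f_hz, 0.25, tolerance = 1e-6)
  expect_lt(f$rms_cm, 1e-8)

  # negative-amplitude input folds into phase, delta in [0, 2pi)
  d2 <- -0.8 * sin(2 * pi * 0.2 * t - 1)
  f2 <- fit_sinusoid(t, d2)
  expect_gte(f2$a_cm, 0)
  expect_gte(f2$phase_rad, 0)
  expect_lt(f2$phase_rad, 2 * pi)
  expect_equal(f2$a_cm, 0.8, tolerance = 1e-6)
  expect_equal(f2$phase_rad, (1 + pi) %% (2 * pi), tolerance = 1e-5)

  flat <- fit_sinusoid(t, rep(0, length(t)))
  expect_equal(flat$a_cm, 0)
  expect_true(flat$flat)
  expect_error(fit_sinusoid(t[1:20], d[1:20]), "periods")
})

test_that("sinusoid amplitude is unbiased under noise (Monte Carlo)", {
  t <- seq(0, 59.8, by = 0.2)  # n = 300
  a_hat <- vapply(1:100, function(s) {
    d <- withr::with_seed(1000 + s,
      1.2 * sin(2 * pi * 0.25 * t - 0.7) + rnorm(length(t), 0, 0.05))
    fit_sinusoid(t, d)$a_cm
  }, numeric(1))
  se <- sd(a_hat) / sqrt(length(a_hat))
  expect_lt(abs(mean(a_hat) - 1.2), 3 * se + 1e-6)
})

test_that("end-to-end amplitude/frequency recovery holds across the protocol envelope", {
  geom <- reduced_geometry()
  cases <- list(c(a = 2.0, f = 10, r = 5, al = 120),
                c(a = 1.0, f = 20, r = 15, al = 300),
                c(a = 0.8, f = 12, r = 10, al = 220))
  for (cs in cases) {
    p <- patient_point_spherical(cs[["r"]], cs[["al"]] * pi / 180, pi / 2)
    w <- motion_waveform(a_z = cs[["a"]], f_z = cs[["f"]], phase_z = 0.4)
    tr <- exact_moving_track_z(p, w, geom)
    fit <- fit_stationary(tr, geom)
    trace <- to_patient_displacements(tr, fit, geom)
    sf <- fit_sinusoid(trace$time_s, trace$dz_cm)
    expect_lt(abs(sf$a_cm - cs[["a"]]) / cs[["a"]], 0.01)
    expect_lt(abs(sf$f_hz * 60 - cs[["f"]]) / cs[["f"]], 0.005)
    # axis separation: cross-axis amplitude below 5% of the injected one
    for (ax in c("dx_cm", "dy_cm")) {
      v <- trace[[ax]][is.finite(trace[[ax]])]
      cross <- tryCatch(fit_sinusoid(trace$time_s[is.finite(trace[[ax]])], v)$a_cm,
                        error = function(e) max(abs(v)))
      expect_lt(cross, 0.05 * cs[["a"]])
    }
  }
})

test_that("trace correlation recovers phase shifts and amplitude ratios", {
  mk_trace <- function(a, delta, f = 0.25) {
    t <- seq(0, 60, by = 1 / 6)
    tb <- tibble::tibble(frame = seq_along(t), time_s = t, theta_deg = t * 6,
                         dx_cm = 0, dy_cm = 0,
                         dz_cm = a * sin(2 * pi * f * t - delta), flag = "ok")
    class(tb) <- c("motion_trace", class(tb))
    tb
  }
  a <- mk_trace(0.9, 0)
  self <- correlate_tracks(a, a, "z")
  expect_equal(self$pearson_r, 1)
  expect_equal(self$lag_s, 0)

  shifted <- correlate_tracks(a, mk_trace(0.9, pi / 2), "z")
  expect_equal(abs(shifted$phase_diff_rad), pi / 2, tolerance = 1e-3)
  expect_lt(abs(shifted$pearson_r), 0.1)

  # internal 9 mm vs external 1.5 mm, same frequency and phase
  pair <- correlate_tracks(mk_trace(0.9, 1.2), mk_trace(0.15, 1.2), "z")
  expect_gt(pair$pearson_r, 0.999)
  expect_equal(pair$amplitude_ratio, 6, tolerance = 1e-6)
  expect_error(correlate_tracks(a[1:5, ], a[1:5, ], "z"), "")
})

test_that("gantry-sag subtraction restores the stationary fit", {
  geom <- reduced_geometry()
  p <- patient_point_spherical(10, 0.7, 0.9)
  clean <- exact_track(p, geom)
  # second-harmonic sag: not absorbable by a stationary-track perturbation
  sag_tab <- tibble::tibble(theta_deg = seq(0, 360, by = 5))
  sag_tab$dj_px <- 1.5 * sin(2 * sag_tab$theta_deg * pi / 180)
  sag_tab$dk_px <- 0.8 * cos(2 * sag_tab$theta_deg * pi / 180)

  expect_equal(subtract_sag(clean, tibble::tibble(theta_deg = c(0, 360),
                                                  dj_px = 0, dk_px = 0))$jm_px,
               clean$jm_px)
  const <- subtract_sag(clean, tibble::tibble(theta_deg = c(0, 360),
                                              dj_px = 1, dk_px = 0))
  expect_equal(const$jm_px, clean$jm_px - 1)

  sagged <- clean
  sagged$jm_px <- sagged$jm_px +
    stats::approx(sag_tab$theta_deg, sag_tab$dj_px, sagged$theta_deg)$y
  sagged$km_px <- sagged$km_px +
    stats::approx(sag_tab$theta_deg, sag_tab$dk_px, sagged$theta_deg)$y
  rms_sagged <- fit_stationary(sagged, geom)$residual_rms_px
  rms_fixed <- fit_stationary(subtract_sag(sagged, sag_tab), geom)$residual_rms_px
  expect_gt(rms_sagged, 0.5)
  expect_lt(rms_fixed, 1e-6)
  expect_error(subtract_sag(clean, sag_tab[sag_tab$theta_deg < 180, ]),
               "cover")
})

test_that("tidiers expose fit parameters as tibbles", {
  res <- protocol_result()
  td <- generics::tidy(res$fit)
  expect_equal(td$term, c("r_cm", "alpha_deg", "beta_deg"))
  expect_equal(td$estimate[1], 10, tolerance = 0.01)
  gl <- generics::glance(res$fit)
  expect_true(all(c("residual_rms_px", "n_points") %in% names(gl)))
  tm <- tidy_motion_fits(res$sinusoids)
  expect_equal(nrow(tm), 3)
  expect_equal(tm$a_cm[tm$axis == "z"], 1.75, tolerance = 0.01)
})
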