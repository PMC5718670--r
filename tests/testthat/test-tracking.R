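test_that("template extraction validates its ROI", {
  geom <- reduced_geometry(n_frames = 4)
  mk <- marker_spec(patient_point(0, 0, 0), diameter_mm = 3, length_mm = 3)
  st <- generate_scan(list(mk), geom)
  ctr <- cm_to_px(0, 0, geom)
  roi <- list(j_px = round(ctr$j_px), k_px = round(ctr$k_px),
              half_w = 5, half_h = 5)
  tpl <- extract_template(st, 1, roi)
  expect_equal(dim(tpl$patch), c(11, 11))
  expect_equal(mean(tpl$patch), 0)
  # the dark blob minimum sits at the patch center (within the half-pixel
  # quantization of the ROI grid)
  pk <- which(tpl$patch == min(tpl$patch), arr.ind = TRUE)
  expect_lte(max(abs(pk[1, ] - 6)), 1)
  # flat ROI -> error; off-frame ROI -> error
  expect_error(extract_template(st, 1, list(j_px = 5, k_px = 5,
                                            half_w = 3, half_h = 3)),
               "zero intensity variance")
  expect_error(extract_template(st, 1, list(j_px = 1, k_px = 1,
                                            half_w = 5, half_h = 5)),
               "outside the frame")
})

test_that("ZNCC map equals a brute-force per-offset correlation", {
  set.seed(11)
  frame <- matrix(runif(32 * 32, 0, 100), 32, 32)
  patch <- frame[10:18, 7:17]  # 9 x 11 template cut from the frame
  fast <- zncc_map(frame, patch)
  slow <- zncc_loops(frame, patch)
  expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-10)
  # self-match: score exactly 1 at the cut position
  pk <- which(fast == max(fast), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(10, 7))
  expect_equal(max(fast), 1, tolerance = 1e-12)
})

test_that("ZNCC score is invariant under affine intensity rescaling", {
  geom <- reduced_geometry(n_frames = 4)
  mk <- marker_spec(patient_point_spherical(5, 0.4, 1.3))
  st <- generate_scan(list(mk), geom, noise_sd = 10, seed = 3)
  row <- st$truth[st$truth$frame == 1, ]
  tpl <- extract_template(st, 1, list(j_px = round(row$j_px),
                                      k_px = round(row$k_px),
                                      half_w = 6, half_h = 6))
  m1 <- ncc_match(st$frames[[2]], tpl)
  m2 <- ncc_match(3.7 * st$frames[[2]] + 250, tpl)
  expect_lt(abs(m1$score - m2$score), 1e-9)
  expect_equal(m1$j_px, m2$j_px)
  expect_error(ncc_match(st$frames[[2]], tpl,
                         list(j_px = 2, k_px = 2, half_w = 30, half_h = 30)),
               "outside the frame")
})

test_that("markers are localized to subpixel accuracy under mild noise", {
  geom <- reduced_geometry(n_frames = 40)
  mk <- marker_spec(patient_point_spherical(7, 0.9, 1.2), id = "s")
  st <- generate_scan(list(mk), geom, noise_sd = 20, seed = 5)
  row <- st$truth[st$truth$frame == 1, ]
  tpl <- extract_template(st, 1, list(j_px = round(row$j_px),
                                      k_px = round(row$k_px),
                                      half_w = 6, half_h = 6))
  errs <- vapply(seq_along(st$frames), function(i) {
    m <- ncc_match(st$frames[[i]], tpl)
    max(abs(m$j_px - st$truth$j_px[i]), abs(m$k_px - st$truth$k_px[i]))
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("track_stack follows a stationary marker and handles empty stacks", {
  geom <- reduced_geometry(n_frames = 60)
  mk <- marker_spec(patient_point_spherical(6, 2.2, 0.9), id = "s")
  st <- generate_scan(list(mk), geom)
  row <- st$truth[st$truth$frame == 1, ]
  tpl <- extract_template(st, 1, list(j_px = round(row$j_px),
                                      k_px = round(row$k_px),
                                      half_w = 6, half_h = 6))
  tr <- track_stack(st, tpl)
  expect_true(all(tr$status == "detected"))
  expect_lt(max(abs(tr$jm_px - st$truth$j_px)), 0.5)
  expect_lt(max(abs(tr$km_px - st$truth$k_px)), 0.5)

  empty <- projection_stack(list(), make_schedule(0), geom)
  tre <- track_stack(empty, tpl)
  expect_equal(nrow(tre), 0)
})

test_that("a marker leaving the field of view yields missing frames", {
  geom <- reduced_geometry(n_frames = 120)
  p <- patient_point_spherical(15, 0, pi / 2)
  mk <- marker_spec(p, id = "edge")
  st <- generate_scan(list(mk), geom)
  vis <- stationary_track(p, geom)$in_fov
  first_vis <- which(vis)[1]
  row <- st$truth[st$truth$frame == first_vis, ]
  tpl <- extract_template(st, first_vis,
                          list(j_px = round(row$j_px), k_px = round(row$k_px),
                               half_w = 5, half_h = 5))
  tr <- track_stack(st, tpl, seed_px = c(row$j_px, row$k_px))
  expect_true(all(tr$status[!vis] == "missing"))
  expect_gt(mean(tr$status == "detected"), 0.3)
  expect_lt(mean(tr$status == "detected"), 0.75)
})

test_that("outlier flagging hits injected spikes and spares clean tracks", {
  geom <- reduced_geometry()
  clean <- protocol_result()$track
  expect_equal(sum(clean$status == "outlier"), 0)

  p <- patient_point_spherical(10, 40 * pi / 180, pi / 2)
  tr <- exact_moving_track_z(p, motion_waveform(a_z = 1.75, f_z = 15), geom)
  tr$jm_px[100] <- tr$jm_px[100] + 20   # one 20 px tracking failure
  out <- flag_outliers(tr)
  expect_equal(which(out$status == "outlier"), 100L)

  flat <- new_track_tbl(1:50, seq(0, 4.9, by = 0.1), seq(0, 49),
                        rep(80, 50), rep(60, 50))
  flat$km_px[25] <- 40
  out2 <- flag_outliers(flat)
  expect_equal(which(out2$status == "outlier"), 25L)
  expect_true(all(out2$status[c(24, 26)] == "detected"))

  short <- flat[1:4, ]
  expect_warning(flag_outliers(short), "fewer than 5")
})

test_that("gap interpolation fills interior holes but never extrapolates", {
  geom <- reduced_geometry()
  p <- patient_point_spherical(10, 40 * pi / 180, pi / 2)
  truth <- exact_moving_track_z(p, motion_waveform(a_z = 1.75, f_z = 15), geom)

  intact <- interpolate_gaps(truth)
  expect_identical(intact$jm_px, truth$jm_px)

  holed <- truth
  hole <- 150:154
  holed$status[hole] <- "missing"
  holed$jm_px[hole] <- NA; holed$km_px[hole] <- NA
  filled <- interpolate_gaps(holed)
  expect_true(all(filled$status[hole] == "interpolated"))
  expect_lt(max(abs(filled$jm_px[hole] - truth$jm_px[hole])), 0.5)
  expect_lt(max(abs(filled$km_px[hole] - truth$km_px[hole])), 0.5)

  lead <- truth
  lead$status[1:10] <- "missing"
  lead$jm_px[1:10] <- NA
  led <- interpolate_gaps(lead)
  expect_true(all(led$status[1:10] == "missing"))

  # a gap longer than max_gap_s stays missing
  long <- truth
  long$status[100:160] <- "missing"
  long$jm_px[100:160] <- NA
  kept <- interpolate_gaps(long, max_gap_s = 5)
  expect_true(all(kept$status[100:160] == "missing"))
})

test_that("tracks round-trip through CSV", {
  tr <- protocol_result()$track
  f <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, f)
  back <- read_track(f)
  expect_equal(back$jm_px, tr$jm_px)
  expect_equal(back$status, tr$status)
})
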