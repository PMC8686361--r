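test_that("step width and length follow the perpendicular decomposition", {
  # contacts at (0,0) and (0.15, 0.40) with progression along +Y:
  # step length 40 cm (along progression), step width 15 cm (perpendicular)
  set <- standing_set(n_frames = 100)
  set$markers$RHEE[, 1:2] <- 0
  set$markers$LHEE[, 1] <- 0.15
  set$markers$LHEE[, 2] <- 0.40
  seg <- manual_seg(1, 100, 1, left_hs = 50, right_hs = 10)
  st <- spatiotemporal_features(set, seg)
  expect_equal(st$step_width, 15, tolerance = 1e-9)
  expect_equal(st$step_length_inner, 40, tolerance = 1e-9)  # left steps, inner
  expect_true(is.na(st$step_length_outer))
})

test_that("whole-window bilateral stance gives 100% double, 0% single", {
  set <- standing_set(n_frames = 120)
  seg <- manual_seg(1, 120, 1.2, left_hs = c(10, 90), right_hs = c(5, 95))
  st <- spatiotemporal_features(set, seg)
  expect_equal(st$double_support_inner, 100)
  expect_equal(st$single_support_inner, 0)
})

test_that("sagittal knee ROM of a programmed sinusoid is its range", {
  n <- 400; rate <- 100
  set <- standing_set(n_frames = n, rate = rate)
  t <- (0:(n - 1)) / rate
  beta <- (20 + 15 * sin(2 * pi * 1 * t)) * pi / 180  # knee angle series
  lasi <- set$markers$LASI
  kne <- lasi; kne[, 3] <- kne[, 3] - 0.4  # thigh straight down
  ank <- kne + 0.4 * cbind(0, sin(-beta), -cos(-beta))
  set$markers$LKNE <- kne
  set$markers$LANK <- ank
  seg <- manual_seg(1, n, 4)
  rom <- joint_rom_features(set, seg)
  expect_equal(rom$rom_knee_inner, 30, tolerance = 1e-6)
  # a rigid pose has zero ROM everywhere
  rigid <- joint_rom_features(standing_set(200), manual_seg(1, 200, 2))
  expect_true(all(abs(unlist(rigid)) < 1e-9))
})

test_that("toe clearance is swing max over stance baseline; no swing flags NA", {
  n <- 200
  set <- standing_set(n_frames = n)
  z <- set$markers$LTOE[, 3]
  z[81:120] <- z[81:120] + 0.03 * sin(pi * seq(0, 1, length.out = 40))
  set$markers$LTOE[, 3] <- z
  seg <- manual_seg(1, n, 2, left_hs = c(10, 140), left_to = 75,
                    right_hs = c(12, 150))
  tc <- toe_clearance(set, seg)
  expect_equal(tc$toe_clearance_inner, 3, tolerance = 1e-3)
  expect_true(is.na(tc$toe_clearance_outer))  # foot never leaves the floor
})

test_that("anti-phase equals the shoulder-on-pelvis yaw offset", {
  set <- standing_set(n_frames = 100)
  seg <- manual_seg(1, 100, 1)
  expect_equal(max_anti_phase(set, seg), 0, tolerance = 1e-9)
  th <- 15 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  for (lb in c("LSHO", "RSHO"))
    set$markers[[lb]][, 1:2] <- set$markers[[lb]][, 1:2] %*% t(R)
  expect_equal(max_anti_phase(set, seg), 15, tolerance = 1e-9)
  # sinusoidal offset peaking at 12 degrees
  n <- 600
  set2 <- standing_set(n_frames = n)
  yaw <- 12 * pi / 180 * sin(2 * pi * 0.9 * (0:(n - 1)) / 100)
  for (i in seq_len(n)) {
    R <- matrix(c(cos(yaw[i]), sin(yaw[i]), -sin(yaw[i]), cos(yaw[i])), 2, 2)
    for (lb in c("LSHO", "RSHO"))
      set2$markers[[lb]][i, 1:2] <- set2$markers[[lb]][i, 1:2] %*% t(R)
  }
  expect_equal(max_anti_phase(set2, manual_seg(1, n, 6)), 12,
               tolerance = 0.1 / 12)
})

test_that("incline angle is atan(horizontal offset / vertical rise)", {
  set <- standing_set(n_frames = 50)
  seg <- manual_seg(1, 50, 0.5)
  expect_equal(incline_angle(set, seg), 0, tolerance = 1e-9)
  h <- 0.2
  for (lb in c("LFHD", "RFHD", "LBHD", "RBHD"))
    set$markers[[lb]][, 1] <- set$markers[[lb]][, 1] + h
  v <- 1.70 - 0.02  # head centroid height above the foot markers
  expect_equal(incline_angle(set, seg), atan(h / v) * 180 / pi,
               tolerance = 1e-6)
})

test_that("temporal coordination reads peak lags in the pelvis frame", {
  n <- 800; rate <- 100
  set <- standing_set(n_frames = n, rate = rate)
  t <- (0:(n - 1)) / rate
  f <- 0.8
  set$markers$LKNE[, 2] <- 0.10 * sin(2 * pi * f * t)
  set$markers$LELB[, 2] <- 0.10 * sin(2 * pi * f * (t - 0.2))
  set$markers$RKNE[, 2] <- 0.10 * sin(2 * pi * f * t + pi)
  set$markers$RELB[, 2] <- 0.10 * sin(2 * pi * f * t + pi)
  hs_l <- seq(30, n - 50, by = round(100 / f))
  hs_r <- hs_l + round(50 / f)
  seg <- manual_seg(1, n, 8, left_hs = hs_l, right_hs = hs_r)
  dt <- temporal_coordination(set, seg)
  expect_equal(dt$dt_ipsi_inner, 0.2, tolerance = 0.01 / 0.2)  # delayed arm
  expect_equal(dt$dt_ipsi_outer, 0, tolerance = 1e-9)          # simultaneous
})

test_that("COM path statistics match closed forms", {
  # stationary COM: all five features zero
  seg <- manual_seg(1, 100, 1)
  still <- structure(list(xy = matrix(0.3, 100, 2)), class = "com_trajectory")
  cf <- com_features(still, seg, 100)
  expect_true(all(abs(unlist(cf)) < 1e-12))
  # circular path radius r, one revolution in T seconds
  r <- 0.4; n <- 1000; T_rev <- 10
  th <- 2 * pi * (0:(n - 1)) / n
  circ <- structure(list(xy = cbind(r * cos(th), r * sin(th))),
                    class = "com_trajectory")
  seg2 <- manual_seg(1, n, T_rev)
  cf2 <- com_features(circ, seg2, n / T_rev)
  open_arc <- 2 * pi * r * (n - 1) / n  # frames span all but the last chord
  expect_equal(cf2$com_total_distance, open_arc, tolerance = 1e-5)
  expect_equal(cf2$com_velocity, open_arc / T_rev, tolerance = 1e-5)
  expect_error(com_features(structure(list(xy = matrix(0, 2, 2)),
                                      class = "com_trajectory"),
                            manual_seg(1, 2, 0.02), 100), "3 frames")
})

test_that("95% ellipse area matches the chi-squared form on Gaussian data", {
  set.seed(99)
  S <- matrix(c(4e-4, 1.5e-4, 1.5e-4, 2.5e-4), 2, 2)
  L <- chol(S)
  n <- 1e5
  xy <- matrix(rnorm(2 * n), n, 2) %*% L
  com <- structure(list(xy = xy), class = "com_trajectory")
  cf <- com_features(com, manual_seg(1, n, 100), 100)
  analytic_cm2 <- 1e4 * pi * qchisq(0.95, 2) * sqrt(det(S))
  expect_equal(cf$com_area_95ci, analytic_cm2, tolerance = 0.02)
})

test_that("extraction averages trials and is deterministic", {
  tr <- simulate_turn_trial(quick_params(seed = 5))
  one <- extract_features(tr$set, tr$metadata)
  three <- extract_features(list(tr$set, tr$set, tr$set), tr$metadata)
  expect_identical(as.numeric(one), as.numeric(three))
  again <- extract_features(tr$set, tr$metadata)
  expect_identical(one, again)
  expect_named(one, feature_registry())
})

test_that("features are invariant to global translation and Z rotation", {
  tr <- simulate_turn_trial(quick_params(seed = 8))
  f0 <- extract_features(tr$set, tr$metadata)
  f1 <- extract_features(transform_set(tr$set, deg = 118, dxy = c(-3, 9)),
                         tr$metadata)
  # COM RMS components are defined on global axes and rotate; all others
  # are frame-invariant
  inv <- setdiff(names(f0), c("com_rms_ap", "com_rms_ml"))
  expect_equal(f0[inv], f1[inv], tolerance = 2e-3)
})

test_that("stance equals own-foot single support plus double support", {
  tr <- simulate_turn_trial(quick_params(seed = 13))
  seg <- segment_turn(tr$set, "left")
  st <- spatiotemporal_features(tr$set, seg)
  for (role in c("inner", "outer")) {
    lhs <- st[[paste0("stance_", role)]]
    rhs <- st[[paste0("single_support_", role)]] +
      st[[paste0("double_support_", role)]]
    expect_lt(abs(lhs - rhs), 1.5)
  }
})
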