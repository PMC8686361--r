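rotating_pelvis <- function(deg_per_s, n = 1100, rate = 100, width = 0.24) {
  t <- (0:(n - 1)) / rate
  th <- deg_per_s * t * pi / 180
  half <- width / 2
  mk <- list(LASI = cbind(-half * cos(th), -half * sin(th), 0.95),
             RASI = cbind(half * cos(th), half * sin(th), 0.95))
  marker_set(mk, rate)
}

test_that("pelvic heading is exact for constant rotation and zero at rest", {
  set <- rotating_pelvis(36, n = 1001)
  h <- compute_pelvic_heading(set)
  t <- (0:1000) / 100
  expect_equal(h, 36 * t, tolerance = 1e-6)
  still <- rotating_pelvis(0, n = 100)
  expect_equal(compute_pelvic_heading(still), rep(0, 100))
})

test_that("turn phase detection hits the analytic 10/360 degree crossings", {
  h <- compute_pelvic_heading(rotating_pelvis(36, n = 1100))
  w <- detect_turn_phase(h, rate = 100)
  expect_equal(w$start_time, 10 / 36, tolerance = 1e-9)
  expect_equal(w$end_time, 10, tolerance = 1e-9)
  expect_equal(w$duration, 350 / 36, tolerance = 1e-9)
  expect_equal(w$direction, 1)
  # clockwise turns are detected through |heading|
  w2 <- detect_turn_phase(-h, rate = 100)
  expect_equal(w2$duration, w$duration)
  expect_equal(w2$direction, -1)
  expect_error(detect_turn_phase(rep(0, 100), 100), "incomplete turn")
})

test_that("turn duration is robust to heading noise (sigma = 0.2 deg)", {
  t <- (0:1099) / 100
  durations <- vapply(1:60, function(s) {
    set.seed(s)
    h <- 36 * t + rnorm(length(t), 0, 0.2)
    detect_turn_phase(h, 100)$duration
  }, numeric(1))
  expect_true(all(abs(durations - 350 / 36) < 0.05))
})

test_that("turn window is invariant to global translation and Z rotation", {
  tr <- simulate_turn_trial(quick_params(seed = 3))
  seg0 <- segment_turn(tr$set, "left")
  moved <- transform_set(tr$set, deg = 73, dxy = c(4.2, -1.7))
  seg1 <- segment_turn(moved, "left")
  expect_equal(seg1$window$duration, seg0$window$duration, tolerance = 1e-9)
  expect_identical(seg1$events$left$heel_strikes,
                   seg0$events$left$heel_strikes)
  expect_identical(seg1$events$right$toe_offs, seg0$events$right$toe_offs)
})

test_that("gait events on the puppet match the ground-truth schedule", {
  devs <- c(); n_hs <- 0
  for (s in 1:3) {
    tr <- simulate_turn_trial(quick_params(seed = s))
    seg <- segment_turn(tr$set, "left")
    ev <- tr$events
    for (ft in c("left", "right")) for (ty in c("heel_strike", "toe_off")) {
      truef <- ev$frame[ev$foot == ft & ev$type == ty]
      truef <- truef[truef >= seg$window$start_frame &
                       truef <= seg$window$end_frame]
      det <- if (ty == "heel_strike") seg$events[[ft]]$heel_strikes else
        seg$events[[ft]]$toe_offs
      devs <- c(devs, vapply(truef, function(f)
        min(abs(det - f)), numeric(1)))
    }
    n_hs <- n_hs + length(seg$events$left$heel_strikes) +
      length(seg$events$right$heel_strikes)
  }
  expect_gte(mean(devs <= 1), 0.95)
  expect_equal(n_hs, 3 * quick_params()$n_steps)  # all programmed steps found
})

test_that("static feet raise a no-steps error", {
  set <- standing_set(n_frames = 300)
  expect_error(detect_gait_events(set), "no steps")
})

test_that("count_steps combines events and refined duration", {
  ev <- list(left = list(heel_strikes = c(10, 110), toe_offs = 70),
             right = list(heel_strikes = 60, toe_offs = 120))
  w <- list(start_frame = 1, end_frame = 150, duration = 1.49)
  cs <- count_steps(ev, w)
  expect_equal(cs$steps, 3)
  expect_equal(cs$duration, 1.49)
  empty <- list(left = list(heel_strikes = integer(), toe_offs = integer()),
                right = list(heel_strikes = integer(), toe_offs = integer()))
  expect_equal(count_steps(empty, w)$steps, 0)
})

test_that("reconstructed stance fraction matches the programmed value", {
  tr <- simulate_turn_trial(quick_params(seed = 11, stance_fraction = 0.62))
  seg <- segment_turn(tr$set, "left")
  st <- spatiotemporal_features(tr$set, seg)
  expect_equal(st$stance_inner, 62, tolerance = 2 / 62)   # 2% of cycle
  expect_equal(st$stance_outer, 62, tolerance = 2 / 62)
})
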