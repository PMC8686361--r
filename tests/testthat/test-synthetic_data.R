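test_that("trials are deterministic given the seed", {
  a <- simulate_turn_trial(puppet_params(seed = 42))
  b <- simulate_turn_trial(puppet_params(seed = 42))
  expect_identical(a$set$markers, b$set$markers)
  expect_identical(a$truth, b$truth)
  c <- simulate_turn_trial(puppet_params(seed = 43))
  expect_false(identical(a$set$markers$LHEE, c$set$markers$LHEE))
})

test_that("ground-truth log and markers agree on event timing", {
  tr <- simulate_turn_trial(quick_params(seed = 2))
  seg <- segment_turn(tr$clean, "left")
  devs <- c()
  for (ft in c("left", "right")) for (ty in c("heel_strike", "toe_off")) {
    truef <- tr$events$frame[tr$events$foot == ft & tr$events$type == ty]
    truef <- truef[truef >= seg$window$start_frame &
                     truef <= seg$window$end_frame]
    det <- if (ty == "heel_strike") seg$events[[ft]]$heel_strikes else
      seg$events[[ft]]$toe_offs
    devs <- c(devs, vapply(truef, function(f) min(abs(det - f)), numeric(1)))
  }
  expect_true(all(devs <= 1))
})

test_that("null dials produce null features through the pipeline", {
  tr <- simulate_turn_trial(quick_params(seed = 4, lean = 1e-9,
                                         yaw_offset_peak = 1e-9))
  fv <- extract_features(tr$set, tr$metadata, filter = NULL)
  expect_lt(fv["incline_angle"], 0.2)
  expect_lt(fv["max_anti_phase"], 0.2)
})

test_that("programmed step geometry is recovered end to end", {
  tr <- simulate_turn_trial(puppet_params(seed = 6, step_length_inner = 0.40))
  fv <- extract_features(tr$set, tr$metadata)
  expect_equal(unname(fv["step_length_inner"]), 40, tolerance = 2 / 40)
})

test_that("a right-inner (clockwise) trial mirrors cleanly", {
  tr <- simulate_turn_trial(quick_params(seed = 9, inner_side = "right"))
  expect_identical(tr$metadata$inner_side, "right")
  h <- compute_pelvic_heading(tr$clean)
  expect_lt(min(h), -360)  # clockwise rotation
  fv <- extract_features(tr$set, tr$metadata)
  expect_equal(unname(fv["step_length_inner"]),
               100 * quick_params()$step_length_inner, tolerance = 0.06)
})

test_that("parameter validation rejects inconsistent puppets", {
  expect_error(puppet_params(stance_fraction = 0.45), "stance_fraction")
  expect_error(puppet_params(cadence = -1), "cadence")
  expect_error(puppet_params(n_steps = 2), "n_steps")
  expect_error(puppet_params(noise_sd = -0.1), "noise")
})

test_that("cohorts are reproducible and validate their inputs", {
  a <- simulate_cohort(3, seed = 77)
  b <- simulate_cohort(3, seed = 77)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_cohort(0), "n_per_group")
})

test_that("archetype offsets plant the reported PD directions", {
  co <- simulate_cohort(12, c("control", "pd"), seed = 5)
  g <- co$subjects$group
  tr <- co$truth
  expect_lt(mean(tr$step_length_inner[g == "pd"]),
            mean(tr$step_length_inner[g == "control"]))
  expect_gt(mean(tr$step_width[g == "pd"]),
            mean(tr$step_width[g == "control"]))
  expect_gt(mean(tr$double_support_inner[g == "pd"]),
            mean(tr$double_support_inner[g == "control"]))
  expect_gt(mean(tr$rom_thorax[g == "pd"]),
            mean(tr$rom_thorax[g == "control"]))
  expect_lt(mean(tr$incline_angle[g == "pd"]),
            mean(tr$incline_angle[g == "control"]))
})

test_that("freezer archetype plants the reported FOG directions", {
  co <- simulate_cohort(12, c("control", "freezer"), seed = 8)
  g <- co$subjects$group
  tr <- co$truth
  expect_lt(mean(tr$step_length_outer[g == "freezer"]),
            mean(tr$step_length_outer[g == "control"]))
  expect_gt(mean(tr$rom_hip_inner[g == "freezer"]),
            mean(tr$rom_hip_inner[g == "control"]))
  expect_lt(mean(tr$rom_ankle_inner[g == "freezer"]),
            mean(tr$rom_ankle_inner[g == "control"]))
  expect_lt(mean(tr$max_anti_phase[g == "freezer"]),
            mean(tr$max_anti_phase[g == "control"]))
  expect_gt(mean(tr$dt_contra_outer[g == "freezer"]),
            mean(tr$dt_contra_outer[g == "control"]))
  expect_gt(mean(tr$com_total_distance[g == "freezer"]),
            mean(tr$com_total_distance[g == "control"]))
})

test_that("feature-table simulator controls effects and correlation", {
  tab <- simulate_feature_table(200, c(a = 1.5, b = 0), correlation = 0.4,
                                seed = 1)
  m1 <- colMeans(tab$features[tab$labels == 1, ]) -
    colMeans(tab$features[tab$labels == 0, ])
  expect_equal(unname(m1["a"]), 1.5, tolerance = 0.15)
  expect_lt(abs(m1["b"]), 0.3)
  r <- cor(tab$features$a[tab$labels == 0], tab$features$b[tab$labels == 0])
  expect_equal(r, 0.4, tolerance = 0.35)
  expect_identical(
    simulate_feature_table(20, c(x = 1), seed = 3)$features,
    simulate_feature_table(20, c(x = 1), seed = 3)$features)
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_feature_table(10, c(a = 1, b = 0), correlation = bad),
               "positive definite")
})

test_that("a duplicated column is caught by the VIF screen", {
  tab <- simulate_feature_table(40, c(a = 1, b = 0.5), seed = 2)
  tab$features$a2 <- tab$features$a
  vf <- vif_filter(tab$features, c("a", "b", "a2"))
  expect_true(any(c("a", "a2") %in% vf$dropped))
  expect_true(all(vf$vif <= 2.5))
})
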