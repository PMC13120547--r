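test_that("vertical velocity equals the brute-force finite difference", {
  set.seed(5)
  for (rep in 1:10) {
    x <- cumsum(rnorm(40, 0, 5)) + 800
    y <- cumsum(rnorm(40, 0, 5)) + 400
    s <- path_sequence(x, y, fps = 60)
    expect_identical(vertical_velocity(s), oracle_diff(y, 60))
  }
  # linear case: 2 px/frame at 60 fps -> 120 px/s everywhere
  s <- path_sequence(rep(100, 30), seq(200, by = 2, length.out = 30))
  expect_equal(unique(vertical_velocity(s)[-1]), 120)
  # constant -> zero
  s0 <- path_sequence(rep(100, 30), rep(200, 30))
  expect_true(all(vertical_velocity(s0)[-1] == 0))
})

test_that("vertical velocity needs at least two usable frames", {
  s <- path_sequence(rep(1, 5), rep(1, 5))
  s$visibility[2:5, 12] <- FALSE
  expect_error(vertical_velocity(s), "fewer than 2 frames")
})

test_that("trunk inclination matches plane geometry", {
  expect_equal(trunk_inclination(c(100, 300), c(100, 200)), 0)
  expect_equal(trunk_inclination(c(100, 300), c(200, 300)), 90)
  expect_equal(trunk_inclination(c(0, 0), c(100, -100)), 45)
  expect_equal(trunk_inclination(c(0, 0), c(0, 50)), 180)  # inverted
  expect_warning(out <- trunk_inclination(c(1, 1), c(1, 1)), "coincident")
  expect_true(is.na(out))
})

test_that("aspect ratio is width over height and rejects flat boxes", {
  expect_equal(aspect_ratio(c(0, 0, 100, 100)), 1)
  expect_equal(aspect_ratio(c(0, 0, 60, 180)), 1 / 3)
  expect_error(aspect_ratio(c(0, 0, 10, 0)), "height")
  # a lying pose from the generator widens the box beyond square
  s <- simulate_fall(clean_params("controlled"))
  n <- n_frames(s)
  expect_gt(max(aspect_ratio(s$bbox)), 1)
})

test_that("segmentation recovers template truth within two frames", {
  for (prof in c("controlled", "chaotic", "freezing")) {
    s <- simulate_fall(clean_params(prof))
    seg <- segment_phases(s)
    expect_lte(abs(seg$peak_decel_frame - s$meta$truth_peak_frame), 2)
    expect_equal(seg$half_width, 12)  # round(0.2 * 60)
    expect_equal(seg$impact[2] - seg$impact[1] + 1, 25)
    # ordered, non-overlapping, covering phases
    expect_equal(seg$pre_fall[2] + 1, seg$impact[1])
    expect_equal(seg$impact[2] + 1, seg$post_fall[1])
    expect_lte(seg$post_fall[2], n_frames(s))
  }
})

test_that("impact half-width follows the 200 ms rule at any frame rate", {
  for (fps in c(30, 50, 60)) {
    s <- simulate_fall(clean_params("controlled"), fps = fps)
    seg <- segment_phases(s)
    expect_equal(seg$half_width, round(0.2 * fps))
  }
})

test_that("a constant-velocity descent puts the peak at descent onset", {
  # velocity jumps to 240 px/s at frame 31 and never decelerates
  y <- c(rep(300, 30), 300 + cumsum(rep(4, 150)))
  s <- path_sequence(rep(500, 180), y)
  seg <- segment_phases(s)
  expect_lte(abs(seg$peak_decel_frame - 31), 4)
})

test_that("no motion means no detected fall", {
  s <- path_sequence(rep(500, 60), rep(300, 60))
  expect_error(segment_phases(s), "no fall detected")
})

test_that("static sequences yield zero motion metrics", {
  s <- path_sequence(rep(500, 60), rep(300, 60))
  m <- extract_metrics(s)
  for (col in c("avg_velocity", "max_velocity", "movement_range_x",
                "movement_range_y", "position_variability_x",
                "velocity_variability", "avg_descent_rate",
                "max_descent_rate", "total_vertical_change",
                "high_movement_frames", "movement_intensity")) {
    expect_equal(m[[col]], 0, info = col)
  }
  expect_equal(m$avg_confidence, 1)
})

test_that("order statistics and metric invariants hold on random falls", {
  for (seed in 1:6) {
    prof <- c("controlled", "chaotic", "freezing")[(seed %% 3) + 1]
    s <- simulate_fall(profile_params(prof, seed = seed))
    m <- extract_metrics(repair_gaps(s))
    expect_gte(m$max_velocity, m$avg_velocity)
    expect_gte(m$max_acceleration, m$avg_acceleration)
    expect_gte(m$max_descent_rate, m$avg_descent_rate)
    expect_lte(m$total_vertical_change, m$movement_range_y + 1e-9)
    expect_gte(m$movement_range_x, 0)
    expect_true(m$avg_confidence >= 0 && m$avg_confidence <= 1)
  }
})

test_that("metrics are translation-invariant and velocities scale linearly", {
  s <- simulate_fall(clean_params("controlled"))
  m <- extract_metrics(s)

  shift <- s
  shift$keypoints[, , 1] <- shift$keypoints[, , 1] + 120
  shift$bbox[, 1] <- shift$bbox[, 1] + 120
  m_shift <- extract_metrics(shift)
  expect_equal(m_shift, m, tolerance = 1e-9, ignore_attr = TRUE)

  # doubling all coordinates doubles velocities and ranges
  dbl <- s
  dbl$keypoints[, , 1:2] <- dbl$keypoints[, , 1:2] * 2
  dbl$frame_size <- s$frame_size * 2
  dbl$bbox <- s$bbox * 2
  m_dbl <- extract_metrics(dbl)
  for (col in c("avg_velocity", "max_velocity", "movement_range_x",
                "movement_range_y", "avg_descent_rate", "max_descent_rate")) {
    expect_equal(m_dbl[[col]], 2 * m[[col]], tolerance = 1e-9, info = col)
  }
  expect_equal(m_dbl$mean_trunk_angle, m$mean_trunk_angle, tolerance = 1e-9)
})

test_that("mirroring the scene preserves the metric vector", {
  s <- simulate_fall(clean_params("chaotic", seed = 2))
  mir <- s
  mir$keypoints[, , 1] <- s$frame_size[1] - s$keypoints[, , 1]
  mir$bbox[, 1] <- s$frame_size[1] - (s$bbox[, 1] + s$bbox[, 3])
  expect_equal(extract_metrics(mir), extract_metrics(s), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("frame features match schema shape and brute-force derivatives", {
  schema <- frame_feature_schema()
  expect_length(schema, 150)
  s <- simulate_fall(profile_params("controlled", seed = 8))
  f <- extract_frame_features(repair_gaps(s))
  expect_equal(dim(f), c(n_frames(s), 150))
  expect_identical(colnames(f), as.vector(schema))

  # derivative columns equal the naive loop on the raw columns
  for (col in c("left_wrist_x", "right_ankle_y", "nose_y")) {
    d <- oracle_diff(f[, col], s$fps)
    d[1] <- 0
    expect_identical(unname(f[, paste0("d1_", col)]), d)
    d2 <- oracle_diff2(f[, col], s$fps)
    d2[1:2] <- 0
    expect_identical(unname(f[, paste0("d2_", col)]), d2)
  }
})

test_that("a constant pose has all-zero derivative columns", {
  s <- path_sequence(rep(700, 40), rep(350, 40))
  f <- extract_frame_features(s)
  d_cols <- grep("^d[12]_", colnames(f), value = TRUE)
  expect_true(all(f[, d_cols] == 0))
  expect_true(all(f[, "centroid_displacement"] == 0))
})
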