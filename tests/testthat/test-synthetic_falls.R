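test_that("same seed and parameters give identical sequences", {
  p <- profile_params("chaotic", seed = 77)
  s1 <- simulate_fall(p)
  s2 <- simulate_fall(p)
  expect_identical(s1$keypoints, s2$keypoints)
  expect_identical(s1$visibility, s2$visibility)
  expect_identical(s1$meta$truth_peak_frame, s2$meta$truth_peak_frame)
})

test_that("noiseless trajectories are exactly the closed-form template", {
  # regression against frozen template values: a change in the template
  # breaks downstream ground truth, so it must be deliberate
  s <- simulate_fall(clean_params("controlled", seed = 1))
  hip_y <- (s$keypoints[, 12, 2] + s$keypoints[, 13, 2]) / 2
  expect_equal(hip_y[1], 1080 - 76 - 260)       # standing hip height
  expect_equal(hip_y[length(hip_y)], hip_y[1] + 190)  # full descent depth
  # mid-descent value from the quintic ramp: onset 0.3 s, duration 0.8 s
  u <- (1 - 0.3) / 0.8
  expect_equal(hip_y[61], hip_y[1] + 190 * (u^3 * (10 - 15 * u + 6 * u^2)),
               tolerance = 1e-10)
  expect_true(all(s$keypoints[, , 3] == 1))
  # identical template on every rebuild
  expect_identical(simulate_fall(clean_params("controlled", seed = 1))$keypoints,
                   s$keypoints)
})

test_that("a freezing fall that never starts has a constant hip height", {
  p <- clean_params("freezing", hesitation_delay = 10)
  s <- simulate_fall(p, duration = 3)
  hip_y <- (s$keypoints[, 12, 2] + s$keypoints[, 13, 2]) / 2
  expect_equal(diff(range(hip_y)), 0)
  m <- extract_metrics(s)
  expect_equal(m$avg_descent_rate, 0)
  expect_false(attr(m, "segmentable"))
})

test_that("profile orderings hold on noiseless defaults", {
  m <- lapply(c(controlled = "controlled", chaotic = "chaotic",
                freezing = "freezing"),
              function(p) extract_metrics(simulate_fall(clean_params(p))))
  expect_gt(m$controlled$movement_range_x, m$freezing$movement_range_x)
  expect_gt(m$controlled$avg_descent_rate, m$freezing$avg_descent_rate)
  expect_gt(m$chaotic$movement_intensity, m$controlled$movement_intensity)
  expect_lt(m$controlled$min_neck_distance, m$freezing$min_neck_distance)
})

test_that("infeasible geometry is rejected", {
  expect_error(simulate_fall(clean_params("controlled", descent_depth = 500)),
               "below the ground")
  expect_error(simulate_fall(clean_params("controlled"), duration = 0.3),
               "at least 30 frames")
  expect_error(profile_params("controlled", descent_depth = -5),
               "non-negative")
  expect_error(profile_params("controlled", chin_tuck = 1.4), "\\[0, 1\\]")
  expect_error(profile_params("controlled", nonsense = 1), "unknown")
})

test_that("cohorts have the requested sizes, tags and unique subjects", {
  seqs <- simulate_cohort(cohort_spec(n_pre = 285, n_post = 130, seed = 4))
  expect_length(seqs, 415)
  cohorts <- vapply(seqs, function(s) s$cohort, "")
  expect_equal(sum(cohorts == "pre"), 285)
  expect_equal(sum(cohorts == "post"), 130)
  ids <- vapply(seqs, function(s) s$subject_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  labels <- vapply(seqs, function(s) s$quality_label, "")
  profiles <- vapply(seqs, function(s) s$meta$profile, "")
  expect_true(all(labels[profiles == "controlled"] == "safe"))
  expect_true(all(labels[profiles != "controlled"] == "hazardous"))
  # reproducible from the master seed
  seqs2 <- simulate_cohort(cohort_spec(n_pre = 285, n_post = 130, seed = 4))
  expect_identical(seqs[[17]]$keypoints, seqs2[[17]]$keypoints)
})

test_that("identical mixes give no systematic profile frequency difference", {
  mix <- c(chaotic = 0.2, controlled = 0.5, freezing = 0.3)
  seqs <- simulate_cohort(cohort_spec(n_pre = 150, n_post = 150,
                                      pre_mix = mix, post_mix = mix,
                                      seed = 12))
  profiles <- vapply(seqs, function(s) s$meta$profile, "")
  cohorts <- vapply(seqs, function(s) s$cohort, "")
  p_ctrl <- tapply(profiles == "controlled", cohorts, mean)
  se <- sqrt(2 * 0.5 * 0.5 / 150)
  expect_lt(abs(p_ctrl[["pre"]] - p_ctrl[["post"]]), 4 * se)
})

test_that("dropout rate is realized near its parameter", {
  p <- profile_params("controlled", dropout_rate = 0.05, seed = 31)
  dropped <- mean(!simulate_fall(p, duration = 10)$visibility)
  n <- 600 * 17
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(dropped - 0.05), 3 * se)
})

test_that("default cohort mixes separate cohorts in profile space", {
  # chi-square on cohort x profile significant across seeds
  sig <- vapply(1:20, function(seed) {
    spec <- cohort_spec(n_pre = 120, n_post = 60, seed = seed)
    draws <- with_seed(spec$seed, list(
      profile = c(sample(names(spec$pre_mix), spec$n_pre, TRUE, spec$pre_mix),
                  sample(names(spec$post_mix), spec$n_post, TRUE, spec$post_mix))))
    cohorts <- rep(c("pre", "post"), c(spec$n_pre, spec$n_post))
    suppressWarnings(stats::chisq.test(table(cohorts, draws$profile))$p.value) < 0.05
  }, TRUE)
  expect_gte(mean(sig), 0.95)
})
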