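test_that("write then read reproduces the data model on random sequences", {
  seqs <- lapply(1:25, random_sequence)
  path <- withr::local_tempfile(fileext = ".json")
  write_sequences(seqs, path)
  back <- read_sequences(path)
  expect_length(back, 25)
  for (i in seq_along(seqs)) {
    expect_equal(back[[i]]$subject_id, seqs[[i]]$subject_id)
    expect_equal(back[[i]]$cohort, seqs[[i]]$cohort)
    expect_equal(back[[i]]$quality_label, seqs[[i]]$quality_label)
    expect_equal(back[[i]]$fps, seqs[[i]]$fps)
    expect_equal(back[[i]]$frame_index, seqs[[i]]$frame_index)
    expect_equal(back[[i]]$keypoints, seqs[[i]]$keypoints,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$visibility, seqs[[i]]$visibility)
    expect_equal(back[[i]]$bbox, seqs[[i]]$bbox, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("serialization is byte-stable and an empty list is valid", {
  seqs <- lapply(1:5, random_sequence)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_sequences(seqs, p1)
  write_sequences(seqs, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  p0 <- withr::local_tempfile()
  write_sequences(list(), p0)
  expect_length(read_sequences(p0), 0)
})

test_that("reader clamps out-of-range confidence with a warning", {
  s <- random_sequence(42)
  s$keypoints[2, 5, 3] <- 1.3
  path <- withr::local_tempfile()
  write_sequences(list(s), path)
  expect_warning(back <- read_sequences(path), "clamped")
  expect_equal(back[[1]]$keypoints[2, 5, 3], 1)
})

test_that("malformed input fails with an informative error", {
  path <- withr::local_tempfile()
  writeLines("{not json", path)
  expect_error(read_sequences(path), "malformed JSON")
  writeLines('{"format": "something-else", "sequences": []}', path)
  expect_error(read_sequences(path), "not a safefall-pose")
  # wrong keypoint count names the record
  s <- random_sequence(1)
  write_sequences(list(s), path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$sequences[[1]]$frames[[2]]$keypoints <-
    doc$sequences[[1]]$frames[[2]]$keypoints[1:16]
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), path)
  expect_error(read_sequences(path), "expected 17 keypoints")
  expect_error(read_sequences(tempfile()), "not found")
})

test_that("repair_gaps interpolates short gaps and leaves the rest alone", {
  n <- 20
  kp <- array(1, c(n, 17, 3))
  for (k in 1:17) {
    kp[, k, 1] <- seq(0, 19)      # linear x
    kp[, k, 2] <- seq(0, 38, by = 2)
  }
  s <- fall_sequence("g", fps = 60, keypoints = kp, frame_size = c(100, 100))

  # no low-confidence keypoints: identity
  expect_identical(repair_gaps(s)$keypoints, s$keypoints)

  # single missing frame between (x, y) = (4, 8) and (6, 12) -> (5, 10)
  s2 <- s
  s2$keypoints[6, 3, 3] <- 0.1
  r <- repair_gaps(s2, conf_floor = 0.5, max_gap = 10)
  expect_equal(unname(r$keypoints[6, 3, 1:2]), c(5, 10))
  expect_true(r$imputed[6, 3])
  expect_true(r$visibility[6, 3])

  # gaps longer than max_gap and gaps at the ends stay masked
  s3 <- s
  s3$keypoints[5:9, 2, 3] <- 0.1   # 5-frame gap, max_gap 3
  s3$keypoints[1:2, 4, 3] <- 0.1   # endpoint gap
  r3 <- repair_gaps(s3, conf_floor = 0.5, max_gap = 3)
  expect_false(any(r3$visibility[5:9, 2]))
  expect_false(any(r3$visibility[1:2, 4]))
  expect_false(any(r3$imputed[, 2]))

  # idempotence
  r_once <- repair_gaps(s2)
  expect_identical(repair_gaps(r_once), r_once)
})

test_that("repair error stays below the noise amplitude on a smooth path", {
  noise_sd <- 3
  tt <- seq(0, 2, by = 1 / 60)
  truth_x <- 500 + 100 * sin(tt)
  truth_y <- 400 + 60 * cos(tt)
  set.seed(99)
  s <- path_sequence(truth_x + rnorm(length(tt), 0, noise_sd),
                     truth_y + rnorm(length(tt), 0, noise_sd))
  drop <- sample(5:(length(tt) - 5), 15)
  s$keypoints[drop, 12, 3] <- 0.1
  r <- repair_gaps(s, conf_floor = 0.5, max_gap = 10)
  expect_true(all(r$visibility[, 12]))
  err <- abs(r$keypoints[drop, 12, 1] - (truth_x[drop] - 40))
  expect_lt(max(err), 4 * noise_sd)
})

test_that("derived landmarks are means of their sources and respect masks", {
  kp <- array(0.9, c(2, 17, 3))
  kp[1, 12, 1:2] <- c(100, 200)  # left hip
  kp[1, 13, 1:2] <- c(140, 200)  # right hip
  kp[1, 6, 1:2] <- c(90, 120)    # left shoulder
  kp[1, 7, 1:2] <- c(110, 124)   # right shoulder
  kp[1, 1, 1:2] <- c(101, 95)    # nose
  s <- fall_sequence("lm", fps = 60, keypoints = kp,
                     frame_size = c(1920, 1080))
  lm <- derive_landmarks(s)
  expect_equal(unname(lm$mid_hip[1, ]), c(120, 200))
  expect_equal(unname(lm$mid_shoulder[1, ]), c(100, 122))
  expect_equal(unname(lm$sternum_proxy[1, ]), c(100, 122))
  expect_equal(unname(lm$chin_proxy[1, ]), c(101, 95))

  s$visibility[2, 12] <- FALSE
  lm2 <- derive_landmarks(s)
  expect_true(all(is.na(lm2$mid_hip[2, ])))
  expect_false(anyNA(lm2$mid_shoulder[2, ]))
})

test_that("derived landmarks are equivariant under translation and scaling", {
  s <- random_sequence(7, n_frames = 4)
  lm <- derive_landmarks(s)
  s2 <- s
  s2$keypoints[, , 1] <- s$keypoints[, , 1] * 2 + 30
  s2$keypoints[, , 2] <- s$keypoints[, , 2] * 0.5 + 10
  s2$frame_size <- c(4000, 1080)
  lm2 <- derive_landmarks(s2)
  for (nm in names(lm)) {
    expect_equal(lm2[[nm]][, "x"], lm[[nm]][, "x"] * 2 + 30, tolerance = 1e-12)
    expect_equal(lm2[[nm]][, "y"], lm[[nm]][, "y"] * 0.5 + 10, tolerance = 1e-12)
  }
})

test_that("flatten_keypoints produces one row per frame and keypoint", {
  s <- random_sequence(3, n_frames = 6)
  df <- flatten_keypoints(s)
  expect_equal(nrow(df), 6 * 17)
  expect_equal(df$x[1:17], unname(s$keypoints[1, , 1]))
  expect_setequal(unique(df$keypoint), coco_keypoints())
})
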