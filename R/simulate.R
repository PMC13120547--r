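# Synthetic fall generator
#
# A 2D stick-figure forward-kinematics template (torso segment, head offset,
# four two-segment limbs) drives 17 COCO keypoints through three phases:
# upright stance -> descent (optional squat, then the fall proper, both cubic
# smoothstep ramps of the hip-centre height) -> ground phase. Three motor
# profiles parameterise the template:
#   controlled — rapid squat to lower the CoM, full descent, long horizontal
#                roll, chin tucked (tuck-and-roll / Ukemi);
#   chaotic    — near-instant step-like descent with high-frequency sinusoid
#                flail on wrists/elbows/ankles (and attenuated on the hips);
#   freezing   — hesitation delay, slow shallow descent, no roll, straight
#                extended arms (FOOSH-like), chin not tucked.
# Gaussian keypoint noise and Bernoulli dropout are applied last, so with
# both at zero the output is exactly the closed-form template.

# fixed stick-figure segment lengths (pixels at 1920x1080)
SEG <- list(torso = 160, neck = 60, shoulder_hw = 55, hip_hw = 40,
            upper_arm = 75, forearm = 70, thigh = 110, shank = 100,
            ground_margin = 76)

#' Motor-profile parameters for the fall simulator
#'
#' Returns the parameter set of one of the three motor profiles, with any
#' field overridable. Magnitudes are pixels (at the default 1920x1080
#' frame), durations seconds, and `chin_tuck` / `arm_extension` are in
#' `[0, 1]` (1 = fully tucked chin / fully extended straight arms).
#'
#' @param profile `"controlled"`, `"chaotic"` or `"freezing"`.
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `profile_params`: `profile`,
#'   `stance_height`, `squat_duration`, `fall_duration`, `descent_depth`,
#'   `roll_distance_x`, `sway_amplitude` (slow whole-body lateral balance
#'   sway), `flail_amplitude`, `flail_frequency`,
#'   `hesitation_delay`, `chin_tuck`, `arm_extension`, `keypoint_noise_sd`,
#'   `dropout_rate`, `seed`.
#' @export
profile_params <- function(profile = c("controlled", "chaotic", "freezing"),
                           ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    controlled = list(stance_height = 260, squat_duration = 0.25,
                      fall_duration = 0.55, descent_depth = 190,
                      roll_distance_x = 350, sway_amplitude = 50,
                      flail_amplitude = 0, flail_frequency = 0,
                      hesitation_delay = 0, chin_tuck = 0.9,
                      arm_extension = 0.10),
    chaotic    = list(stance_height = 260, squat_duration = 0.05,
                      fall_duration = 0.25, descent_depth = 220,
                      roll_distance_x = 40, sway_amplitude = 50,
                      flail_amplitude = 60, flail_frequency = 6,
                      hesitation_delay = 0.05, chin_tuck = 0.15,
                      arm_extension = 0.55),
    freezing   = list(stance_height = 260, squat_duration = 0,
                      fall_duration = 1.6, descent_depth = 100,
                      roll_distance_x = 0, sway_amplitude = 50,
                      flail_amplitude = 0, flail_frequency = 0,
                      hesitation_delay = 0.8, chin_tuck = 0.05,
                      arm_extension = 0.9))
  p <- c(list(profile = profile), base,
         list(keypoint_noise_sd = 2, dropout_rate = 0.02, seed = 1L))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stopf("unknown profile parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  num <- unlist(p[setdiff(names(p), c("profile", "seed"))])
  if (any(num < 0)) stopf("profile parameters must be non-negative")
  if (p$chin_tuck > 1 || p$arm_extension > 1 || p$dropout_rate > 1) {
    stopf("chin_tuck, arm_extension and dropout_rate must lie in [0, 1]")
  }
  structure(p, class = "profile_params")
}

#' Simulate one tracked fall sequence
#'
#' Generates a deterministic (given `params$seed`) 17-keypoint pose sequence
#' following the profile's kinematic template, then applies Gaussian
#' keypoint noise and Bernoulli per-keypoint dropout. Ground-truth phase
#' boundaries, the template peak-deceleration frame and the quality label
#' (`controlled` is `"safe"`, the other profiles `"hazardous"`) are stored
#' in `$meta`.
#'
#' @param params A [profile_params()] object.
#' @param fps Frame rate (default 60, the study recording rate).
#' @param duration Sequence duration in seconds (default 3).
#' @param frame_size `(width, height)` pixels (default 1920x1080).
#' @param subject_id Subject identifier.
#' @param cohort `"pre"`, `"post"` or `"unknown"`.
#' @return A [fall_sequence].
#' @export
simulate_fall <- function(params, fps = 60, duration = 3,
                          frame_size = c(1920, 1080),
                          subject_id = "synthetic", cohort = "unknown") {
  n <- round(duration * fps)
  if (n < 30L) stopf("duration * fps must give at least 30 frames")
  ground_y <- frame_size[2] - SEG$ground_margin
  hip_y0 <- ground_y - params$stance_height
  if (hip_y0 < SEG$torso + SEG$neck + 20) {
    stopf("stance_height places the body outside the frame")
  }
  if (params$descent_depth > params$stance_height - 20) {
    stopf("descent_depth %.0f would place the hips below the ground plane",
          params$descent_depth)
  }

  tt <- (seq_len(n) - 1L) / fps
  onset <- 0.3 + params$hesitation_delay
  squat_end <- onset + params$squat_duration
  land <- squat_end + params$fall_duration
  onset_fr <- if (any(tt >= onset)) which(tt >= onset)[1] else n
  land_fr <- if (any(tt >= land)) which(tt >= land)[1] else n

  # hip-centre trajectory: one smooth ramp over the whole descent — the squat
  # hands off into the fall without stopping, so the only deceleration peak
  # is at ground contact
  d_total <- params$squat_duration + params$fall_duration
  s_desc <- if (d_total > 0) {
    smootherstep((tt - onset) / d_total)
  } else as.numeric(tt >= onset)
  hip_y <- hip_y0 + params$descent_depth * s_desc
  # squat/fall progress drive posture only (knee flexion, trunk rotation)
  s_squat <- if (params$squat_duration > 0) {
    smoothstep((tt - onset) / params$squat_duration)
  } else rep(0, n)
  s_fall <- if (params$fall_duration > 0) {
    smoothstep((tt - squat_end) / params$fall_duration)
  } else as.numeric(tt >= squat_end)
  x0 <- frame_size[1] * 0.35
  roll_span <- max(params$fall_duration + 0.4, 0.4)
  s_roll <- smoothstep((tt - squat_end) / roll_span)

  with_seed(params$seed, {
    # slow whole-body lateral balance sway, present in every profile
    sway <- if (params$sway_amplitude > 0) {
      params$sway_amplitude *
        sin(2 * pi * stats::runif(1, 0.25, 0.45) * tt +
            stats::runif(1, 0, 2 * pi))
    } else rep(0, n)
    hip_x <- x0 + params$roll_distance_x * s_roll + sway

    kp <- skeleton_template(params, tt, hip_x, hip_y, s_fall, s_squat,
                            ground_y)
    if (params$flail_amplitude > 0) {
      kp <- add_flail(kp, params, tt, onset, land + 0.3)
    }
    # ground truth from the deterministic (pre-noise) mid-hip trajectory,
    # by raw finite differences
    hip_mid_y <- (kp[, "left_hip", 2L] + kp[, "right_hip", 2L]) / 2
    vy <- c(NA, diff(hip_mid_y)) * fps
    ay <- c(NA, diff(vy)) * fps
    search <- onset_fr:min(land_fr + 3L, n)
    truth_peak <- search[which.max(-ay[search])]
    if (params$keypoint_noise_sd > 0) {
      kp[, , 1:2] <- kp[, , 1:2] +
        stats::rnorm(n * 17L * 2L, 0, params$keypoint_noise_sd)
      kp[, , 3L] <- clamp(1 - abs(stats::rnorm(n * 17L, 0, 0.01)), 0, 1)
    } else {
      kp[, , 3L] <- 1
    }
    vis <- matrix(TRUE, n, 17L)
    if (params$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * 17L) < params$dropout_rate, n, 17L)
      vis[drop] <- FALSE
      kp[, , 3L][drop] <- stats::runif(sum(drop), 0, 0.3)
    }
    kp[, , 1L] <- clamp(kp[, , 1L], 0, frame_size[1])
    kp[, , 2L] <- clamp(kp[, , 2L], 0, frame_size[2])
    fall_sequence(
      subject_id = subject_id, fps = fps, keypoints = kp,
      frame_size = frame_size, visibility = vis, cohort = cohort,
      quality_label = if (params$profile == "controlled") "safe" else "hazardous",
      meta = list(profile = params$profile,
                  onset_frame = onset_fr,
                  land_frame = land_fr,
                  truth_peak_frame = truth_peak,
                  params = unclass(params)))
  })
}

# deterministic part of the skeleton: all 17 keypoints from the hip path
skeleton_template <- function(params, tt, hip_x, hip_y, s_fall, s_squat,
                              ground_y) {
  n <- length(tt)
  theta_max <- switch(params$profile, controlled = 100, chaotic = 85,
                      freezing = 55) * pi / 180
  theta <- theta_max * s_fall                     # trunk angle from vertical
  ax <- sin(theta); ay <- -cos(theta)             # trunk axis (hip -> shoulder)

  kp <- array(NA_real_, c(n, 17L, 3L),
              dimnames = list(NULL, coco_keypoints(), c("x", "y", "confidence")))
  put <- function(name, x, y) {
    kp[, name, 1L] <<- x
    kp[, name, 2L] <<- y
  }

  msx <- hip_x + SEG$torso * ax
  msy <- hip_y + SEG$torso * ay
  put("left_shoulder", msx - SEG$shoulder_hw, msy)
  put("right_shoulder", msx + SEG$shoulder_hw, msy)
  put("left_hip", hip_x - SEG$hip_hw, hip_y)
  put("right_hip", hip_x + SEG$hip_hw, hip_y)

  # chin tuck shortens the effective neck (nose-to-sternum distance)
  neck_eff <- SEG$neck * (1 - 0.7 * params$chin_tuck * s_fall)
  put("nose", msx + neck_eff * ax, msy + neck_eff * ay)
  put("left_eye", kp[, "nose", 1L] - 8, kp[, "nose", 2L] - 6)
  put("right_eye", kp[, "nose", 1L] + 8, kp[, "nose", 2L] - 6)
  put("left_ear", kp[, "nose", 1L] - 16, kp[, "nose", 2L] + 2)
  put("right_ear", kp[, "nose", 1L] + 16, kp[, "nose", 2L] + 2)

  # legs rotate from vertical (standing) toward the ground plane as the
  # trunk reclines; knees flex with the squat
  psi <- 0.9 * theta + 0.6 * s_squat * (25 * pi / 180)
  lx <- sin(psi); ly <- cos(psi)                  # leg axis (hip -> knee)
  flex <- 0.35 * s_squat + 0.15 * s_fall
  psi2 <- psi + flex
  l2x <- sin(psi2); l2y <- cos(psi2)
  for (side in c("left", "right")) {
    hx <- kp[, paste0(side, "_hip"), 1L]
    hy <- kp[, paste0(side, "_hip"), 2L]
    knx <- hx + SEG$thigh * lx
    kny <- pmin(hy + SEG$thigh * ly, ground_y)
    put(paste0(side, "_knee"), knx, kny)
    put(paste0(side, "_ankle"),
        knx + SEG$shank * l2x, pmin(kny + SEG$shank * l2y, ground_y))
  }

  # arms blend from a tucked carriage to a straight downward-forward reach
  e <- params$arm_extension
  reach <- clamp(0.25 + 0.75 * s_fall, 0, 1)      # arms deploy during descent
  for (side in c("left", "right")) {
    sx <- kp[, paste0(side, "_shoulder"), 1L]
    sy <- kp[, paste0(side, "_shoulder"), 2L]
    # tucked: elbow close to torso, wrist drawn up toward the sternum
    elx_t <- sx + 10 * ax; ely_t <- sy + 0.55 * SEG$upper_arm
    wrx_t <- 0.7 * elx_t + 0.3 * msx
    wry_t <- ely_t - 0.45 * SEG$forearm
    # extended: straight arm toward the ground ahead of the body
    dirx <- 0.35; diry <- sqrt(1 - dirx^2)
    elx_e <- sx + SEG$upper_arm * dirx; ely_e <- sy + SEG$upper_arm * diry
    wrx_e <- elx_e + SEG$forearm * dirx
    wry_e <- pmin(ely_e + SEG$forearm * diry, ground_y + 10)
    b <- e * reach
    put(paste0(side, "_elbow"), (1 - b) * elx_t + b * elx_e,
        (1 - b) * ely_t + b * ely_e)
    put(paste0(side, "_wrist"), (1 - b) * wrx_t + b * wrx_e,
        (1 - b) * wry_t + b * wry_e)
  }
  kp
}

# sinusoid flail on distal joints (chaotic profile); seeded phases are drawn
# from the caller's RNG stream
add_flail <- function(kp, params, tt, from, to) {
  # smooth envelope: ramps in/out over 0.15 s so activating and deactivating
  # the flail never introduces a position discontinuity
  env <- smoothstep((tt - from) / 0.15) * smoothstep((to - tt) / 0.15)
  joints <- c("left_wrist", "right_wrist", "left_elbow", "right_elbow",
              "left_ankle", "right_ankle")
  for (j in joints) {
    for (coord in 1:2) {
      ph <- stats::runif(1, 0, 2 * pi)
      f <- params$flail_frequency * stats::runif(1, 0.8, 1.2)
      kp[, j, coord] <- kp[, j, coord] +
        env * params$flail_amplitude * sin(2 * pi * f * tt + ph)
    }
  }
  # attenuated, slower erratic displacement of the pelvis (panic response);
  # kept at a fraction of the flail frequency so hip accelerations stay far
  # below the landing impact
  hip_f <- params$flail_frequency / 3
  for (coord in 1:2) {
    ph <- stats::runif(1, 0, 2 * pi)
    wobble <- env * 0.3 * params$flail_amplitude *
      sin(2 * pi * hip_f * tt + ph)
    for (j in c("left_hip", "right_hip")) {
      kp[, j, coord] <- kp[, j, coord] + wobble
    }
  }
  kp
}

#' Cohort specification for the simulator
#'
#' @param n_pre,n_post Cohort sizes (defaults 285 and 130, the study's
#'   pre/post sample sizes).
#' @param pre_mix,post_mix Named probabilities over
#'   `c(chaotic, controlled, freezing)`; must sum to 1. The defaults skew
#'   the pre-test cohort toward chaotic/freezing responses and the post-test
#'   cohort toward the controlled profile.
#' @param fps,duration,frame_size Recording parameters (defaults 60 fps,
#'   3 s, 1920x1080).
#' @param param_jitter Log-normal sd of the per-subject multiplicative
#'   jitter applied to the magnitude/timing parameters (default 0.15).
#' @param post_descent_gain,post_speed_gain Within-subject training effect
#'   applied to the post cohort: descent depth is multiplied by
#'   `post_descent_gain` (capped by the stance height) and the fall
#'   duration divided by `post_speed_gain`, emulating the decisive
#'   commitment to the fall that training produces on top of the
#'   profile-mix shift (defaults 1.2 and 1.1).
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pre = 285L, n_post = 130L,
                        pre_mix = c(chaotic = 0.10, controlled = 0.55,
                                    freezing = 0.35),
                        post_mix = c(chaotic = 0.02, controlled = 0.83,
                                     freezing = 0.15),
                        fps = 60, duration = 3,
                        frame_size = c(1920, 1080),
                        param_jitter = 0.15,
                        post_descent_gain = 1.2, post_speed_gain = 1.1,
                        seed = 1L) {
  stopifnot(n_pre > 0, n_post > 0)
  for (m in list(pre_mix, post_mix)) {
    if (abs(sum(m) - 1) > 1e-8) stopf("profile mixes must sum to 1")
    if (!setequal(names(m), c("chaotic", "controlled", "freezing"))) {
      stopf("mixes must be named over chaotic/controlled/freezing")
    }
  }
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 pre_mix = pre_mix, post_mix = post_mix, fps = fps,
                 duration = duration, frame_size = frame_size,
                 param_jitter = param_jitter,
                 post_descent_gain = post_descent_gain,
                 post_speed_gain = post_speed_gain,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a pre/post cohort of falls
#'
#' Draws each subject's motor profile from the cohort's mix, jitters the
#' profile parameters per subject (multiplicative log-normal on magnitudes
#' and timings, additive on the chin-tuck/arm-extension blend), and
#' simulates every fall. Subjects get unique ids and per-subject seeds
#' derived from the master seed, so the cohort is reproducible and
#' independent of generation order.
#'
#' @param spec A [cohort_spec()].
#' @param param_table Optional named list of [profile_params()] overriding
#'   the per-profile defaults (names: chaotic/controlled/freezing).
#' @return List of `n_pre + n_post` [fall_sequence] objects.
#' @export
simulate_cohort <- function(spec = cohort_spec(), param_table = NULL) {
  profiles <- c("chaotic", "controlled", "freezing")
  base <- lapply(stats::setNames(profiles, profiles), function(p) {
    if (!is.null(param_table[[p]])) param_table[[p]] else profile_params(p)
  })
  n_tot <- spec$n_pre + spec$n_post
  draws <- with_seed(spec$seed, list(
    profile = c(sample(profiles, spec$n_pre, TRUE, prob = spec$pre_mix[profiles]),
                sample(profiles, spec$n_post, TRUE, prob = spec$post_mix[profiles])),
    seeds = sample.int(.Machine$integer.max - 1L, n_tot)))
  cohort <- rep(c("pre", "post"), c(spec$n_pre, spec$n_post))
  lapply(seq_len(n_tot), function(i) {
    p <- jitter_params(base[[draws$profile[i]]], draws$seeds[i],
                       spec$param_jitter)
    if (cohort[i] == "post") {
      # trained subjects commit to the fall: deeper, faster descent
      p$descent_depth <- min(p$descent_depth * spec$post_descent_gain,
                             p$stance_height - 25)
      p$fall_duration <- p$fall_duration / spec$post_speed_gain
    }
    simulate_fall(p, fps = spec$fps, duration = spec$duration,
                  frame_size = spec$frame_size,
                  subject_id = sprintf("S%04d", i), cohort = cohort[i])
  })
}

jitter_params <- function(p, seed, sd) {
  with_seed(seed, {
    if (sd > 0) {
      for (f in c("descent_depth", "roll_distance_x", "fall_duration",
                  "flail_amplitude", "hesitation_delay", "sway_amplitude")) {
        p[[f]] <- p[[f]] * stats::rlnorm(1, 0, sd)
      }
      if (p$squat_duration > 0) {
        p$squat_duration <- p$squat_duration * stats::rlnorm(1, 0, sd)
      }
      p$stance_height <- p$stance_height * stats::rlnorm(1, 0, sd / 3)
      for (f in c("chin_tuck", "arm_extension")) {
        p[[f]] <- clamp(p[[f]] + stats::rnorm(1, 0, 0.05), 0, 1)
      }
      p$descent_depth <- min(p$descent_depth, p$stance_height - 25)
    }
    p$seed <- sample.int(.Machine$integer.max - 1L, 1L)
    p
  })
}
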