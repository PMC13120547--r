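# Per-frame kinematic signals and fall-phase segmentation.
#
# Conventions: image coordinates, origin top-left, y increases downward, so
# positive vertical velocity means descent. Velocities are backward finite
# differences scaled by fps (pixels/second); accelerations are differences
# of velocities (pixels/second^2). Signal t is aligned with frame t and
# undefined (NA) for the frames before the difference exists.

#' Vertical velocity of the hip centre
#'
#' `vy(t) = (y_midhip(t) - y_midhip(t - 1)) * fps`, in pixels/second, on the
#' raw (unsmoothed) mid-hip height. Positive values indicate descent. The
#' first element, and any frame whose mid-hip is masked, is `NA`.
#'
#' @param seq A `fall_sequence`.
#' @return Numeric vector of length `n_frames(seq)`.
#' @export
vertical_velocity <- function(seq) {
  y <- derive_landmarks(seq)$mid_hip[, "y"]
  if (sum(!is.na(y)) < 2L) {
    stopf("subject %s: fewer than 2 frames with a defined mid-hip",
          seq$subject_id)
  }
  c(NA_real_, diff(y)) * seq$fps
}

#' Trunk inclination from vertical
#'
#' Angle in degrees between the upward vertical axis and the vector from the
#' mid-hip to the mid-shoulder: 0 is upright (shoulders directly above the
#' hips in image coordinates), 90 horizontal, up to 180 fully inverted.
#' Rows with a missing landmark, or with coincident landmarks (undefined
#' angle), give `NA`; coincident landmarks additionally raise a warning.
#'
#' @param mid_hip,mid_shoulder Length-2 vectors `(x, y)` or `n x 2` matrices
#'   in image coordinates.
#' @return Numeric vector of angles in `[0, 180]` degrees.
#' @export
trunk_inclination <- function(mid_hip, mid_shoulder) {
  if (is.null(dim(mid_hip))) mid_hip <- matrix(mid_hip, ncol = 2L)
  if (is.null(dim(mid_shoulder))) mid_shoulder <- matrix(mid_shoulder, ncol = 2L)
  vx <- mid_shoulder[, 1L] - mid_hip[, 1L]
  vy <- mid_shoulder[, 2L] - mid_hip[, 2L]
  len <- sqrt(vx^2 + vy^2)
  zero <- !is.na(len) & len == 0
  if (any(zero)) warnf("%d frame(s) with coincident hip/shoulder landmarks; angle undefined",
                       sum(zero))
  len[zero] <- NA_real_
  acos(clamp(-vy / len, -1, 1)) * 180 / pi
}

#' Bounding-box aspect ratio
#'
#' `AR = width / height` of the person bounding box. Values above 1
#' typically indicate a lying posture.
#'
#' @param bbox Length-4 vector `(x_min, y_min, width, height)` or an
#'   `n x 4` matrix.
#' @return Numeric vector of ratios.
#' @export
aspect_ratio <- function(bbox) {
  if (is.null(dim(bbox))) bbox <- matrix(bbox, ncol = 4L)
  if (any(bbox[, 4L] <= 0, na.rm = TRUE)) stopf("bounding-box height must be > 0")
  bbox[, 3L] / bbox[, 4L]
}

#' Per-frame kinematic series
#'
#' Computes the per-frame signals consumed by segmentation and metric
#' aggregation: raw vertical velocity/acceleration of the mid-hip, planar
#' mid-hip speed and acceleration magnitude on coordinates smoothed by a
#' centered moving average of width `smooth_window` (second differences of
#' raw pixel coordinates are noise-dominated at 60 fps), trunk inclination,
#' bounding-box aspect ratio and the neck-protection distance (chin proxy to
#' sternum proxy).
#'
#' @param seq A `fall_sequence`.
#' @param smooth_window Moving-average width in frames (default 5).
#' @return A data.frame with one row per frame: `t`, `vy`, `ay`, `vy_smooth`,
#'   `speed`, `accel`, `trunk_angle`, `aspect_ratio`, `neck_distance`.
#' @export
kinematic_series <- function(seq, smooth_window = 5L) {
  lm <- derive_landmarks(seq)
  fps <- seq$fps
  hip <- lm$mid_hip
  vy <- c(NA_real_, diff(hip[, "y"])) * fps
  ay <- c(NA_real_, diff(vy)) * fps
  xs <- moving_average(hip[, "x"], smooth_window)
  ys <- moving_average(hip[, "y"], smooth_window)
  vx_s <- c(NA_real_, diff(xs)) * fps
  vy_s <- c(NA_real_, diff(ys)) * fps
  speed <- sqrt(vx_s^2 + vy_s^2)
  accel <- sqrt((c(NA_real_, diff(vx_s)) * fps)^2 +
                (c(NA_real_, diff(vy_s)) * fps)^2)
  neck <- sqrt(rowSums((lm$chin_proxy - lm$sternum_proxy)^2))
  list2DF(list(
    t = seq_len(n_frames(seq)),
    vy = vy,
    ay = ay,
    vy_smooth = moving_average(vy, smooth_window),
    speed = speed,
    accel = accel,
    trunk_angle = suppressWarnings(trunk_inclination(lm$mid_hip, lm$mid_shoulder)),
    aspect_ratio = aspect_ratio(seq$bbox),
    neck_distance = neck))
}

#' Segment a fall into pre-fall, impact and post-fall phases
#'
#' The vertical velocity is smoothed with a centered moving average of width
#' `smooth_window`; the descent episode is the contiguous run of smoothed
#' `vy` above `motion_floor` with the largest total descent (ties go to the
#' earlier run). The peak-deceleration frame is the frame of maximal
#' vertical deceleration (most negative `ay` of the smoothed velocity)
#' within the episode extended by `smooth_window` frames, and the impact
#' phase spans `+/- round(0.2 * fps)` frames (200 ms) around it, clipped at
#' the sequence bounds. Everything before is pre-fall, everything after
#' post-fall. For a constant-velocity descent (no deceleration anywhere)
#' the peak degenerates to the first frame of the episode.
#'
#' @param seq A `fall_sequence`.
#' @param smooth_window Moving-average width in frames (default 5).
#' @param motion_floor Minimum smoothed descent velocity, pixels/second,
#'   for a frame to count as falling (default 40).
#' @return List of class `phase_segmentation`: `pre_fall`, `impact`,
#'   `post_fall` (each `c(start, end)` positional frame indices; an empty
#'   interval has `start > end`), `peak_decel_frame`, `half_width`.
#' @export
segment_phases <- function(seq, smooth_window = 5L, motion_floor = 40) {
  segment_phases_core(kinematic_series(seq, smooth_window), seq$fps,
                      smooth_window, motion_floor, seq$subject_id)
}

segment_phases_core <- function(ks, fps, smooth_window, motion_floor,
                                subject_id = "?") {
  n <- nrow(ks)
  vs <- ks$vy_smooth
  above <- !is.na(vs) & vs > motion_floor
  if (!any(above)) {
    stopf("subject %s: no descent exceeds the motion floor (%g px/s); no fall detected",
          subject_id, motion_floor)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  tot <- vapply(runs, function(j) sum(vs[starts[j]:ends[j]]), 0)
  best <- runs[which.max(tot)]
  ep <- c(starts[best], ends[best])

  ay_s <- c(NA_real_, diff(vs)) * fps
  lo <- max(ep[1], 2L)
  hi <- min(ep[2] + smooth_window, n)
  idx <- lo:hi
  decel <- -ay_s[idx]
  peak <- idx[which.max(decel)]

  hw <- round(0.2 * fps)
  impact <- c(max(peak - hw, 1L), min(peak + hw, n))
  structure(list(
    pre_fall = c(1L, impact[1] - 1L),
    impact = impact,
    post_fall = c(impact[2] + 1L, n),
    peak_decel_frame = peak,
    half_width = hw), class = "phase_segmentation")
}
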