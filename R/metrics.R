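# Sequence-level kinematic metric vector.
#
# The 15 core metrics fall into three categories:
#   Movement  (9): avg/max velocity, avg/max acceleration, movement range
#                  x/y, high-movement frames, movement intensity, avg
#                  confidence
#   Stability (3): position variability x/y, velocity variability
#   Fall      (3): avg/max descent rate, total vertical change
# plus three postural metrics (mean trunk angle, max aspect ratio, min neck
# distance). All are aggregated over the full segmented episode, i.e. the
# whole sequence from the pre-fall start to the post-fall end.

#' Names and categories of the sequence-level metrics
#'
#' @param postural Include the three postural metrics (default `TRUE`).
#' @return Named character vector mapping metric name to category
#'   (`movement`, `stability`, `fall`, `postural`).
#' @export
metric_categories <- function(postural = TRUE) {
  m <- c(avg_velocity = "movement", max_velocity = "movement",
         avg_acceleration = "movement", max_acceleration = "movement",
         movement_range_x = "movement", movement_range_y = "movement",
         high_movement_frames = "movement", movement_intensity = "movement",
         avg_confidence = "movement",
         position_variability_x = "stability",
         position_variability_y = "stability",
         velocity_variability = "stability",
         avg_descent_rate = "fall", max_descent_rate = "fall",
         total_vertical_change = "fall")
  if (postural) {
    m <- c(m, mean_trunk_angle = "postural", max_aspect_ratio = "postural",
           min_neck_distance = "postural")
  }
  m
}

#' Metric-extraction configuration
#'
#' @param smooth_window Centered moving-average width (frames) applied to
#'   the mid-hip coordinates before differencing (default 5).
#' @param tau_move High-movement threshold: per-frame mid-hip displacement
#'   in pixels/frame above which a frame counts as high movement
#'   (default 15).
#' @param motion_floor Segmentation motion floor in pixels/second
#'   (default 40).
#' @return A named list.
#' @export
metric_config <- function(smooth_window = 5L, tau_move = 15,
                          motion_floor = 40) {
  list(smooth_window = smooth_window, tau_move = tau_move,
       motion_floor = motion_floor)
}

#' Extract the sequence-level kinematic metric vector
#'
#' Aggregates the per-frame kinematic series over the full fall episode into
#' the 15 core metrics plus 3 postural metrics. Velocity/acceleration
#' statistics use the smoothed planar mid-hip signals; positional ranges and
#' variabilities use the raw mid-hip trajectory; descent rates are the mean
#' (over the whole window, zeros included) and maximum of the positive part
#' of the smoothed vertical velocity. Phase segmentation is attempted and
#' attached as the `"phases"` attribute; a sequence with no detected fall
#' (e.g. a static pose) still yields metrics, with `segmentable = FALSE`.
#'
#' @param seq A `fall_sequence` (gap-repaired if needed).
#' @param config A [metric_config()].
#' @return A one-row data.frame of 18 metrics, with attributes `phases` and
#'   `segmentable`.
#' @export
extract_metrics <- function(seq, config = metric_config()) {
  v <- metric_values(seq, config)
  m <- as.data.frame(as.list(v$values))
  attr(m, "phases") <- v$phases
  attr(m, "segmentable") <- !is.null(v$phases)
  m
}

# fast internal path: named numeric vector of the 18 metrics
metric_values <- function(seq, config = metric_config()) {
  ks <- kinematic_series(seq, config$smooth_window)
  hip <- derive_landmarks(seq)$mid_hip
  phases <- tryCatch(
    segment_phases_core(ks, seq$fps, config$smooth_window,
                        config$motion_floor, seq$subject_id),
    error = function(e) NULL)

  disp <- sqrt(diff(hip[, "x"])^2 + diff(hip[, "y"])^2)  # px/frame, raw
  high <- !is.na(disp) & disp > config$tau_move
  vy_pos <- pmax(ks$vy_smooth, 0)

  rng <- function(x) if (all(is.na(x))) NA_real_ else diff(range(x, na.rm = TRUE))
  values <- c(
    avg_velocity = mean(ks$speed, na.rm = TRUE),
    max_velocity = max(ks$speed, na.rm = TRUE),
    avg_acceleration = mean(ks$accel, na.rm = TRUE),
    max_acceleration = max(ks$accel, na.rm = TRUE),
    movement_range_x = rng(hip[, "x"]),
    movement_range_y = rng(hip[, "y"]),
    position_variability_x = stats::sd(hip[, "x"], na.rm = TRUE),
    position_variability_y = stats::sd(hip[, "y"], na.rm = TRUE),
    velocity_variability = stats::sd(ks$speed, na.rm = TRUE),
    max_descent_rate = max(vy_pos, na.rm = TRUE),
    avg_descent_rate = mean(vy_pos, na.rm = TRUE),
    total_vertical_change = rng(hip[, "y"]),
    high_movement_frames = sum(high),
    movement_intensity = if (any(high)) mean(disp[high]) else 0,
    avg_confidence = mean(seq$keypoints[, , 3L]),
    mean_trunk_angle = mean(ks$trunk_angle, na.rm = TRUE),
    max_aspect_ratio = max(ks$aspect_ratio, na.rm = TRUE),
    min_neck_distance = min(ks$neck_distance, na.rm = TRUE))
  list(values = values, phases = phases)
}

#' Metric table for a list of sequences
#'
#' Runs [repair_gaps()] and [extract_metrics()] on every sequence and binds
#' the results with subject metadata.
#'
#' @param seqs List of `fall_sequence` objects.
#' @param config A [metric_config()].
#' @param repair Run gap repair first (default `TRUE`).
#' @return A data.frame with `subject_id`, `cohort`, `quality_label`,
#'   `profile` (when generator metadata is present) and the 18 metrics.
#' @export
cohort_metrics <- function(seqs, config = metric_config(), repair = TRUE) {
  vals <- matrix(NA_real_, length(seqs), length(metric_categories()),
                 dimnames = list(NULL, names(metric_categories())))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (repair) s <- repair_gaps(s)
    mv <- metric_values(s, config)$values
    vals[i, ] <- mv[colnames(vals)]
  }
  cbind(
    list2DF(list(
      subject_id = vapply(seqs, function(s) s$subject_id, ""),
      cohort = vapply(seqs, function(s) s$cohort, ""),
      quality_label = vapply(seqs, function(s)
        s$quality_label %||% NA_character_, ""),
      profile = vapply(seqs, function(s)
        s$meta$profile %||% NA_character_, ""))),
    as.data.frame(vals))
}

#' Core 15-metric column names
#' @return Character vector of the 15 core metric names.
#' @export
core_metric_names <- function() names(metric_categories(postural = FALSE))
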