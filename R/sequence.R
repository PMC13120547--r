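#' COCO-17 keypoint names
#'
#' Canonical ordering of the 17 COCO-convention anatomical keypoints used
#' throughout the package: nose, eyes, ears, shoulders, elbows, wrists,
#' hips, knees, ankles.
#'
#' @return Character vector of length 17.
#' @export
coco_keypoints <- function() {
  c("nose",
    "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Construct a tracked pose sequence
#'
#' A `fall_sequence` holds one tracked identity's time-ordered 2D skeleton
#' frames as produced by a top-down pose-estimation pipeline: per frame, 17
#' COCO keypoints (x, y, confidence), a visibility mask, and a bounding box.
#' Image coordinates have their origin at the top-left corner with y
#' increasing downward, so descent corresponds to increasing y.
#'
#' @param subject_id Opaque subject identifier.
#' @param fps Recording frame rate (frames/second, > 0).
#' @param keypoints Numeric array `n_frames x 17 x 3`, the last dimension
#'   being (x, y, confidence).
#' @param frame_size Integer vector `(width, height)` in pixels.
#' @param track_id Integer tracker identity (default 1).
#' @param visibility Logical `n_frames x 17` matrix, `TRUE` = usable. When
#'   `NULL`, all keypoints are marked visible.
#' @param bbox Numeric `n_frames x 4` matrix `(x_min, y_min, width, height)`.
#'   When `NULL`, boxes are derived from the visible keypoints with a
#'   5-pixel margin.
#' @param frame_index Strictly increasing integer vector; defaults to
#'   `0:(n_frames - 1)`.
#' @param cohort One of `"pre"`, `"post"`, `"unknown"`.
#' @param quality_label Optional `"safe"` / `"hazardous"` ground truth.
#' @param imputed Logical `n_frames x 17` matrix flagging interpolated
#'   keypoints (default all `FALSE`).
#' @param meta Free-form list of generator/provenance metadata.
#'
#' @return An object of class `fall_sequence`.
#' @seealso [validate_sequence()], [read_sequences()], [simulate_fall()]
#' @export
fall_sequence <- function(subject_id, fps, keypoints, frame_size,
                          track_id = 1L, visibility = NULL, bbox = NULL,
                          frame_index = NULL, cohort = "unknown",
                          quality_label = NA_character_, imputed = NULL,
                          meta = list()) {
  if (length(dim(keypoints)) != 3L || dim(keypoints)[2] != 17L ||
      dim(keypoints)[3] != 3L) {
    stopf("`keypoints` must be an n x 17 x 3 array (x, y, confidence)")
  }
  n <- dim(keypoints)[1]
  dimnames(keypoints) <- list(NULL, coco_keypoints(), c("x", "y", "confidence"))
  if (is.null(visibility)) visibility <- matrix(TRUE, n, 17L)
  if (is.null(imputed)) imputed <- matrix(FALSE, n, 17L)
  colnames(visibility) <- coco_keypoints()
  colnames(imputed) <- coco_keypoints()
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  if (is.null(bbox)) bbox <- bbox_from_keypoints(keypoints, visibility)
  colnames(bbox) <- c("x_min", "y_min", "width", "height")
  seq <- structure(
    list(subject_id = as.character(subject_id),
         track_id = as.integer(track_id),
         fps = as.numeric(fps),
         frame_size = as.numeric(frame_size),
         frame_index = as.integer(frame_index),
         keypoints = keypoints,
         visibility = visibility,
         imputed = imputed,
         bbox = bbox,
         cohort = match.arg(cohort, c("pre", "post", "unknown")),
         quality_label = quality_label,
         meta = meta),
    class = "fall_sequence")
  seq
}

bbox_from_keypoints <- function(kp, visibility, margin = 5) {
  xs <- kp[, , 1L]; ys <- kp[, , 2L]
  # frames with no visible keypoint fall back to all keypoints
  mask <- visibility | !matrix(rowSums(visibility) > 0, nrow(visibility), 17L)
  xs[!mask] <- NA_real_; ys[!mask] <- NA_real_
  cols <- function(m) lapply(seq_len(ncol(m)), function(k) m[, k])
  x_min <- do.call(pmin, c(cols(xs), na.rm = TRUE))
  x_max <- do.call(pmax, c(cols(xs), na.rm = TRUE))
  y_min <- do.call(pmin, c(cols(ys), na.rm = TRUE))
  y_max <- do.call(pmax, c(cols(ys), na.rm = TRUE))
  cbind(x_min - margin, y_min - margin,
        x_max - x_min + 2 * margin, y_max - y_min + 2 * margin)
}

#' Number of frames in a sequence
#' @param seq A `fall_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$keypoints)[1]

#' Validate (and lightly repair) a tracked sequence
#'
#' Checks the structural invariants of a `fall_sequence`: exactly 17
#' keypoints per frame, strictly increasing frame indices, positive fps and
#' bounding-box extents. Confidences outside `[0, 1]` and coordinates
#' outside the frame are clamped with a warning, mirroring how defensive
#' consumers treat slightly out-of-range pose-estimator output.
#'
#' @param seq A `fall_sequence`.
#' @param clamp Clamp out-of-range confidences/coordinates instead of
#'   failing (default `TRUE`).
#' @return The validated (possibly clamped) sequence.
#' @export
validate_sequence <- function(seq, clamp = TRUE) {
  if (!inherits(seq, "fall_sequence")) stopf("not a fall_sequence")
  n <- n_frames(seq)
  if (seq$fps <= 0) stopf("fps must be > 0 (subject %s)", seq$subject_id)
  if (length(seq$frame_size) != 2L || any(seq$frame_size <= 0)) {
    stopf("frame_size must be positive (width, height)")
  }
  if (n >= 2L && any(diff(seq$frame_index) <= 0)) {
    stopf("frame_index must be strictly increasing (subject %s)", seq$subject_id)
  }
  if (any(seq$bbox[, 3:4] <= 0, na.rm = TRUE)) {
    stopf("bounding boxes must have positive width and height (subject %s)",
          seq$subject_id)
  }
  conf <- seq$keypoints[, , 3L]
  if (any(conf < 0 | conf > 1)) {
    if (!clamp) stopf("confidence outside [0, 1] (subject %s)", seq$subject_id)
    warnf("subject %s: %d confidence value(s) outside [0, 1] clamped",
          seq$subject_id, sum(conf < 0 | conf > 1))
    seq$keypoints[, , 3L] <- clamp(conf, 0, 1)
  }
  w <- seq$frame_size[1]; h <- seq$frame_size[2]
  xs <- seq$keypoints[, , 1L]; ys <- seq$keypoints[, , 2L]
  n_out <- sum(xs < 0 | xs > w | ys < 0 | ys > h, na.rm = TRUE)
  if (n_out > 0) {
    if (!clamp) stopf("coordinates outside the frame (subject %s)", seq$subject_id)
    warnf("subject %s: %d coordinate value(s) outside the frame clamped",
          seq$subject_id, n_out)
    seq$keypoints[, , 1L] <- clamp(xs, 0, w)
    seq$keypoints[, , 2L] <- clamp(ys, 0, h)
  }
  seq
}

#' @export
print.fall_sequence <- function(x, ...) {
  cat(sprintf("<fall_sequence> subject %s (track %d): %d frames @ %g fps, %gx%g px\n",
              x$subject_id, x$track_id, n_frames(x), x$fps,
              x$frame_size[1], x$frame_size[2]))
  cat(sprintf("  cohort: %s   quality: %s   visible: %.1f%%   imputed: %.1f%%\n",
              x$cohort, ifelse(is.na(x$quality_label), "-", x$quality_label),
              100 * mean(x$visibility), 100 * mean(x$imputed)))
  invisible(x)
}

#' Derive composite anatomical landmarks
#'
#' Computes per-frame derived landmarks from the 17 COCO keypoints:
#' `mid_hip` (mean of the two hips, the centre-of-mass proxy),
#' `mid_shoulder` (mean of the two shoulders), `chin_proxy` (the nose — the
#' closest stable COCO proxy for the chin) and `sternum_proxy` (the shoulder
#' midpoint). A landmark is `NA` on frames where any of its source
#' keypoints is not visible.
#'
#' @param seq A `fall_sequence`.
#' @return A list of four `n_frames x 2` matrices (columns x, y):
#'   `mid_hip`, `mid_shoulder`, `chin_proxy`, `sternum_proxy`.
#' @export
derive_landmarks <- function(seq) {
  kp <- seq$keypoints
  vis <- seq$visibility
  pair_mid <- function(a, b) {
    m <- (kp[, a, 1:2, drop = FALSE] + kp[, b, 1:2, drop = FALSE]) / 2
    m <- matrix(m, ncol = 2L)
    m[!(vis[, a] & vis[, b]), ] <- NA_real_
    colnames(m) <- c("x", "y")
    m
  }
  mid_hip <- pair_mid("left_hip", "right_hip")
  mid_shoulder <- pair_mid("left_shoulder", "right_shoulder")
  chin <- matrix(kp[, "nose", 1:2], ncol = 2L,
                 dimnames = list(NULL, c("x", "y")))
  chin[!vis[, "nose"], ] <- NA_real_
  list(mid_hip = mid_hip,
       mid_shoulder = mid_shoulder,
       chin_proxy = chin,
       sternum_proxy = mid_shoulder)
}
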