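# Frame-level feature expansion for supervised fall-quality classification.
#
# Schema (version 1): for each of the 17 COCO keypoints the raw x, y and
# confidence columns; the 4 derived landmark coordinate pairs; first and
# second temporal derivatives (backward differences scaled by fps and
# fps^2, zero-padded at the sequence start) of all 21 point coordinates;
# trunk angle, aspect ratio and neck distance with their first derivatives;
# and the per-frame mid-hip centroid displacement. 150 columns in total.

FEATURE_SCHEMA_VERSION <- 1L

#' Column schema of the frame-level feature matrix
#'
#' @return Character vector of the 150 column names, with attribute
#'   `version`.
#' @export
frame_feature_schema <- function() {
  kps <- coco_keypoints()
  lms <- c("mid_hip", "mid_shoulder", "chin_proxy", "sternum_proxy")
  raw <- c(t(outer(kps, c("x", "y", "confidence"), paste, sep = "_")))
  lmc <- c(t(outer(lms, c("x", "y"), paste, sep = "_")))
  pts <- c(c(t(outer(kps, c("x", "y"), paste, sep = "_"))), lmc)
  cols <- c(raw, lmc,
            paste0("d1_", pts), paste0("d2_", pts),
            "trunk_angle", "aspect_ratio", "neck_distance",
            "d1_trunk_angle", "d1_aspect_ratio", "d1_neck_distance",
            "centroid_displacement")
  attr(cols, "version") <- FEATURE_SCHEMA_VERSION
  cols
}

#' Frame-level feature matrix
#'
#' Expands a (repaired) sequence into the per-frame feature matrix used for
#' supervised classification: raw keypoint coordinates and confidences,
#' derived landmarks, first/second temporal derivatives of all 21 point
#' coordinates, the three postural signals with their first derivatives,
#' and the per-frame centroid displacement. Derivatives are backward finite
#' differences scaled by fps (and fps squared), zero-padded at the start so
#' a constant pose yields all-zero derivative columns. Masked landmark
#' coordinates propagate as NA.
#'
#' @param seq A `fall_sequence`.
#' @param smooth_window Width for the postural-signal smoothing used only by
#'   the underlying kinematic series (default 5).
#' @return Numeric matrix `n_frames x 150` with [frame_feature_schema()]
#'   column names.
#' @export
extract_frame_features <- function(seq, smooth_window = 5L) {
  n <- n_frames(seq)
  fps <- seq$fps
  lm <- derive_landmarks(seq)
  d1 <- function(x) if (n < 2L) rep(0, n) else c(0, diff(x) * fps)
  # second derivative as the difference of first derivatives (not a single
  # second difference) so it is bit-identical to the naive two-pass loop
  d2 <- function(x) {
    if (n < 3L) return(rep(0, n))
    c(0, 0, diff(diff(x) * fps) * fps)
  }

  raw <- seq$keypoints
  raw_mat <- do.call(cbind, lapply(seq_len(17L), function(k) raw[, k, ]))
  lm_mat <- cbind(lm$mid_hip, lm$mid_shoulder, lm$chin_proxy, lm$sternum_proxy)

  pts <- cbind(do.call(cbind, lapply(seq_len(17L), function(k) raw[, k, 1:2])),
               lm_mat)
  d1_mat <- apply(pts, 2L, d1)
  d2_mat <- apply(pts, 2L, d2)
  if (n == 1L) { d1_mat <- matrix(d1_mat, 1L); d2_mat <- matrix(d2_mat, 1L) }

  ks <- kinematic_series(seq, smooth_window)
  hip <- lm$mid_hip
  centroid_disp <- c(0, sqrt(diff(hip[, "x"])^2 + diff(hip[, "y"])^2))

  out <- cbind(raw_mat, lm_mat, d1_mat, d2_mat,
               ks$trunk_angle, ks$aspect_ratio, ks$neck_distance,
               d1(ks$trunk_angle), d1(ks$aspect_ratio), d1(ks$neck_distance),
               centroid_disp)
  colnames(out) <- as.character(frame_feature_schema())
  out
}

#' Frame-level feature table for a cohort
#'
#' Binds [extract_frame_features()] over sequences, keeping subject metadata
#' columns for grouped cross-validation, and optionally restricting to the
#' segmented fall episode and/or subsampling frames.
#'
#' @param seqs List of `fall_sequence` objects.
#' @param stride Keep every `stride`-th frame (default 1 = all).
#' @param repair Run gap repair first (default `TRUE`).
#' @return A data.frame: `subject_id`, `cohort`, `quality_label`, `frame`,
#'   then the 150 feature columns.
#' @export
cohort_frame_features <- function(seqs, stride = 1L, repair = TRUE) {
  rows <- lapply(seqs, function(s) {
    if (repair) s <- repair_gaps(s)
    f <- extract_frame_features(s)
    keep <- seq(1L, nrow(f), by = stride)
    cbind(data.frame(subject_id = s$subject_id, cohort = s$cohort,
                     quality_label = s$quality_label, frame = keep,
                     stringsAsFactors = FALSE),
          as.data.frame(f[keep, , drop = FALSE]))
  })
  do.call(rbind, rows)
}
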