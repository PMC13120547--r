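# Pose-JSON dialect
#
# Top level object:
#   format:   "safefall-pose"
#   version:  "1.0"
#   sequences: array of identities, each with
#     subject_id, track_id, fps, frame_size [w, h], cohort,
#     quality_label (nullable), meta (object), frames: array of
#       { frame_index, bbox [x_min, y_min, width, height],
#         keypoints: 17 x [x, y, confidence] in COCO order,
#         visibility: 17 booleans, imputed: 17 booleans }
# A machine-readable copy of this schema ships in
# inst/extdata/pose-schema.json.

POSE_FORMAT <- "safefall-pose"
POSE_VERSION <- "1.0"

#' Read tracked pose sequences from a pose-JSON file
#'
#' Parses the documented pose-JSON dialect (see
#' `system.file("extdata", "pose-schema.json", package = "safefall")`) into a
#' list of [fall_sequence] objects. Every sequence is validated; confidences
#' outside `[0, 1]` are clamped with a warning.
#'
#' @param path Path to a pose-JSON file.
#' @return List of `fall_sequence` objects.
#' @seealso [write_sequences()]
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stopf("malformed JSON in %s: %s",
                                            path, conditionMessage(e)))
  if (!identical(doc$format, POSE_FORMAT)) {
    stopf("%s: not a %s file (format field: %s)",
          path, POSE_FORMAT, doc$format %||% "<missing>")
  }
  lapply(seq_along(doc$sequences), function(i) {
    rec <- doc$sequences[[i]]
    frames <- rec$frames
    n <- length(frames)
    if (n == 0L) stopf("record %d (subject %s): no frames", i,
                       rec$subject_id %||% "<missing>")
    kp <- array(NA_real_, c(n, 17L, 3L))
    vis <- matrix(TRUE, n, 17L)
    imp <- matrix(FALSE, n, 17L)
    bbox <- matrix(NA_real_, n, 4L)
    fidx <- integer(n)
    for (t in seq_len(n)) {
      fr <- frames[[t]]
      if (length(fr$keypoints) != 17L) {
        stopf("record %d (subject %s), frame %d: expected 17 keypoints, got %d",
              i, rec$subject_id, t, length(fr$keypoints))
      }
      kp[t, , ] <- matrix(unlist(fr$keypoints), 17L, 3L, byrow = TRUE)
      if (!is.null(fr$visibility)) vis[t, ] <- unlist(fr$visibility)
      if (!is.null(fr$imputed)) imp[t, ] <- unlist(fr$imputed)
      bbox[t, ] <- unlist(fr$bbox)
      fidx[t] <- fr$frame_index
    }
    validate_sequence(fall_sequence(
      subject_id = rec$subject_id,
      track_id = rec$track_id %||% 1L,
      fps = rec$fps,
      frame_size = unlist(rec$frame_size),
      keypoints = kp, visibility = vis, imputed = imp, bbox = bbox,
      frame_index = fidx,
      cohort = rec$cohort %||% "unknown",
      quality_label = rec$quality_label %||% NA_character_,
      meta = rec$meta %||% list()))
  })
}

#' Write tracked pose sequences to a pose-JSON file
#'
#' Serializes sequences to the documented pose-JSON dialect with a fixed key
#' ordering, so identical inputs always produce byte-identical files.
#' `read_sequences(write_sequences(x))` reproduces the data model (numeric
#' values round-trip at 15 significant digits).
#'
#' @param seqs List of [fall_sequence] objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  recs <- lapply(seqs, function(s) {
    n <- n_frames(s)
    frames <- lapply(seq_len(n), function(t) {
      list(frame_index = s$frame_index[t],
           bbox = unname(s$bbox[t, ]),
           keypoints = lapply(seq_len(17L), function(k) unname(s$keypoints[t, k, ])),
           visibility = unname(s$visibility[t, ]),
           imputed = unname(s$imputed[t, ]))
    })
    list(subject_id = s$subject_id,
         track_id = s$track_id,
         fps = s$fps,
         frame_size = unname(s$frame_size),
         cohort = s$cohort,
         quality_label = s$quality_label,
         meta = s$meta,
         frames = frames)
  })
  doc <- list(format = POSE_FORMAT, version = POSE_VERSION, sequences = recs)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Mask low-confidence keypoints and interpolate short occlusion gaps
#'
#' Pose estimators drop or misplace keypoints during self-occlusion. This
#' repair pass (1) marks keypoints with confidence below `conf_floor` as not
#' visible, then (2) linearly interpolates each invisible run of at most
#' `max_gap` frames per keypoint coordinate, flagging the filled frames in
#' the `imputed` mask and setting their confidence to `conf_floor` so the
#' operation is idempotent. Runs longer than `max_gap`, and runs touching
#' the sequence ends, stay masked — endpoints are never extrapolated.
#'
#' @param seq A `fall_sequence`.
#' @param conf_floor Confidence threshold below which a keypoint is treated
#'   as missing (default 0.5, the usual detection threshold upstream).
#' @param max_gap Longest run, in frames, that is interpolated
#'   (default 10, about 167 ms at 60 fps — shorter than the impact window).
#' @return The repaired `fall_sequence`.
#' @export
repair_gaps <- function(seq, conf_floor = 0.5, max_gap = 10L) {
  n <- n_frames(seq)
  if (n < 3L) return(seq)
  vis <- seq$visibility & (seq$keypoints[, , 3L] >= conf_floor)
  if (all(vis)) return(seq)
  xs <- seq$keypoints[, , 1L]
  ys <- seq$keypoints[, , 2L]
  cf <- seq$keypoints[, , 3L]
  imp <- seq$imputed
  for (k in which(colSums(!vis) > 0L)) {
    miss <- !vis[, k]
    if (all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      s <- starts[j]; e <- ends[j]
      if (s == 1L || e == n || (e - s + 1L) > max_gap) next
      idx <- s:e
      w <- (idx - (s - 1L)) / (e - s + 2L)
      xs[idx, k] <- xs[s - 1L, k] + w * (xs[e + 1L, k] - xs[s - 1L, k])
      ys[idx, k] <- ys[s - 1L, k] + w * (ys[e + 1L, k] - ys[s - 1L, k])
      cf[idx, k] <- conf_floor
      imp[idx, k] <- TRUE
      vis[idx, k] <- TRUE
    }
  }
  seq$keypoints[, , 1L] <- xs
  seq$keypoints[, , 2L] <- ys
  seq$keypoints[, , 3L] <- cf
  seq$imputed <- imp
  seq$visibility <- vis
  seq
}

#' Flatten a sequence's keypoints to a long data frame
#'
#' One row per frame and keypoint, for CSV export and interoperability.
#'
#' @param seq A `fall_sequence`.
#' @return A data.frame with columns subject_id, track_id, frame_index,
#'   keypoint, x, y, confidence, visible, imputed.
#' @export
flatten_keypoints <- function(seq) {
  n <- n_frames(seq)
  data.frame(
    subject_id = seq$subject_id,
    track_id = seq$track_id,
    frame_index = rep(seq$frame_index, each = 17L),
    keypoint = rep(coco_keypoints(), times = n),
    x = as.vector(t(seq$keypoints[, , 1L])),
    y = as.vector(t(seq$keypoints[, , 2L])),
    confidence = as.vector(t(seq$keypoints[, , 3L])),
    visible = as.vector(t(seq$visibility)),
    imputed = as.vector(t(seq$imputed)),
    stringsAsFactors = FALSE)
}
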