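{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "safefall-pose",
  "description": "Tracked 2D skeleton sequences emulating pose-estimation pipeline output. Image coordinates: origin top-left, y increases downward. Keypoints follow COCO-17 order: nose, left_eye, right_eye, left_ear, right_ear, left_shoulder, right_shoulder, left_elbow, right_elbow, left_wrist, right_wrist, left_hip, right_hip, left_knee, right_knee, left_ankle, right_ankle.",
  "type": "object",
  "required": ["format", "version", "sequences"],
  "properties": {
    "format": {"const": "safefall-pose"},
    "version": {"type": "string"},
    "sequences": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subject_id", "fps", "frame_size", "frames"],
        "properties": {
          "subject_id": {"type": "string"},
          "track_id": {"type": "integer"},
          "fps": {"type": "number", "exclusiveMinimum": 0},
          "frame_size": {
            "type": "array", "items": {"type": "number"},
            "minItems": 2, "maxItems": 2,
            "description": "[width, height] in pixels"
          },
          "cohort": {"enum": ["pre", "post", "unknown"]},
          "quality_label": {"enum": ["safe", "hazardous", null]},
          "meta": {"type": "object"},
          "frames": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["frame_index", "bbox", "keypoints"],
              "properties": {
                "frame_index": {"type": "integer", "minimum": 0},
                "bbox": {
                  "type": "array", "items": {"type": "number"},
                  "minItems": 4, "maxItems": 4,
                  "description": "[x_min, y_min, width, height]; width and height > 0"
                },
                "keypoints": {
                  "type": "array", "minItems": 17, "maxItems": 17,
                  "items": {
                    "type": "array", "items": {"type": "number"},
                    "minItems": 3, "maxItems": 3,
                    "description": "[x, y, confidence]; confidence in [0, 1]"
                  }
                },
                "visibility": {
                  "type": "array", "items": {"type": "boolean"},
                  "minItems": 17, "maxItems": 17
                },
                "imputed": {
                  "type": "array", "items": {"type": "boolean"},
                  "minItems": 17, "maxItems": 17
                }
              }
            }
          }
        }
      }
    }
  }
}
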