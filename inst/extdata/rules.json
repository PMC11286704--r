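[
  {
    "object_class": "fat_rim",
    "comment": "thin bright shell tracing the body contour: very wide bounding box, very low face-count sphericity",
    "predicates": [
      {"feature": "bbox_x_mm", "min": 90},
      {"feature": "sphericity", "max": 0.35},
      {"feature": "volume_ml", "min": 5}
    ]
  },
  {
    "object_class": "spinal_canal",
    "comment": "thin craniocaudal cylinder at the posterior midline spanning most of the stack",
    "predicates": [
      {"feature": "craniocaudal_span_frac", "min": 0.6},
      {"feature": "centroid_x", "min": 0.4, "max": 0.6},
      {"feature": "sphericity", "max": 0.45},
      {"feature": "principal_axis_angle_deg", "max": 20}
    ]
  },
  {
    "object_class": "bladder",
    "comment": "large compact inferior midline ellipsoid",
    "predicates": [
      {"feature": "volume_ml", "min": 25},
      {"feature": "centroid_y", "min": 0.7},
      {"feature": "centroid_x", "min": 0.3, "max": 0.7},
      {"feature": "sphericity", "min": 0.55}
    ]
  },
  {
    "object_class": "gallbladder",
    "comment": "compact right-upper-quadrant ellipsoid, anterior half",
    "predicates": [
      {"feature": "volume_ml", "min": 3, "max": 30},
      {"feature": "centroid_y", "max": 0.42},
      {"feature": "centroid_x", "max": 0.45},
      {"feature": "centroid_z", "max": 0.55},
      {"feature": "sphericity", "min": 0.5}
    ]
  },
  {
    "object_class": "renal_pelvis_ureter",
    "comment": "small paramedian branched blob, posterior half (right)",
    "predicates": [
      {"feature": "volume_ml", "min": 1, "max": 12},
      {"feature": "centroid_x", "min": 0.12, "max": 0.42},
      {"feature": "centroid_y", "min": 0.3, "max": 0.62},
      {"feature": "centroid_z", "min": 0.5}
    ]
  },
  {
    "object_class": "renal_pelvis_ureter",
    "comment": "small paramedian branched blob, posterior half (left)",
    "predicates": [
      {"feature": "volume_ml", "min": 1, "max": 12},
      {"feature": "centroid_x", "min": 0.58, "max": 0.88},
      {"feature": "centroid_y", "min": 0.3, "max": 0.62},
      {"feature": "centroid_z", "min": 0.5}
    ]
  },
  {
    "object_class": "intervertebral_disc",
    "comment": "small oblate spheroids stacked at the posterior midline",
    "predicates": [
      {"feature": "volume_ml", "max": 4},
      {"feature": "centroid_x", "min": 0.35, "max": 0.65},
      {"feature": "centroid_z", "min": 0.55},
      {"feature": "sphericity", "min": 0.45}
    ]
  }
]
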