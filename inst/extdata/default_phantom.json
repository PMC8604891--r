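{
  "description": "Synthetic head-and-neck voxel phantom: three nested ellipsoidal PTVs (simultaneous integrated boost, 33 fractions) with laterally placed parotids, posterior midline spinal canal, superior brainstem/brain, inferior brachial plexus and esophagus, anterior glottis/mandible/oral cavity. Geometry is synthetic: topology and spatial trade-offs emulate a head-and-neck case, not patient anatomy.",
  "grid_shape": [80, 80, 80],
  "spacing_mm": [2.0, 2.0, 2.0],
  "fractions": 33,
  "prescriptions_gy": {"ptv1": 69.96, "ptv2": 59.4, "ptv3": 54.0},
  "structures": [
    {"name": "ptv1",            "shape": "ellipsoid", "center_mm": [80, 88, 80],   "size_mm": [16, 14, 18]},
    {"name": "ptv2",            "shape": "ellipsoid", "center_mm": [80, 88, 80],   "size_mm": [26, 22, 30]},
    {"name": "ptv3",            "shape": "ellipsoid", "center_mm": [80, 84, 80],   "size_mm": [40, 34, 46]},
    {"name": "spinal_canal",    "shape": "cylinder",  "center_mm": [80, 30, 80],   "size_mm": [5, 5, 60]},
    {"name": "parotid_left",    "shape": "ellipsoid", "center_mm": [26, 84, 90],   "size_mm": [9, 12, 14]},
    {"name": "parotid_right",   "shape": "ellipsoid", "center_mm": [134, 84, 90],  "size_mm": [9, 12, 14]},
    {"name": "brainstem",       "shape": "ellipsoid", "center_mm": [80, 55, 144],  "size_mm": [7, 7, 10]},
    {"name": "brain",           "shape": "ellipsoid", "center_mm": [80, 95, 150],  "size_mm": [28, 22, 8]},
    {"name": "brachial_plexus", "shape": "ellipsoid", "center_mm": [80, 75, 24],   "size_mm": [35, 8, 8]},
    {"name": "esophagus",       "shape": "cylinder",  "center_mm": [80, 42, 38],   "size_mm": [5, 5, 22]},
    {"name": "glottis",         "shape": "ellipsoid", "center_mm": [80, 126, 70],  "size_mm": [7, 6, 9]},
    {"name": "mandible",        "shape": "ellipsoid", "center_mm": [80, 124, 112], "size_mm": [30, 10, 8]},
    {"name": "oral_cavity",     "shape": "ellipsoid", "center_mm": [80, 128, 90],  "size_mm": [18, 9, 12]}
  ]
}
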