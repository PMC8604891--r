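{
  "name": "hn_mrl_challenge_reconstructed",
  "version": 1,
  "provenance": "reconstructed",
  "description": "Tiered 150-point plan quality metric: 6 PTV submetrics (max 78) and 10 OAR submetrics (max 72). Tier boundaries and hard bounds are reconstructed defaults, not the original challenge values: ideal coverage thresholds follow the 95%/107%-of-prescription convention, conformation-number bands are 0.8 (ideal) / 0.7 (good) / 0.6 (acceptable), and every boundary is overridable in this file. Boundaries are listed from worst to best in each metric's direction of improvement; a value exactly on a boundary takes the better tier. Binary metrics award full points on pass and 0 on fail.",
  "tier_labels": ["unacceptable", "marginal", "acceptable", "good", "ideal"],
  "gates": {
    "max_delivery_min": 20,
    "hard_constraints": [
      {"metric_id": "ptv1_d95",               "bound": 63.0, "direction": "higher_better"},
      {"metric_id": "spinal_canal_d0_1cc",    "bound": 50.0, "direction": "lower_better"},
      {"metric_id": "brainstem_d0_1cc",       "bound": 54.0, "direction": "lower_better"},
      {"metric_id": "brachial_plexus_d0_5cc", "bound": 54.0, "direction": "lower_better"},
      {"metric_id": "brain_d0_1cc",           "bound": 54.0, "direction": "lower_better"},
      {"metric_id": "mandible_d0_1cc",        "bound": 66.0, "direction": "lower_better"}
    ]
  },
  "metrics": [
    {"metric_id": "ptv1_d95", "label": "PTV1 D95% [Gy]", "structure": "ptv1",
     "kind": "D_percent", "parameter": 95, "direction": "higher_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [63.0, 64.5, 65.5, 66.5],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "ptv1_d0_1cc", "label": "PTV1 D0.1cc [Gy]", "structure": "ptv1",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [79.8, 78.0, 76.8, 74.9],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "ptv2_d95", "label": "PTV2 D95% [Gy]", "structure": "ptv2",
     "kind": "D_percent", "parameter": 95, "direction": "higher_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [53.5, 55.0, 56.0, 57.0],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "ptv3_d95", "label": "PTV3 D95% [Gy]", "structure": "ptv3",
     "kind": "D_percent", "parameter": 95, "direction": "higher_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [48.6, 49.5, 50.4, 51.3],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "ptv3_ptv2_v56_7", "label": "PTV3-PTV2 V56.7Gy [%]", "structure": "ptv3-ptv2",
     "kind": "V_gy_percent", "parameter": 56.7, "direction": "lower_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [45, 38, 31, 25],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "ptv3_cn", "label": "PTV3 conformation", "structure": "ptv3",
     "kind": "conformation", "parameter": 54.0, "direction": "higher_better", "group": "PTV",
     "schedule": {"mode": "tiered", "max_points": 13,
                  "boundaries": [0.5, 0.6, 0.7, 0.8],
                  "tier_points": [0, 3.25, 6.5, 9.75, 13]}},
    {"metric_id": "spinal_canal_d0_1cc", "label": "Spinal canal D0.1cc [Gy]", "structure": "spinal_canal",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [50.0, 48.0, 46.5, 45.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "parotid_left_dmean", "label": "Parotid gland left Dmean [Gy]", "structure": "parotid_left",
     "kind": "D_mean", "parameter": null, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [32.0, 30.0, 28.0, 26.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "parotid_right_dmean", "label": "Parotid gland right Dmean [Gy]", "structure": "parotid_right",
     "kind": "D_mean", "parameter": null, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [31.0, 29.0, 27.0, 25.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "brainstem_d0_1cc", "label": "Brainstem D0.1cc [Gy]", "structure": "brainstem",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [54.0, 50.0, 47.0, 44.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "brachial_plexus_d0_5cc", "label": "Brachial plexus D0.5cc [Gy]", "structure": "brachial_plexus",
     "kind": "D_cc", "parameter": 0.5, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "binary", "max_points": 6,
                  "boundaries": [54.0],
                  "tier_points": [0, 6]}},
    {"metric_id": "brain_d0_1cc", "label": "Brain D0.1cc [Gy]", "structure": "brain",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "binary", "max_points": 6,
                  "boundaries": [54.0],
                  "tier_points": [0, 6]}},
    {"metric_id": "esophagus_d0_1cc", "label": "Esophagus D0.1cc [Gy]", "structure": "esophagus",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [54.0, 51.0, 48.0, 45.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "glottis_dmean", "label": "Glottis Dmean [Gy]", "structure": "glottis",
     "kind": "D_mean", "parameter": null, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [50.0, 48.0, 45.5, 43.5],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "mandible_d0_1cc", "label": "Mandible D0.1cc [Gy]", "structure": "mandible",
     "kind": "D_cc", "parameter": 0.1, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [66.0, 64.0, 62.0, 60.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}},
    {"metric_id": "oral_cavity_dmean", "label": "Oral cavity Dmean [Gy]", "structure": "oral_cavity",
     "kind": "D_mean", "parameter": null, "direction": "lower_better", "group": "OAR",
     "schedule": {"mode": "tiered", "max_points": 7.5,
                  "boundaries": [45.0, 41.0, 38.0, 35.0],
                  "tier_points": [0, 1.875, 3.75, 5.625, 7.5]}}
  ]
}
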