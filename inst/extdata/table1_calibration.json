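{
  "description": "Cohort calibration: per-field truncated-normal marginals (scale = reported SD, bounds = reported range, location solved so the distribution median matches the reported median) and the rank correlations reported for the study cohort. The conformation-number SD is reported to one decimal as 0.0; 0.04 is used as the scale floor. pqm_latent and ptv_latent are standard-normal latent plan-quality factors carrying the correlations of segment count with overall and PTV-subtotal plan quality; they are mutually correlated at 0.9 because the overall score contains the PTV subtotal and the PTV subtotal dominates its spread (SD 5.5 of 6.5) - leaving them independent would make the reported segment correlations jointly infeasible.",
  "fields": [
    {"id": "ptv1_d95",              "unit": "Gy",  "mean": 67.5,  "sd": 1.2,   "median": 67.0,  "min": 66.2,  "max": 69.7},
    {"id": "ptv1_d0_1cc",           "unit": "Gy",  "mean": 74.1,  "sd": 1.3,   "median": 73.9,  "min": 72.0,  "max": 76.6},
    {"id": "ptv2_d95",              "unit": "Gy",  "mean": 59.0,  "sd": 1.0,   "median": 58.9,  "min": 57.5,  "max": 60.8},
    {"id": "ptv3_d95",              "unit": "Gy",  "mean": 52.4,  "sd": 0.8,   "median": 52.6,  "min": 50.7,  "max": 53.5},
    {"id": "ptv3_ptv2_v56_7",       "unit": "%",   "mean": 22.3,  "sd": 7.8,   "median": 21.6,  "min": 8.3,   "max": 35.8},
    {"id": "ptv3_cn",               "unit": "1",   "mean": 0.7,   "sd": 0.04,  "median": 0.7,   "min": 0.7,   "max": 0.8},
    {"id": "spinal_canal_d0_1cc",   "unit": "Gy",  "mean": 44.0,  "sd": 2.4,   "median": 43.4,  "min": 39.0,  "max": 48.8},
    {"id": "parotid_left_dmean",    "unit": "Gy",  "mean": 22.0,  "sd": 1.5,   "median": 22.3,  "min": 17.8,  "max": 23.8},
    {"id": "parotid_right_dmean",   "unit": "Gy",  "mean": 26.4,  "sd": 1.4,   "median": 26.0,  "min": 24.4,  "max": 29.1},
    {"id": "brainstem_d0_1cc",      "unit": "Gy",  "mean": 42.1,  "sd": 4.0,   "median": 42.1,  "min": 35.7,  "max": 48.9},
    {"id": "brachial_plexus_d0_5cc","unit": "Gy",  "mean": 51.2,  "sd": 1.6,   "median": 51.6,  "min": 48.5,  "max": 53.6},
    {"id": "brain_d0_1cc",          "unit": "Gy",  "mean": 48.5,  "sd": 2.9,   "median": 49.7,  "min": 43.2,  "max": 52.4},
    {"id": "esophagus_d0_1cc",      "unit": "Gy",  "mean": 44.5,  "sd": 2.7,   "median": 44.4,  "min": 39.7,  "max": 49.1},
    {"id": "glottis_dmean",         "unit": "Gy",  "mean": 42.3,  "sd": 1.9,   "median": 42.9,  "min": 39.1,  "max": 44.9},
    {"id": "mandible_d0_1cc",       "unit": "Gy",  "mean": 59.7,  "sd": 2.4,   "median": 59.5,  "min": 56.9,  "max": 64.8},
    {"id": "oral_cavity_dmean",     "unit": "Gy",  "mean": 36.6,  "sd": 3.5,   "median": 36.0,  "min": 32.6,  "max": 44.9},
    {"id": "n_beams",               "unit": "count","mean": 21.1, "sd": 13.5,  "median": 17.5,  "min": 11,    "max": 60,   "integer": true},
    {"id": "n_segments",            "unit": "count","mean": 147.6,"sd": 24.2,  "median": 139.0, "min": 114,   "max": 208,  "integer": true},
    {"id": "mu",                    "unit": "MU",  "mean": 918.9, "sd": 232.7, "median": 909.5, "min": 539,   "max": 1474, "integer": true},
    {"id": "beam_on_min",           "unit": "min", "mean": 1.5,   "sd": 0.4,   "median": 1.5,   "min": 0.8,   "max": 2.5},
    {"id": "delivery_min",          "unit": "min", "mean": 18.7,  "sd": 1.7,   "median": 18.8,  "min": 14.9,  "max": 22.4},
    {"id": "experience_years",      "unit": "yr",  "mean": 9.2,   "sd": 6.9,   "median": 7.0,   "min": 2.0,   "max": 20.0},
    {"id": "viewray_years",         "unit": "yr",  "mean": 1.1,   "sd": 0.6,   "median": 1.0,   "min": 0.0,   "max": 2.0},
    {"id": "pqm_latent",            "unit": "z",   "latent": true},
    {"id": "ptv_latent",            "unit": "z",   "latent": true}
  ],
  "correlations": [
    {"field_a": "n_beams",          "field_b": "n_segments",          "rho": 0.67},
    {"field_a": "n_beams",          "field_b": "mu",                  "rho": -0.63},
    {"field_a": "n_segments",       "field_b": "pqm_latent",          "rho": 0.75},
    {"field_a": "n_segments",       "field_b": "ptv_latent",          "rho": 0.76},
    {"field_a": "pqm_latent",       "field_b": "ptv_latent",          "rho": 0.9},
    {"field_a": "experience_years", "field_b": "spinal_canal_d0_1cc", "rho": -0.55},
    {"field_a": "experience_years", "field_b": "glottis_dmean",       "rho": -0.55}
  ]
}
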