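{
  "version": "1.0",
  "survey_km": {"y2013": 183, "y2014": 652, "y2015": 405, "y2016": 82, "total": 1322},
  "scats_detected_total": 1118,
  "scats_rsf": {"bear": 373, "cougar": 42, "coyote": 223, "wolf": 470, "total": 1108},
  "contents_analyzed": {"total": 476, "macroscopic": 226, "dna": 250,
    "by_species": {"bear": 130, "cougar": 33, "coyote": 114, "wolf": 199}},
  "elk_containing": {"total": 157, "bear": 24, "wolf": 75, "coyote": 42, "cougar": 16},
  "available_set": {"total": 870, "bear": 257, "wolf": 363, "coyote": 223, "cougar": 27},
  "elk_rate": {"bear": 0.19, "cougar": 0.46, "coyote": 0.36, "wolf": 0.38},
  "kills": {"total": 104, "bear": 42, "cougar": 16, "wolf": 37, "unknown": 9},
  "constants": {
    "detect_p": 0.9,
    "park_density_ratio": 2.4,
    "smoothing_window_m": 12900,
    "pred_buffer_radius_m": 1300,
    "pelk_radius_m": {"wolf": 3000, "bear": 1500, "cougar": 2000, "coyote": 2000},
    "kill_buffer_radius_m": 250,
    "control_radius_m": 13200,
    "n_controls": 20,
    "n_available": 10,
    "exclusion_elev_m": 2000,
    "n_bins": 10,
    "n_validation_points": 1000,
    "corridor_length_m": 1300,
    "corridor_width_m": 50
  },
  "rsf_coefficients": {
    "bear": {"conifer": -0.71, "cutblk": 0.84, "ndvi": 0.0002, "slope": 0.02,
             "trailuse": 0.86, "distroad": 0.00005, "trailuse:distroad": 0.00005},
    "cougar": {"conifer": -1.92, "edgedens": 8.39},
    "coyote": {"shrub": 2.63, "slope": -0.05, "trailuse": 1.62, "distroad": 0.00006},
    "wolf": {"distwater": -0.0001, "cutblk": -2.47, "slope": -0.04,
             "trailuse": 1.29, "distroad": 0.00005}
  },
  "pelk_coefficients": {
    "bear": {"herbfg": 0.06, "open": -4.83},
    "cougar": {"edgedens": 1.25},
    "coyote": {"herbfg": 0.05, "distwater": 0.00032, "roaddens": -0.88},
    "wolf": {"herbfg": 0.21, "rugg": 0.85, "decid": -36.29}
  },
  "kill_coefficients": {
    "decid": 1.20, "distedge": 2.09, "distwater": -7.24,
    "herbfg": 3.78, "open": 2.61, "rugg": -6.67
  },
  "ruf_coefficients_synthetic": {
    "herbfg": 0.35, "herb": 1.0, "burn": 0.6, "distedge": 0.0004
  },
  "wolf_pdf_synthetic": {
    "territory_frac_x": [0.25, 0.55, 0.8],
    "territory_frac_y": [0.6, 0.35, 0.7],
    "pack_sizes": [8, 6, 3],
    "bandwidth_m": 2500
  }
}
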