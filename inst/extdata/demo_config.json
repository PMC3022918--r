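{
  "seed": 42,
  "sim": {
    "n_genes": 8,
    "junctions_per_gene": [6, 10],
    "n_tissues": 5,
    "frac_alternative": 0.3,
    "delta_magnitude": 2.5,
    "alt_tissue_range": [1, 2],
    "probe_effect_sd": 1,
    "tissue_baseline_range": 4,
    "noise_sd": 0.4,
    "seq_depth_scale": 100,
    "array_background_mean": 100,
    "array_background_sd": 15,
    "array_saturation": 3500,
    "array_gain": null,
    "dilution_factors": [0.01, 0.1, 1],
    "n_unused_features": 20,
    "qpcr_ct_intercept": 30,
    "qpcr_dropout_prob": 0.1,
    "nb_dispersion": null,
    "seed": 42
  },
  "z": 1.96,
  "upper": 3500,
  "min_reads": 4,
  "pseudocount": 0,
  "tol": 0.01,
  "max_iter": 10,
  "scale": "mad",
  "cutoff": "fixed:1.3",
  "platforms": ["seq", "array", "qpcr"],
  "score_methods": ["R", "M"]
}
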