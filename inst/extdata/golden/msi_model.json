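{
  "type": "msi_logistic",
  "features": ["indel_fraction", "indels_per_mb", "snvs_per_mb"],
  "coefficients": {
    "(Intercept)": -92.1653574165035,
    "indel_fraction": 621.31186711179,
    "indels_per_mb": -14.7238026440615,
    "snvs_per_mb": 4.1901486915881
  },
  "cutoff": 0.5,
  "n_train": 600
}
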