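{
  "slope": -1.99999997241305,
  "intercept": 1.99988145810938,
  "residual_sd": 4.28850786314996e-05,
  "n_points": 9,
  "t_range": [
    0.1,
    0.9
  ],
  "provenance": {
    "source_normal": "sim_seed1",
    "source_tumor": "sim_seed2",
    "note": "synthetic: fitted on a noiseless simulated admixture series (diploid normal vs pure tumor with homozygous CDKN2A/B deletion, hg38, 500-kb bins, fractions 0.1-0.9); regenerate with simulate_admixture_series() + fit_baseline()"
  }
}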