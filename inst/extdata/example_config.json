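{
  "seed": 1,
  "n_subjects": 2,
  "speeds": [1.0, 2.5, 4.0],
  "n_strides": 16,
  "lambda_cutoff": 80,
  "delta_cutoff": 1.5,
  "coh_lambda_cutoff": 55,
  "coh_delta_cutoff": 4,
  "n_surrogates": 100,
  "coh_alpha": 0.05,
  "stages": ["modes", "synergy", "coherence", "stats"]
}
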