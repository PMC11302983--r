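{
  "description": "Schema for correlations.json written by run_variability(): each named correlation object must carry scalar numeric fields.",
  "required_objects": ["H_sigma2", "eta_sigma2", "rate_sigma2"],
  "required_fields": ["coefficient", "slope", "n", "n_dropped"]
}
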