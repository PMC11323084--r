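{
  "protein": "TP53 DNA-binding domain",
  "threshold": 3.46,
  "threshold_percentile": 0.05,
  "notes": "Frozen default decision profile: structural-deviation scores strictly greater than 3.46 are deleterious, scores at or below are non-deleterious. Derived from the lower 5% quantile of a log-normal fit to pathogenic training scores for the p53 DNA-binding domain."
}
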