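# Example srmforge pipeline configuration.
# Every key can also be overridden with the matching CLI flag.
selection:
  min_clean_transitions: 3     # co-eluting, interference-free transitions required
  cv_threshold_pct: 20         # replicate %CV threshold
  cv_comparison: lte           # "lte" (<=) or "lt" (<)
  top_k_peptides_by_intensity: 5
  n_peptides_per_protein: 2
  n_transitions_per_peptide: 5
  require_min_peptides_per_protein: 1
  apex_tolerance_min: 0.1      # minutes
  tic_normalize: true
schedule:
  window_min: 5                # scheduled RT window, minutes
  max_concurrent_transitions: 200
  dwell_ms: 10                 # export metadata
  ce_coefficients:             # CE = slope * precursor m/z + intercept, per charge
    "2": {slope: 0.034, intercept: 3.314}
    "3": {slope: 0.044, intercept: 3.314}
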