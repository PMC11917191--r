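# Demo configuration for runPipeline(): a small simulated study.
seed: 11
simulate:
  n_dyads: 8
contingency:
  window_ms: 1000
  warmup_ms: 60000
  coded_ms: 240000
preproc:
  dpf: 5.1
  min_trials: 3
stats:
  n_bins: 6
  bin_s: 3
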