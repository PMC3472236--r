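# Example workbench config: current-clamp light response of the canonical
# cell driven by a naturalistic-like conductance waveform.
mode: current_clamp
cell: canonical
seed: 1
stimulus:
  type: naturalistic
  duration_s: 5
  mean_nS: 5
  contrast: 0.5
  tau_corr_ms: 100
  dt_ms: 1
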