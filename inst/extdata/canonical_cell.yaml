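cell:
  name: canonical
  capacitance_pF: 380.0
  g_leak_nS: 0.86262203910692736
  e_leak_mV: 0.0
  e_light_mV: 10.0
  v_rest_mV: -60.0
  temperature_K: 293.14999999999997726
  conductances:
  - name: KDR
    g_max_nS: 78.0
    e_rev_mV: -68.0
    activation:
      v_half_mV: -31.0
      slope_mV: 12.0
      order: 1
      tau_alpha_per_s: 4.0
      tau_beta_per_s: 156.0
      tau_slope_per_V: 43.0
      tau_offset_ms: 0.0
  - name: KA
    g_max_nS: 60.00000000000000711
    e_rev_mV: -68.0
    activation:
      v_half_mV: -43.0
      slope_mV: 8.40000000000000036
      order: 2
      tau_constant_ms: 1.5
    inactivation:
      v_half_mV: -85.0
      slope_mV: -11.30000000000000071
      order: 1
      tau_alpha_per_s: 341.0
      tau_beta_per_s: 0.21099999999999999
      tau_slope_per_V: -44.0
      tau_offset_ms: 0.0
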