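# Shared fixtures: the registry gates pulled off the canonical cell, and a
# few tolerances used across files.

kv_cell_fixture <- canonical_cell()
kdr_gate <- kv_cell_fixture$conductances$KDR$activation
ka_act_gate <- kv_cell_fixture$conductances$KA$activation
ka_inact_gate <- kv_cell_fixture$conductances$KA$inactivation

# closed-form values computed independently of the package (frozen from a
# high-precision evaluation of the printed formulas)
REF <- list(
  a_kdr_m60 = 0.0819110,     # (1 + exp(29/12))^-1
  h_ka_m60 = 0.0986432,      # (1 + exp(25/11.3))^-1
  tau_kdr_m43_ms = 20.0131,  # 1/(4 e^{1.849} + 156 e^{-1.849})
  tau_kdr_m70_ms = 11.2563,
  tau_ka_inact_m70_ms = 49.3507,
  g_ka_m60_nS = 0.0806403,   # 60 * a^2 h
  g_leak_nS = 0.862622,      # current balance at -60 mV
  r_in_Mohm = 136.383,
  r_in_m84_Mohm = 557.16,
  e_k_mV = -84.1772,         # RT/F ln(5/140) at 293.15 K
  slope_decade_mV = 58.1672,
  bell_peak_mV = -42.5996,   # ln(4/156)/(2*43)
  validation_ss_nA = 3.4904        # 52 nS a_inf(3 mV) 71 mV + KA + leak
)

# short constant-conductance stimulus on a uniform grid
constant_stim <- function(g, duration = 1, dt = 1e-3) {
  tm <- seq(0, duration, by = dt)
  stimulus_waveform(tm, rep(g, length(tm)))
}
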