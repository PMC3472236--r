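---
title: "Modelling and characterizing Kv conductances in a nocturnal photoreceptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and characterizing Kv conductances in a nocturnal photoreceptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoKv)
```

## The model

photoKv implements an isopotential Hodgkin–Huxley-type model of a cockroach
photoreceptor soma and the patch-clamp analysis pipeline used to
parameterize it. The membrane carries a light-gated conductance
$g_{light}(t)$, two voltage-gated potassium conductances — a sustained
delayed rectifier (KDR) and a transient, inactivating A-type conductance
(KA) — and a passive leak:

$$
C\frac{dV}{dt} = -\Big[\, g_{light}(t)(V - E_{light})
 + G_{KDR}\,a_{KDR}\,(V-E_K)
 + G_{KA}\,a_{KA}^2\,h_{KA}\,(V-E_K)
 + g_{leak}(V - E_{leak}) \Big]
$$

Each gating variable relaxes with first-order kinetics,
$dx/dt = (x_\infty(V) - x)/\tau_x(V)$. The steady state of a gate is a
Boltzmann in the membrane voltage; because an order-$P$ conductance uses
$x^P$, the *fitted* steady-state conductance curve is the order-$P$
Boltzmann

$$
g(V) = g_{max}\big(1 + e^{(V_{50}-V)/s}\big)^{-P},
$$

while the relaxing variable itself targets the first-order level. This
distinction matters only for the second-order KA activation; the package
keeps it explicit (`boltzmann_steady_state()` is the fitted-curve form,
`equilibrium_gating()` the dynamical one). With $P = 2$ the fitted
$V_{50}$ is *not* the half-maximum voltage of the conductance, a point the
documentation of `fit_boltzmann()` repeats because it is a classic reading
error.

Time constants follow the bell law
$\tau(V) = 1/(\alpha e^{-s_\tau V} + \beta e^{s_\tau V}) + \tau_0$ with $V$
in volts. The canonical registry (`canonical_cell()`) carries:

| gate | $V_{50}$ (mV) | slope (mV) | $P$ | kinetics |
|---|---|---|---|---|
| KDR activation | −31 | 12 | 1 | $\alpha=4$, $\beta=156$, $s_\tau=43$ V$^{-1}$ |
| KA activation | −43 | 8.4 | 2 | constant 1.5 ms |
| KA inactivation | −85 | −11.3 | 1 | $\alpha=341$, $\beta=0.211$, $s_\tau=-44$ V$^{-1}$ |

with $G_{KDR}=78$ nS, $G_{KA}=60$ nS, $E_K=-68$ mV (the measured, not the
ideal Nernst, reversal; the channel is not perfectly selective under
multi-ionic conditions), $C=380$ pF, $E_{leak}=0$ mV, $E_{light}=+10$ mV,
rest at −60 mV, room temperature. A validation variant
(`validation_cell()`) swaps in the 52 nS KDR maximum of the representative
recorded cell. We set $\tau_0 = 0$: the mean estimates are 1 ± 2 and
0 ± 2 ms, statistically indistinguishable from zero, and the zero-offset
bell reproduces the reported 20→11 ms range of KDR activation over the
physiological −70…−10 mV window exactly. The field is retained for data
that need it.

The KA reversal potential is set equal to KDR's −68 mV: the transient
current overlaps the sustained one too much for an independent tail
measurement, and both behave as potassium currents.

Units are SI internally (volts, siemens, farads, seconds). The bell
exponents are written for volts, so feeding millivolts silently produces
nonsense; the `mV()`, `nS()`, `pF()`, `ms()` helpers and the unit-suffixed
config keys (`v_half_mV: -31`) exist to keep that conversion at the
boundary.

## Calibration and passive properties

The leak is not free: `calibrate_leak()` solves the algebraic current
balance at the resting potential, giving 0.863 nS (printed 0.9 nS) for the
canonical cell. The reciprocal of the total instantaneous conductance with
gates at equilibrium is then 136 MΩ at rest, with KDR carrying ~87% of the
resting conductance — the delayed rectifier is open at rest and shapes even
single-photon responses. The KA conductance at rest is only ~0.08 nS: the
activation and inactivation curves overlap near −50 mV, but inactivation
wins at −60 mV.

"Input resistance" here always means the *instantaneous* chord convention
(gating frozen). A steady-state (chord-between-operating-points)
convention gives very different numbers away from rest — e.g. ~920 MΩ for
a −74→−84 mV chord versus ~557 MΩ instantaneous at −84 mV — and published
values measured "at −84 mV" depend on which convention the acquisition
software used. The package computes the instantaneous one and leaves the
other to the user via `steady_state_current()`.

`membrane_time_constant(pF(400), Mohm(150))` gives the 60 ms passive time
constant and 2.65 Hz corner frequency of a typical dark-adapted cell — a
slow low-pass that trades bandwidth for single-photon gain.

## Simulation

`simulate_voltage_clamp()` treats the clamp as ideal: the command is
honoured instantly (epochs are half-open `[start, end)`), there is no
capacitive current, and only the gating ODEs are integrated (lsoda,
rtol 1e-8 — the per-epoch problem is linear and cheap, so the voltage-clamp
path is integrated tighter than its oracle tolerance). Capacitive
transients and series-resistance error belong to the *acquisition*, so
they live in the synthetic-data generators, not the simulator.

`simulate_current_clamp()` integrates the full four-state system with
lsoda at rtol 1e-6 / atol 1e-9; gating time constants of 1.5–50 ms against
10 s stimuli make a stiff-capable method the safe default. The initial
state is the gating equilibrium at `v0` (the resting potential unless
overridden). Every run's output satisfies the charge balance
$C\,dV/dt + \sum I = 0$ to finite-difference accuracy, and the voltage is
bounded by the reversal potentials — both are tested invariants.

Fixed-voltage gating has the closed-form solution
$x(t) = x_\infty - (x_\infty - x_0)e^{-t/\tau}$ (`gating_relaxation()`),
kept in the package purely as an independent oracle: the test suite demands
the integrated gating match it to 10⁻⁶ across multi-epoch protocols.

### The subtraction protocol and its artifact

The experimental isolation of KA — step families after an
inactivation-removing (−117 mV) versus an inactivating (−57 mV) prepulse,
subtracted — is reproduced by `simulate_subtraction_protocol()`. The
simulated true KA current during a +3 mV step peaks at ~1.0 nA about
2.2 ms after the step (validation cell), matching a semi-analytic
maximization of $G a(t)^2 h(t)(V-E_K)$.

The subtraction itself, however, is a biased estimator of that current:
KDR enters the two families with different activation histories
(≈0.10 versus ≈0.001 at the prepulse ends) and relaxes with τ ≈ 5.5 ms
during the step, and the −57 mV prepulse leaves ~8% of KA un-inactivated.
In the model the subtraction current therefore undershoots the true KA
peak by roughly a third. The object returned carries the model's true KA
family (`$ka_true`) precisely so this error is measurable; an
artifact-free isolation — the one an experimenter cannot do — subtracts a
companion simulation of the same cell with $G_{KA}=0$ under the *same*
prepulse, which recovers the true KA current to numerical accuracy and is
what the recovery test asserts to within 2% of peak.

### Conductance-scaling experiments

`conductance_scaling_experiment()` reruns a light response with one
maximal conductance scaled, holding the calibrated leak fixed (the scaling
emulates a knockdown on an otherwise identical membrane) and starting each
run from its own equilibrium adapted to the stimulus's initial light
conductance, so no artificial onset transient contaminates the comparison.
Scaling KDR 0.1–10× monotonically moves the depolarization level —
removing the rectifier lets the light current saturate the membrane,
over-expressing it clamps the response down. Scaling KA 0–10× changes the
simulated response by only ~1–2 mV: its peak current under naturalistic
stimulation is ~40 pA against KDR's ~1 nA (ratio < 0.05 in the tests).
Note the package's honest accounting here: the "no visible effect" of KA
corresponds to a 1–2 mV trace difference, invisible at the tens-of-mV
scale of a light response but resolvable numerically; the 0×-vs-10× pair
exceeds a strict 1 mV band at intermediate depolarizations, where the
steady-state activation/inactivation overlap peaks.

## The fitting pipeline

All fits go through damped least squares (`minpack.lm::nlsLM`) with
data-driven starts (half-rise voltage for $V_{50}$, a quarter of the
voltage span for the slope, time-to-63% for time constants) and positivity
bounds on $g_{max}$, τ, IC$_{50}$ and the Hill coefficient; linear
problems (tail reversal, Nernst slope) use `lm()`. Every fitter returns a
`kv_fit` with broom-style `tidy()`/`glance()` methods, a prediction
function for `autoplot()`, and *flags* rather than silent failure:
degenerate inputs (flat segments, sustained-only transients, saturated
dose designs, tail families that do not bracket zero) yield a flagged
result, never an invented parameter. On noiseless data generated from its
own model family every fitter achieves zero residual and exact recovery —
a tested invariant.

Choices the source data left open, and what we did:

* **Pulse function.** The transient-current shape is implemented as
  $I_{max}(1-e^{-t/\tau_{act}})^2 e^{-t/\tau_{inact}}$ — the standard
  $m^2h$ form consistent with second-order activation. (The printed
  formula's parenthesis placement is ambiguous; the exponent belongs to
  the activation bracket.)
* **Tail amplitudes.** Default is a single-exponential fit extrapolated to
  the repolarization instant; a fixed-latency read is available but biased
  low by deactivation during the latency, which is also a tested property.
  Fit windows are configurable.
* **Series-resistance correction** is applied offline and only to samples
  exceeding ±200 pA (below that the voltage error is sub-noise); the
  corrected voltage $V_{cmd} - I R_s$ rides along as a `v_effective`
  column.
* **Multi-cell data** are fit per cell and summarized as median / mean ±
  SD, with no hierarchical pooling — matching how such results are
  reported.
* **Nernst slopes** are in mV per *decade* of external concentration
  (58.2 mV/decade ideal at 293.15 K); shallower measured slopes (52)
  indicate imperfect K⁺ selectivity.

## Synthetic data: what it emulates, what it does not

Every generator is a pure function of (parameters, seed) and embeds its
ground truth in the output, so each analysis stage closes the loop against
known truth without recorded data:

* `make_voltage_clamp_dataset()` forward-simulates current families and
  injects the acquisition artifacts the simulator deliberately omits: a
  capacitive charging transient at each command transition (time constant
  $R_sC$, total charge $C\,\Delta V$ — a tested conservation property) and
  additive Gaussian current noise, default SD 5 pA (a plausible whole-cell
  rig figure; the source gives none).
* `make_activation_dataset()` produces per-cell conductance–voltage
  points with lognormal between-cell maxima (CV 0.25, matching the
  reported ~28% spread of KDR maxima) and point noise proportional to
  each cell's maximum (5%; 3% for normalized inactivation data).
* `make_tail_family()` anchors the reversal-potential relation at
  −68 mV @ 5 mM with the *measured* 52 mV/decade slope by default; the
  ideal Nernst relation is one argument away.
* `make_naturalistic_conductance()` stands in for a light conductance
  derived from natural intensity recordings: exponentiated AR(1) noise —
  log-normal amplitudes, low-pass correlation (100 ms default), rescaled
  to the requested mean the way stimulus intensities are normalized at the
  rig. It makes **no** claim of statistical identity with any recorded
  natural series (no 1/f tail, no scene structure); it exercises the
  simulator with fluctuating, positively skewed, slowly varying input,
  which is what the scaling and current-partition experiments need. The
  default mean of 5 nS was chosen once so that simulated responses
  depolarize to the −50…−35 mV range with KDR currents approaching 1 nA,
  the regime the recorded light responses occupy.
* `make_quantum_bump_train()` is explicitly phenomenological: Poisson
  event times, gamma-shaped inward bumps (shape 3, 10 ms scale), lognormal
  amplitude scatter around −20 pA and jittered ~25 ms latencies. Bump
  shape parameters are order-of-magnitude choices for a slow nocturnal
  photoreceptor, not fitted values.

Passing recovery tests on these generators shows the *estimators* are
correct and unbiased at bench-like noise; it does not validate the noise
model against a real rig, and real recordings add drift, seal
deterioration and imperfect space clamp that none of the generators
emulate.

## Numerical choices and problem sizes

* Voltage-clamp gating: lsoda, rtol 1e-8 / atol 1e-12 per epoch
  (linear ODEs; tightened so the closed-form comparison at 1e-6 measures
  model fidelity, not solver slack).
* Current clamp: lsoda, rtol 1e-6 / atol 1e-9 on all states.
* Root-finding (resting and light-adapted equilibria): `uniroot` on the
  current balance, bracketed by the reversal potentials, tol 1e-12.
* Monte-Carlo recovery: 100 seeded datasets per experiment (600/500/400
  Boltzmann fits, 100 dose-response fits), seconds of runtime; per-dataset
  seeds are derived affinely from the base seed and stay below 2³¹.
* Simulation tests use 2–5 s stimuli at 1 kHz — long against the 60 ms
  membrane time constant, short enough to keep the suite quick.
* Ties and degeneracies: epoch boundaries belong to the following epoch;
  duplicate concentrations are allowed in Nernst fits; a conductance with
  `g_max = 0` is legal everywhere (it is how knockdowns are expressed).

## Known limitations

* The hyperpolarization-activated inward-rectifying chloride current is
  not part of the model: it activates well below the physiological range
  of light responses. Simulations below ~−80 mV are outside the model's
  validity.
* One compartment only: no axon, no spike-like phenomena, no synaptic
  load.
* Phototransduction is not mechanistic — light enters as a conductance
  waveform, so adaptation and bump statistics are inputs, not predictions.
* No temperature scaling of kinetics (parameters are room-temperature
  values; no Q10 is provided).
* The two-prepulse subtraction inherits the KDR-history artifact described
  above; treat subtraction-derived KA amplitudes as lower bounds near the
  peak.

## A worked mini-example

```{r example, eval = FALSE}
cell <- canonical_cell()
cell$g_leak * 1e9                     # 0.8626 nS, prints as 0.9
input_resistance(cell) / 1e6          # 136.4 Mohm
conductance_share(cell, "KDR")        # 0.87

stim <- make_naturalistic_conductance(duration = 5, seed = 42)
sim <- simulate_current_clamp(cell, stim)
autoplot(sim)

fit <- fit_boltzmann(
  make_activation_dataset(cell$conductances$KDR$activation, nS(78),
                          mV(seq(-47, 23, 10)), n_cells = 1, seed = 1))
tidy(fit)
```
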