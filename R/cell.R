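#' Whole-cell model parameters
#'
#' The isopotential photoreceptor soma: membrane capacitance, passive leak,
#' light-current reversal potential, the list of voltage-gated conductances,
#' the resting potential and the bath temperature. All voltages are liquid
#' junction potential corrected values, matching how patch-clamp voltages
#' are reported.
#'
#' @param capacitance Whole-cell capacitance (F), positive.
#' @param conductances List of [conductance_spec()] objects.
#' @param g_leak Leak conductance (S), non-negative; `NA` until calibrated
#'   (see [calibrate_leak()]).
#' @param e_leak Leak reversal potential (V).
#' @param e_light Reversal potential of the light-induced current (V).
#' @param v_rest Dark resting potential (V).
#' @param temperature Bath temperature (K), positive.
#' @param name Label for printing and provenance.
#' @return An object of class `kv_cell`.
#' @export
cell_parameters <- function(capacitance, conductances = list(),
                            g_leak = NA_real_, e_leak = 0,
                            e_light = mV(10), v_rest = mV(-60),
                            temperature = 293.15, name = "cell") {
  .check_number(capacitance, "capacitance")
  if (capacitance <= 0) abort("`capacitance` must be positive.")
  if (!is.na(g_leak) && g_leak < 0) abort("`g_leak` must be non-negative.")
  .check_number(temperature, "temperature")
  if (temperature <= 0) abort("`temperature` must be positive.")
  if (!all(vapply(conductances, .is_conductance, logical(1)))) {
    abort("`conductances` must be a list of conductance_spec() objects.")
  }
  names(conductances) <- vapply(conductances, `[[`, character(1), "name")
  structure(
    list(name = name, capacitance = capacitance, g_leak = g_leak,
         e_leak = e_leak, e_light = e_light, conductances = conductances,
         v_rest = v_rest, temperature = temperature),
    class = "kv_cell"
  )
}

#' @export
print.kv_cell <- function(x, ...) {
  cat(sprintf("<kv_cell> %s: C = %g pF, v_rest = %g mV, E_light = %g mV\n",
              x$name, x$capacitance * 1e12, x$v_rest * 1e3, x$e_light * 1e3))
  cat(sprintf("  leak: g = %s, E_leak = %g mV\n",
              if (is.na(x$g_leak)) "uncalibrated"
              else sprintf("%.4g nS", x$g_leak * 1e9),
              x$e_leak * 1e3))
  for (cs in x$conductances) {
    cat(sprintf("  %s: g_max = %g nS, E_rev = %g mV\n",
                cs$name, cs$g_max * 1e9, cs$e_rev * 1e3))
  }
  invisible(x)
}

.is_cell <- function(x) inherits(x, "kv_cell")

.kv_table1 <- function() {
  e_k <- mV(-68)
  kdr_act <- gating_parameters(
    v_half = mV(-31), slope = mV(12), order = 1,
    tau_alpha = 4, tau_beta = 156, tau_slope = 43, tau_offset = 0,
    label = "KDR activation"
  )
  ka_act <- gating_parameters(
    v_half = mV(-43), slope = mV(8.4), order = 2,
    tau_constant = ms(1.5), label = "KA activation"
  )
  ka_inact <- gating_parameters(
    v_half = mV(-85), slope = mV(-11.3), order = 1,
    tau_alpha = 341, tau_beta = 0.211, tau_slope = -44, tau_offset = 0,
    label = "KA inactivation"
  )
  list(e_k = e_k, kdr_act = kdr_act, ka_act = ka_act, ka_inact = ka_inact)
}

#' Canonical model-cell parameter registry
#'
#' The reference photoreceptor model cell: mean delayed-rectifier (KDR)
#' conductance of 78 nS with first-order activation (V50 = -31 mV,
#' slope = 12 mV), transient A-type (KA) conductance of 60 nS with
#' second-order activation (V50 = -43 mV, slope = 8.4 mV, constant 1.5 ms
#' activation time constant) and first-order inactivation (V50 = -85 mV,
#' slope = -11.3 mV), both reversing at E_K = -68 mV; whole-cell
#' capacitance 380 pF, leak reversal 0 mV, light reversal +10 mV, resting
#' potential -60 mV, room temperature (293.15 K). The leak conductance is
#' calibrated to zero the net membrane current at rest (about 0.86 nS,
#' printing as 0.9 nS).
#'
#' @param calibrated If `TRUE` (default) the returned cell has `g_leak`
#'   solved by [calibrate_leak()]; if `FALSE`, `g_leak` is `NA`.
#' @return A `kv_cell` object.
#' @seealso [validation_cell()] for the voltage-clamp validation variant.
#' @export
canonical_cell <- function(calibrated = TRUE) {
  tt <- .kv_table1()
  cell <- cell_parameters(
    capacitance = pF(380),
    conductances = list(
      conductance_spec("KDR", g_max = nS(78), e_rev = tt$e_k,
                       activation = tt$kdr_act),
      conductance_spec("KA", g_max = nS(60), e_rev = tt$e_k,
                       activation = tt$ka_act, inactivation = tt$ka_inact)
    ),
    name = "canonical"
  )
  if (calibrated) cell <- calibrate_cell(cell)
  cell
}

#' Voltage-clamp validation cell
#'
#' The variant used to validate the model against the recorded two-prepulse
#' subtraction protocol: identical gating parameters to [canonical_cell()]
#' but with the representative cell's maximal conductances, 52 nS for KDR
#' and 60 nS for KA.
#'
#' @inheritParams canonical_cell
#' @return A `kv_cell` object.
#' @export
validation_cell <- function(calibrated = TRUE) {
  cell <- canonical_cell(calibrated = FALSE)
  cell$name <- "validation"
  cell$conductances$KDR$g_max <- nS(52)
  if (calibrated) cell <- calibrate_cell(cell)
  cell
}

#' Calibrate the leak conductance to zero net current at rest
#'
#' Solves the algebraic current balance
#' \deqn{\sum_i g_{max,i}\, a_{\infty,i}^{P_i} h_{\infty,i}\,(V_{rest} -
#' E_{rev,i}) + g_{leak}(V_{rest} - E_{leak}) = 0}
#' for \eqn{g_{leak}}, with every gate at its equilibrium level for
#' `v_rest`. A balance that would require a negative leak is rejected.
#'
#' @param cell A [cell_parameters()] object.
#' @param v_rest Resting potential (V); defaults to the cell's own.
#' @return Leak conductance in siemens.
#' @export
calibrate_leak <- function(cell, v_rest = cell$v_rest) {
  stopifnot(.is_cell(cell))
  .check_number(v_rest, "v_rest")
  if (v_rest == cell$e_leak) {
    abort("`v_rest` equals `e_leak`; the leak balance is degenerate.")
  }
  i_kv <- sum(vapply(cell$conductances, function(cs) {
    g <- conductance_value(equilibrium_gating(cs, v_rest), cs)
    g * (v_rest - cs$e_rev)
  }, numeric(1)))
  g_leak <- -i_kv / (v_rest - cell$e_leak)
  if (g_leak < 0) {
    abort(sprintf(
      "Leak balance infeasible: would need g_leak = %.3g nS < 0.",
      g_leak * 1e9))
  }
  g_leak
}

#' @rdname calibrate_leak
#' @return `calibrate_cell()` returns the cell with `g_leak` (and `v_rest`)
#'   set.
#' @export
calibrate_cell <- function(cell, v_rest = cell$v_rest) {
  cell$g_leak <- calibrate_leak(cell, v_rest)
  cell$v_rest <- v_rest
  cell
}

#' Instantaneous whole-cell input resistance
#'
#' Reciprocal of the total instantaneous conductance
#' \eqn{g_{leak} + \sum_i g_{max,i} a^{P_i} h_i} with every gate frozen at
#' its equilibrium level for `v`. No gating-derivative (slope-conductance)
#' terms enter: this is the chord conductance an instantaneous voltage
#' perturbation sees.
#'
#' @param cell A calibrated [cell_parameters()] object.
#' @param v Membrane voltage (V); defaults to the resting potential.
#' @return Resistance in ohms.
#' @export
input_resistance <- function(cell, v = cell$v_rest) {
  stopifnot(.is_cell(cell))
  if (is.na(cell$g_leak)) abort("Cell is not calibrated; run calibrate_cell().")
  .check_number(v, "v")
  g_tot <- cell$g_leak + sum(vapply(cell$conductances, function(cs) {
    conductance_value(equilibrium_gating(cs, v), cs)
  }, numeric(1)))
  if (g_tot <= 0) abort("Total conductance is zero; resistance undefined.")
  1 / g_tot
}

#' Share of the total resting conductance carried by one conductance
#'
#' @inheritParams input_resistance
#' @param name Conductance name, e.g. `"KDR"`.
#' @return Dimensionless fraction in \[0, 1\].
#' @export
conductance_share <- function(cell, name, v = cell$v_rest) {
  stopifnot(.is_cell(cell))
  if (!name %in% names(cell$conductances)) {
    abort(sprintf("No conductance named '%s' in this cell.", name))
  }
  cs <- cell$conductances[[name]]
  g <- conductance_value(equilibrium_gating(cs, v), cs)
  g * input_resistance(cell, v)
}

#' Membrane time constant and low-pass cut-off frequency
#'
#' \eqn{\tau_m = R C} and the corresponding first-order low-pass corner
#' frequency \eqn{f_c = 1/(2\pi \tau_m)}.
#'
#' @param capacitance Membrane capacitance (F), positive.
#' @param resistance Membrane resistance (ohm), positive.
#' @return A tibble with columns `tau` (s) and `cutoff` (Hz).
#' @examples
#' membrane_time_constant(pF(400), Mohm(150))  # tau = 60 ms, ~2.65 Hz
#' @export
membrane_time_constant <- function(capacitance, resistance) {
  .check_number(capacitance, "capacitance")
  .check_number(resistance, "resistance")
  if (any(capacitance <= 0) || any(resistance <= 0)) {
    abort("`capacitance` and `resistance` must be positive.")
  }
  tau <- resistance * capacitance
  tibble(tau = tau, cutoff = 1 / (2 * pi * tau))
}

#' Nernst equilibrium potential
#'
#' \deqn{E = \frac{R T}{z F} \ln\frac{[C]_{out}}{[C]_{in}}}
#'
#' Concentrations may be in any common unit (mM throughout this package);
#' only their ratio enters.
#'
#' @param c_in,c_out Intracellular and extracellular concentrations,
#'   positive, same unit.
#' @param z Ion valence (non-zero integer); +1 for potassium.
#' @param temperature Absolute temperature (K).
#' @return Equilibrium potential in volts.
#' @examples
#' nernst_potential(140, 5, z = 1, temperature = 293.15) * 1e3  # ~ -84 mV
#' @export
nernst_potential <- function(c_in, c_out, z = 1, temperature = 293.15) {
  .check_number(c_in, "c_in")
  .check_number(c_out, "c_out")
  if (any(c_in <= 0) || any(c_out <= 0)) {
    abort("Concentrations must be positive.")
  }
  if (any(z == 0)) abort("`z` must be non-zero.")
  .R_GAS * temperature / (z * .FARADAY) * log(c_out / c_in)
}

#' Ideal Nernst slope per tenfold concentration change
#'
#' \eqn{\ln(10)\, R T / (z F)}: about 58.2 mV per decade of external
#' concentration for a monovalent ion at 293.15 K. Slopes of measured
#' reversal potentials against log10 external concentration are compared to
#' this value; a shallower measured slope indicates a channel that is not
#' perfectly selective under multi-ionic conditions.
#'
#' @inheritParams nernst_potential
#' @return Slope in volts per decade.
#' @export
nernst_slope_per_decade <- function(z = 1, temperature = 293.15) {
  log(10) * .R_GAS * temperature / (z * .FARADAY)
}
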