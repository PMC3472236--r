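#' Gating parameters for one voltage-dependent gate
#'
#' Bundles the Boltzmann steady-state law and the bell-shaped time-constant
#' law of a single activation or inactivation gate of a voltage-gated
#' conductance.
#'
#' The steady state is the order-`P` Boltzmann
#' \deqn{x_\infty(V) = \left(1 + e^{(V_{50} - V)/s}\right)^{-P}}
#' where a positive slope `s` gives a gate that opens with depolarization
#' (activation) and a negative slope one that closes (inactivation).
#'
#' The voltage dependence of the time constant is the bell function
#' \deqn{\tau(V) = \frac{1}{\alpha e^{-s_\tau V} + \beta e^{s_\tau V}} + \tau_0}
#' with `V` in volts. A gate whose kinetics are effectively
#' voltage-independent (the fast activation of the transient A-type current)
#' sets `tau_constant` instead, which overrides the bell law.
#'
#' @param v_half Half-point voltage \eqn{V_{50}} (V).
#' @param slope Slope factor (V); must be non-zero, sign carries the
#'   activation/inactivation polarity.
#' @param order Gating order `P` (positive integer); the conductance uses
#'   \eqn{x^P}.
#' @param tau_alpha,tau_beta Bell rate coefficients \eqn{\alpha, \beta}
#'   (s^-1), both non-negative, not both zero.
#' @param tau_slope Bell exponent coefficient \eqn{s_\tau} (V^-1).
#' @param tau_offset Additive time-constant floor \eqn{\tau_0} (s).
#' @param tau_constant Optional constant time constant (s) overriding the
#'   bell law.
#' @param label Optional gate name used in printing.
#' @return An object of class `kv_gating`.
#' @examples
#' kdr_act <- gating_parameters(v_half = mV(-31), slope = mV(12), order = 1,
#'                              tau_alpha = 4, tau_beta = 156, tau_slope = 43)
#' boltzmann_steady_state(kdr_act, mV(-31))  # 0.5
#' bell_time_constant(kdr_act, mV(-43))      # ~20 ms
#' @export
gating_parameters <- function(v_half, slope, order = 1,
                              tau_alpha = NULL, tau_beta = NULL,
                              tau_slope = NULL, tau_offset = 0,
                              tau_constant = NULL, label = NULL) {
  .check_number(v_half, "v_half")
  .check_number(slope, "slope")
  if (slope == 0) abort("`slope` must be non-zero.")
  if (length(order) != 1 || order < 1 || order != round(order)) {
    abort("`order` must be a positive integer.")
  }
  if (is.null(tau_constant)) {
    if (is.null(tau_alpha) || is.null(tau_beta) || is.null(tau_slope)) {
      abort(paste0("Supply either `tau_constant` or all of `tau_alpha`, ",
                   "`tau_beta`, `tau_slope`."))
    }
    .check_number(tau_alpha, "tau_alpha")
    .check_number(tau_beta, "tau_beta")
    .check_number(tau_slope, "tau_slope")
    if (tau_alpha < 0 || tau_beta < 0) {
      abort("`tau_alpha` and `tau_beta` must be non-negative.")
    }
    if (tau_alpha == 0 && tau_beta == 0) {
      abort("`tau_alpha` and `tau_beta` cannot both be zero.")
    }
  } else {
    .check_number(tau_constant, "tau_constant")
    if (tau_constant <= 0) abort("`tau_constant` must be positive.")
  }
  .check_number(tau_offset, "tau_offset")
  if (tau_offset < 0) abort("`tau_offset` must be non-negative.")

  structure(
    list(v_half = v_half, slope = slope, order = as.integer(order),
         tau_alpha = tau_alpha, tau_beta = tau_beta, tau_slope = tau_slope,
         tau_offset = tau_offset, tau_constant = tau_constant,
         label = label),
    class = "kv_gating"
  )
}

#' @export
print.kv_gating <- function(x, ...) {
  cat(sprintf("<kv_gating>%s V50 = %g mV, slope = %g mV, order = %d\n",
              if (is.null(x$label)) "" else paste0(" ", x$label, ":"),
              x$v_half * 1e3, x$slope * 1e3, x$order))
  if (is.null(x$tau_constant)) {
    cat(sprintf("  tau: 1/(%g exp(-%g V) + %g exp(%g V)) + %g ms\n",
                x$tau_alpha, x$tau_slope, x$tau_beta, x$tau_slope,
                x$tau_offset * 1e3))
  } else {
    cat(sprintf("  tau: constant %g ms\n", x$tau_constant * 1e3))
  }
  invisible(x)
}

.is_gating <- function(x) inherits(x, "kv_gating")

#' Boltzmann steady-state level of a gate
#'
#' Evaluates \eqn{(1 + e^{(V_{50}-V)/s})^{-P}}, the equilibrium open
#' probability of an order-`P` gate at membrane voltage `v`.
#'
#' @param gp A [gating_parameters()] object.
#' @param v Membrane voltage(s), volts. Must be finite.
#' @return Numeric vector in (0, 1), same length as `v`.
#' @export
boltzmann_steady_state <- function(gp, v) {
  stopifnot(.is_gating(gp))
  .check_number(v, "v")
  (1 + exp((gp$v_half - v) / gp$slope))^(-gp$order)
}

# Steady state of the dynamical gating variable itself (always first order).
# The order P enters the conductance as x^P, so the fitted steady-state
# conductance curve is the order-P Boltzmann returned by
# boltzmann_steady_state(), while the relaxing variable x targets the
# first-order level. For P = 1 the two coincide.
.gate_steady <- function(gp, v) {
  (1 + exp((gp$v_half - v) / gp$slope))^(-1)
}

#' Bell-function time constant of a gate
#'
#' Evaluates \eqn{\tau(V) = 1/(\alpha e^{-s_\tau V} + \beta e^{s_\tau V}) +
#' \tau_0}. When the gate carries a constant time constant (`tau_constant`),
#' that value is returned for every voltage.
#'
#' @inheritParams boltzmann_steady_state
#' @return Time constant(s) in seconds, strictly positive.
#' @export
bell_time_constant <- function(gp, v) {
  stopifnot(.is_gating(gp))
  .check_number(v, "v")
  if (!is.null(gp$tau_constant)) {
    return(rep_len(gp$tau_constant, length(v)))
  }
  1 / (gp$tau_alpha * exp(-gp$tau_slope * v) +
         gp$tau_beta * exp(gp$tau_slope * v)) + gp$tau_offset
}

#' Voltage of the bell-function time-constant peak
#'
#' The maximizer of the bell law solves
#' \eqn{\alpha e^{-s_\tau V} = \beta e^{s_\tau V}}, i.e.
#' \eqn{V^* = \ln(\alpha/\beta) / (2 s_\tau)}.
#'
#' @inheritParams boltzmann_steady_state
#' @return Voltage (V) at which the time constant peaks.
#' @export
bell_peak_voltage <- function(gp) {
  stopifnot(.is_gating(gp))
  if (!is.null(gp$tau_constant)) {
    abort("Gate has a constant time constant; no bell peak.")
  }
  if (gp$tau_alpha == 0 || gp$tau_beta == 0) {
    abort("Bell peak undefined when `tau_alpha` or `tau_beta` is zero.")
  }
  log(gp$tau_alpha / gp$tau_beta) / (2 * gp$tau_slope)
}

#' Closed-form gating relaxation at fixed voltage
#'
#' At constant voltage the first-order gating equation
#' \eqn{dx/dt = (x_\infty - x)/\tau} has the exact solution
#' \eqn{x(t) = x_\infty(V) - (x_\infty(V) - x_0)\, e^{-t/\tau(V)}},
#' where \eqn{x_\infty} is the first-order steady state of the gating
#' variable (the order `P` enters the conductance as \eqn{x^P}, not the
#' relaxation). This is the independent oracle against which the numerical
#' integration of piecewise-constant voltage protocols is checked.
#'
#' @inheritParams boltzmann_steady_state
#' @param v Fixed membrane voltage (V), scalar.
#' @param x0 Initial gating level in \[0, 1\].
#' @param t Time(s) since the voltage step (s).
#' @return Gating level(s) at `t`.
#' @export
gating_relaxation <- function(gp, v, x0, t) {
  stopifnot(.is_gating(gp))
  .check_number(v, "v")
  .check_number(t, "t")
  if (any(x0 < 0 | x0 > 1)) abort("`x0` must lie in [0, 1].")
  xinf <- .gate_steady(gp, v)
  tau <- bell_time_constant(gp, v)
  xinf - (xinf - x0) * exp(-t / tau)
}
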