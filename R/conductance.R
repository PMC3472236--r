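#' A named voltage-gated conductance
#'
#' A maximal conductance with its reversal potential, an activation gate and
#' an optional inactivation gate. The instantaneous conductance is
#' \eqn{g = g_{max}\, a^P\, h} (with \eqn{h = 1} when there is no
#' inactivation gate) and the current it carries is
#' \eqn{I = g\,(V - E_{rev})}.
#'
#' @param name Label, e.g. `"KDR"` or `"KA"`.
#' @param g_max Maximal conductance (S), non-negative.
#' @param e_rev Reversal potential (V).
#' @param activation A [gating_parameters()] object.
#' @param inactivation Optional [gating_parameters()] object.
#' @return An object of class `kv_conductance`.
#' @export
conductance_spec <- function(name, g_max, e_rev, activation,
                             inactivation = NULL) {
  .check_number(g_max, "g_max")
  if (g_max < 0) abort("`g_max` must be non-negative.")
  .check_number(e_rev, "e_rev")
  stopifnot(.is_gating(activation))
  if (!is.null(inactivation)) stopifnot(.is_gating(inactivation))
  structure(
    list(name = name, g_max = g_max, e_rev = e_rev,
         activation = activation, inactivation = inactivation),
    class = "kv_conductance"
  )
}

#' @export
print.kv_conductance <- function(x, ...) {
  cat(sprintf("<kv_conductance> %s: g_max = %g nS, E_rev = %g mV, %s\n",
              x$name, x$g_max * 1e9, x$e_rev * 1e3,
              if (is.null(x$inactivation)) "activation only"
              else "activation + inactivation"))
  invisible(x)
}

.is_conductance <- function(x) inherits(x, "kv_conductance")

#' Equilibrium gating state of a conductance
#'
#' Sets every gating variable of `spec` to its (first-order) steady-state
#' level at each voltage in `v`. The activation order `P` applies when the
#' state is converted to a conductance (\eqn{g_{max} a^P h}, see
#' [conductance_value()]), so the implied steady-state conductance follows
#' the order-`P` Boltzmann of [boltzmann_steady_state()].
#'
#' @param spec A [conductance_spec()] object.
#' @param v Membrane voltage(s), volts.
#' @return A tibble with columns `voltage`, `a` (activation level) and,
#'   if the conductance inactivates, `h` (inactivation level), plus a
#'   `conductance` column from `spec$name`.
#' @export
equilibrium_gating <- function(spec, v) {
  stopifnot(.is_conductance(spec))
  .check_number(v, "v")
  out <- tibble(
    conductance = spec$name,
    voltage = v,
    a = .gate_steady(spec$activation, v)
  )
  if (!is.null(spec$inactivation)) {
    out$h <- .gate_steady(spec$inactivation, v)
  }
  out
}

#' Instantaneous conductance from a gating state
#'
#' Evaluates \eqn{g_{max}\, a^P\, h}. The gating state can be the tibble
#' returned by [equilibrium_gating()] or any data frame carrying `a` (and
#' optionally `h`) columns; rows outside \[0, 1\] are rejected.
#'
#' @param state Data frame with column `a` and, for inactivating
#'   conductances, `h`.
#' @param spec A [conductance_spec()] object.
#' @return Conductance(s) in siemens, bounded by `[0, g_max]`.
#' @export
conductance_value <- function(state, spec) {
  stopifnot(.is_conductance(spec))
  if (!is.data.frame(state)) state <- as_tibble(as.list(state))
  if (!"a" %in% names(state)) abort("`state` must contain column `a`.")
  a <- state$a
  if (any(a < 0 | a > 1)) abort("Activation levels must lie in [0, 1].")
  h <- 1
  if (!is.null(spec$inactivation)) {
    if (!"h" %in% names(state)) {
      abort("`state` must contain column `h` for an inactivating conductance.")
    }
    h <- state$h
    if (any(h < 0 | h > 1)) abort("Inactivation levels must lie in [0, 1].")
  }
  spec$g_max * a^spec$activation$order * h
}
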