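# All internal quantities are SI: volts, siemens, amperes, farads, seconds,
# ohms, kelvin. These helpers convert the units used at the bench (mV, nS,
# pA, pF, ms, megaohm) to SI at the boundary. The bell time-constant law is
# written for voltages in volts, so feeding millivolts into the model is the
# classic failure mode these exist to prevent.

#' Bench-unit conversion helpers
#'
#' Convert quantities expressed in conventional electrophysiology units to
#' the SI values used throughout the package (volts, siemens, amperes,
#' farads, seconds, ohms).
#'
#' @param x Numeric vector in the unit named by the function.
#' @return Numeric vector in SI units.
#' @examples
#' mV(-60)   # -0.06 V
#' nS(78)    # 7.8e-08 S
#' @name units
NULL

#' @rdname units
#' @export
mV <- function(x) x * 1e-3

#' @rdname units
#' @export
nS <- function(x) x * 1e-9

#' @rdname units
#' @export
pA <- function(x) x * 1e-12

#' @rdname units
#' @export
pF <- function(x) x * 1e-12

#' @rdname units
#' @export
ms <- function(x) x * 1e-3

#' @rdname units
#' @export
Mohm <- function(x) x * 1e6

# gas and Faraday constants (CODATA)
.R_GAS <- 8.31446261815324
.FARADAY <- 96485.33212

.check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", name))
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name))
  }
  invisible(x)
}
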