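# Human-readable cell/parameter configs. Every physical quantity carries an
# explicit unit suffix in its key (mV, nS, pF, ms, per_s, per_V, K); values
# are converted to SI on read. Full double precision is preserved so a
# registry round-trips bit-identically.

.gating_to_config <- function(gp) {
  out <- list(
    v_half_mV = gp$v_half / 1e-3,
    slope_mV = gp$slope / 1e-3,
    order = gp$order
  )
  if (is.null(gp$tau_constant)) {
    out$tau_alpha_per_s <- gp$tau_alpha
    out$tau_beta_per_s <- gp$tau_beta
    out$tau_slope_per_V <- gp$tau_slope
    out$tau_offset_ms <- gp$tau_offset / 1e-3
  } else {
    out$tau_constant_ms <- gp$tau_constant / 1e-3
  }
  out
}

.gating_from_config <- function(x, label = NULL) {
  gating_parameters(
    v_half = mV(x$v_half_mV), slope = mV(x$slope_mV), order = x$order,
    tau_alpha = x$tau_alpha_per_s, tau_beta = x$tau_beta_per_s,
    tau_slope = x$tau_slope_per_V,
    tau_offset = if (is.null(x$tau_offset_ms)) 0 else ms(x$tau_offset_ms),
    tau_constant = if (is.null(x$tau_constant_ms)) NULL
                   else ms(x$tau_constant_ms),
    label = label
  )
}

#' Serialize a model cell to a unit-annotated config list
#'
#' @param cell A [cell_parameters()] object.
#' @return A plain list mirroring the YAML config layout.
#' @seealso [write_cell_config()], [read_cell_config()]
#' @export
cell_to_config <- function(cell) {
  stopifnot(.is_cell(cell))
  list(cell = list(
    name = cell$name,
    capacitance_pF = cell$capacitance / 1e-12,
    g_leak_nS = if (is.na(cell$g_leak)) NULL else cell$g_leak / 1e-9,
    e_leak_mV = cell$e_leak / 1e-3,
    e_light_mV = cell$e_light / 1e-3,
    v_rest_mV = cell$v_rest / 1e-3,
    temperature_K = cell$temperature,
    conductances = lapply(unname(cell$conductances), function(cs) {
      out <- list(
        name = cs$name,
        g_max_nS = cs$g_max / 1e-9,
        e_rev_mV = cs$e_rev / 1e-3,
        activation = .gating_to_config(cs$activation)
      )
      if (!is.null(cs$inactivation)) {
        out$inactivation <- .gating_to_config(cs$inactivation)
      }
      out
    })
  ))
}

#' @rdname cell_to_config
#' @param config A list as produced by [cell_to_config()].
#' @export
cell_from_config <- function(config) {
  x <- config$cell %||% config
  conds <- lapply(x$conductances, function(cc) {
    conductance_spec(
      name = cc$name, g_max = nS(cc$g_max_nS), e_rev = mV(cc$e_rev_mV),
      activation = .gating_from_config(cc$activation,
                                       paste(cc$name, "activation")),
      inactivation = if (is.null(cc$inactivation)) NULL
                     else .gating_from_config(cc$inactivation,
                                              paste(cc$name, "inactivation"))
    )
  })
  cell_parameters(
    capacitance = pF(x$capacitance_pF),
    conductances = conds,
    g_leak = if (is.null(x$g_leak_nS)) NA_real_ else nS(x$g_leak_nS),
    e_leak = mV(x$e_leak_mV),
    e_light = mV(x$e_light_mV),
    v_rest = mV(x$v_rest_mV),
    temperature = x$temperature_K,
    name = x$name %||% "cell"
  )
}

#' Read and write cell configs as YAML
#'
#' The on-disk format is a YAML document with unit-suffixed keys
#' (`capacitance_pF`, `g_max_nS`, `v_half_mV`, ...). Doubles are written at
#' full precision, so `read_cell_config(write_cell_config(cell, f))`
#' reproduces the cell bit-identically.
#'
#' @param cell A [cell_parameters()] object.
#' @param path File path.
#' @return `write_cell_config()` returns `path` invisibly;
#'   `read_cell_config()` returns a `kv_cell`.
#' @export
write_cell_config <- function(cell, path) {
  yaml::write_yaml(cell_to_config(cell), path, precision = 17)
  invisible(path)
}

#' @rdname write_cell_config
#' @export
read_cell_config <- function(path) {
  cell_from_config(yaml::read_yaml(path))
}
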