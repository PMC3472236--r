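#' Voltage-clamp protocol
#'
#' An ordered list of command epochs (level, duration). Epochs are half-open
#' `[start, end)`: command transitions are instantaneous, as under an ideal
#' clamp; capacitive transients are an acquisition artifact and live only in
#' the synthetic-data generators.
#'
#' @param epochs Data frame with columns `level` (V) and `duration` (s).
#' @param holding Holding potential (V) defining the initial gating
#'   equilibrium.
#' @param sample_interval Output sampling interval (s).
#' @return An object of class `kv_protocol`.
#' @export
voltage_protocol <- function(epochs, holding, sample_interval = 1e-4) {
  epochs <- as_tibble(epochs)
  if (!all(c("level", "duration") %in% names(epochs))) {
    abort("`epochs` needs columns `level` and `duration`.")
  }
  .check_number(epochs$level, "level")
  .check_number(epochs$duration, "duration")
  if (any(epochs$duration <= 0)) abort("Epoch durations must be positive.")
  .check_number(holding, "holding")
  if (sample_interval <= 0) abort("`sample_interval` must be positive.")
  structure(list(epochs = epochs, holding = holding,
                 sample_interval = sample_interval),
            class = "kv_protocol")
}

#' @export
print.kv_protocol <- function(x, ...) {
  cat(sprintf("<kv_protocol> holding %g mV, %d epochs, dt = %g ms\n",
              x$holding * 1e3, nrow(x$epochs), x$sample_interval * 1e3))
  for (i in seq_len(nrow(x$epochs))) {
    cat(sprintf("  %g mV for %g ms\n", x$epochs$level[i] * 1e3,
                x$epochs$duration[i] * 1e3))
  }
  invisible(x)
}

#' Stimulus waveform for current-clamp simulation
#'
#' A light-conductance time series on a uniform grid, with an optional
#' injected-current series.
#'
#' @param time Strictly increasing, uniformly spaced time base (s).
#' @param g_light Light-dependent conductance series (S), non-negative.
#' @param i_inject Optional injected current series (A).
#' @return A tibble of class `kv_stimulus`.
#' @export
stimulus_waveform <- function(time, g_light, i_inject = NULL) {
  .check_number(time, "time")
  .check_number(g_light, "g_light")
  if (length(time) < 2) abort("`time` needs at least two samples.")
  dt <- diff(time)
  if (any(dt <= 0)) abort("`time` must be strictly increasing.")
  if (diff(range(dt)) > 1e-9 * mean(dt)) abort("`time` must be uniform.")
  if (length(g_light) != length(time)) {
    abort("`g_light` must match `time` in length.")
  }
  if (any(g_light < 0)) abort("`g_light` must be non-negative.")
  out <- tibble(time = time, g_light = g_light)
  if (!is.null(i_inject)) {
    if (length(i_inject) != length(time)) {
      abort("`i_inject` must match `time` in length.")
    }
    out$i_inject <- i_inject
  }
  class(out) <- c("kv_stimulus", class(out))
  out
}

.gate_table <- function(cell) {
  rows <- list()
  for (cs in cell$conductances) {
    nm <- tolower(cs$name)
    rows[[length(rows) + 1L]] <-
      list(col = paste0("act_", nm), gp = cs$activation, cond = cs$name)
    if (!is.null(cs$inactivation)) {
      rows[[length(rows) + 1L]] <-
        list(col = paste0("inact_", nm), gp = cs$inactivation, cond = cs$name)
    }
  }
  rows
}

.equilibrium_state <- function(cell, v) {
  gates <- .gate_table(cell)
  setNames(
    vapply(gates, function(g) .gate_steady(g$gp, v), numeric(1)),
    vapply(gates, `[[`, character(1), "col")
  )
}

.cell_currents <- function(cell, v, state) {
  out <- list()
  for (cs in cell$conductances) {
    nm <- tolower(cs$name)
    a <- state[[paste0("act_", nm)]]
    h <- if (is.null(cs$inactivation)) 1 else state[[paste0("inact_", nm)]]
    out[[paste0("i_", nm)]] <-
      cs$g_max * a^cs$activation$order * h * (v - cs$e_rev)
  }
  out$i_leak <- cell$g_leak * (v - cell$e_leak)
  out
}

#' Net steady-state membrane current at a voltage
#'
#' Total ionic current (leak plus voltage-gated currents with gates at
#' equilibrium, plus an optional constant light conductance) at membrane
#' voltage `v`. Its root is the resting (or light-adapted steady-state)
#' potential.
#'
#' @param cell A calibrated `kv_cell`.
#' @param v Membrane voltage(s) (V).
#' @param g_light Constant light conductance (S).
#' @return Current(s) in amperes (outward positive).
#' @export
steady_state_current <- function(cell, v, g_light = 0) {
  stopifnot(.is_cell(cell))
  vapply(v, function(vv) {
    st <- as.list(.equilibrium_state(cell, vv))
    sum(unlist(.cell_currents(cell, vv, st))) +
      g_light * (vv - cell$e_light)
  }, numeric(1))
}

#' Resting equilibrium potential of a calibrated cell
#'
#' Root of [steady_state_current()] between the most negative reversal
#' potential and the most positive of the leak/light reversal potentials.
#'
#' @inheritParams steady_state_current
#' @return Voltage (V).
#' @export
resting_equilibrium <- function(cell, g_light = 0) {
  stopifnot(.is_cell(cell))
  if (is.na(cell$g_leak)) abort("Cell is not calibrated.")
  e_revs <- vapply(cell$conductances, `[[`, numeric(1), "e_rev")
  lo <- min(e_revs, cell$e_leak) + 1e-6
  hi <- max(cell$e_leak, cell$e_light) - 1e-6
  uniroot(function(v) steady_state_current(cell, v, g_light),
          c(lo, hi), tol = 1e-12)$root
}

.as_kv_sim <- function(df, cell, mode) {
  out <- as_tibble(df)
  class(out) <- c("kv_sim", class(out))
  attr(out, "cell") <- cell
  attr(out, "mode") <- mode
  out
}

#' Simulate a voltage-clamp protocol
#'
#' The membrane voltage is the prescribed command; the first-order gating
#' equations \eqn{dx/dt = (x_\infty(V) - x)/\tau(V)} are integrated
#' numerically within each fixed-voltage epoch (`deSolve::lsoda`), starting
#' from equilibrium at the holding potential, and the ionic currents
#' \eqn{I = g_{max} a^P h (V - E_{rev})} are evaluated at every sample.
#' There is no light term and no capacitive current (ideal clamp).
#'
#' @param cell A calibrated `kv_cell`.
#' @param protocol A [voltage_protocol()].
#' @param rtol,atol Solver tolerances.
#' @return A `kv_sim` tibble with columns `time`, `v`, one column per gate
#'   (`act_kdr`, `act_ka`, `inact_ka`, ...), per-conductance currents
#'   (`i_kdr`, `i_ka`, ...), `i_leak` and `i_total`.
#' @export
simulate_voltage_clamp <- function(cell, protocol, rtol = 1e-8,
                                   atol = 1e-12) {
  stopifnot(.is_cell(cell), inherits(protocol, "kv_protocol"))
  if (is.na(cell$g_leak)) abort("Cell is not calibrated.")
  gates <- .gate_table(cell)
  cols <- vapply(gates, `[[`, character(1), "col")
  si <- protocol$sample_interval

  ends <- cumsum(protocol$epochs$duration)
  starts <- c(0, ends[-length(ends)])
  total <- ends[length(ends)]
  t_global <- seq(0, total, by = si)
  if (t_global[length(t_global)] < total - 1e-12) {
    t_global <- c(t_global, total)
  }
  # half-open epochs: a sample exactly on a boundary belongs to the epoch
  # that starts there (the final sample to the last epoch)
  epoch_of <- pmin(findInterval(t_global, starts), length(starts))

  state <- .equilibrium_state(cell, protocol$holding)
  out_rows <- vector("list", nrow(protocol$epochs))
  for (i in seq_len(nrow(protocol$epochs))) {
    v_cmd <- protocol$epochs$level[i]
    dur <- protocol$epochs$duration[i]
    local_t <- t_global[epoch_of == i] - starts[i]
    solve_t <- sort(unique(c(0, local_t, dur)))
    deriv <- function(t, y, p) {
      list((vapply(gates, function(g) .gate_steady(g$gp, v_cmd),
                   numeric(1)) - y) /
             vapply(gates, function(g) bell_time_constant(g$gp, v_cmd),
                    numeric(1)))
    }
    sol <- deSolve::lsoda(y = state, times = solve_t, func = deriv,
                          rtol = rtol, atol = atol)
    sol_df <- as.data.frame(sol)
    keep <- sol_df[match(round(local_t, 12), round(sol_df$time, 12)), ,
                   drop = FALSE]
    keep$time <- keep$time + starts[i]
    keep$v <- v_cmd
    out_rows[[i]] <- keep
    state <- unlist(sol_df[nrow(sol_df), cols, drop = FALSE])
  }
  res <- dplyr::bind_rows(out_rows)
  curs <- list()
  for (cs in cell$conductances) {
    nm <- tolower(cs$name)
    a <- res[[paste0("act_", nm)]]
    h <- if (is.null(cs$inactivation)) 1 else res[[paste0("inact_", nm)]]
    curs[[paste0("i_", nm)]] <-
      cs$g_max * a^cs$activation$order * h * (res$v - cs$e_rev)
  }
  curs$i_leak <- cell$g_leak * (res$v - cell$e_leak)
  res <- dplyr::bind_cols(res[c("time", "v", cols)], as_tibble(curs))
  res$i_total <- rowSums(res[grep("^i_", names(res))])
  .as_kv_sim(res, cell, "voltage_clamp")
}

#' Simulate a current-clamp (light-response) run
#'
#' Integrates the full Hodgkin-Huxley-type membrane equation
#' \deqn{\frac{dV}{dt} = -\frac{I_{light} + \sum_i I_i + I_{leak} -
#' I_{inject}}{C}}
#' together with the gating equations, driven by a light-conductance
#' waveform (\eqn{I_{light} = g_{light}(t)\,(V - E_{light})}). The solver is
#' stiff-capable (`deSolve::lsoda`): gating time constants of 1.5-50 ms
#' coexist with multi-second stimuli. The initial state is the gating
#' equilibrium at `v0` (defaults to the cell's resting potential); output is
#' sampled on the stimulus grid.
#'
#' @param cell A calibrated `kv_cell`.
#' @param stim A [stimulus_waveform()].
#' @param v0 Initial membrane voltage (V).
#' @param rtol,atol Solver tolerances (relative 1e-6, absolute 1e-9 on all
#'   states by default).
#' @return A `kv_sim` tibble with `time`, `v`, gate columns, `i_light`,
#'   per-conductance currents, `i_leak`.
#' @export
simulate_current_clamp <- function(cell, stim, v0 = cell$v_rest,
                                   rtol = 1e-6, atol = 1e-9) {
  stopifnot(.is_cell(cell), inherits(stim, "kv_stimulus"))
  if (is.na(cell$g_leak)) abort("Cell is not calibrated.")
  gates <- .gate_table(cell)
  cols <- vapply(gates, `[[`, character(1), "col")
  g_fun <- approxfun(stim$time, stim$g_light, rule = 2)
  i_fun <- if ("i_inject" %in% names(stim)) {
    approxfun(stim$time, stim$i_inject, rule = 2)
  } else {
    function(t) 0
  }
  y0 <- c(v = v0, .equilibrium_state(cell, v0))
  gps <- lapply(gates, `[[`, "gp")
  deriv <- function(t, y, p) {
    v <- y[[1]]
    x <- y[-1]
    xinf <- vapply(gps, .gate_steady, numeric(1), v = v)
    tau <- vapply(gps, bell_time_constant, numeric(1), v = v)
    i_ion <- g_fun(t) * (v - cell$e_light) + cell$g_leak * (v - cell$e_leak)
    for (cs in cell$conductances) {
      nm <- tolower(cs$name)
      a <- x[[paste0("act_", nm)]]
      h <- if (is.null(cs$inactivation)) 1 else x[[paste0("inact_", nm)]]
      i_ion <- i_ion + cs$g_max * a^cs$activation$order * h * (v - cs$e_rev)
    }
    list(c(-(i_ion - i_fun(t)) / cell$capacitance, (xinf - x) / tau))
  }
  sol <- deSolve::lsoda(y = y0, times = stim$time, func = deriv,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE solver did not converge (istate = %d, rtol = %g).",
                  attr(sol, "istate")[1], rtol))
  }
  res <- as_tibble(as.data.frame(sol))
  curs <- list(i_light = stim$g_light * (res$v - cell$e_light))
  for (cs in cell$conductances) {
    nm <- tolower(cs$name)
    a <- res[[paste0("act_", nm)]]
    h <- if (is.null(cs$inactivation)) 1 else res[[paste0("inact_", nm)]]
    curs[[paste0("i_", nm)]] <-
      cs$g_max * a^cs$activation$order * h * (res$v - cs$e_rev)
  }
  curs$i_leak <- cell$g_leak * (res$v - cell$e_leak)
  res <- dplyr::bind_cols(res[c("time", "v", cols)], as_tibble(curs))
  .as_kv_sim(res, cell, "current_clamp")
}

#' Simulate the two-prepulse subtraction protocol
#'
#' The experimental isolation of the transient A-type current: one family of
#' depolarizing steps after an inactivation-removing prepulse (total
#' current) and one after an inactivating prepulse (sustained current); the
#' transient current is the pointwise difference on the shared grid.
#'
#' Note that the subtraction is only approximate as an estimator of the true
#' KA current: the delayed-rectifier activation state also differs between
#' the two prepulse histories, and the inactivating prepulse does not
#' inactivate KA completely. The returned `ka_true` family (the model's
#' actual KA current during the total-current run) makes this error
#' measurable; for an artifact-free isolation compare against a companion
#' run with `g_max(KA) = 0` (see the methods vignette).
#'
#' @param cell A calibrated `kv_cell` containing a conductance named `"KA"`.
#' @param test_levels Step command voltages (V).
#' @param prepulse_removing Inactivation-removing prepulse level (V).
#' @param prepulse_inactivating Inactivating prepulse level (V).
#' @param prepulse_duration,step_duration Epoch durations (s).
#' @param holding Holding potential before the prepulse.
#' @param sample_interval Output sampling interval (s).
#' @return An object of class `kv_subtraction`: a list with tibbles `total`,
#'   `sustained` (full simulation columns plus `step`), `transient`
#'   (`step`, `time`, `t_step`, `i`), and `ka_true` (the model's KA current
#'   in the total run), plus the step onset time in `step_onset`.
#' @export
simulate_subtraction_protocol <- function(cell, test_levels,
                                          prepulse_removing = mV(-117),
                                          prepulse_inactivating = mV(-57),
                                          prepulse_duration = 0.5,
                                          step_duration = 0.05,
                                          holding = cell$v_rest,
                                          sample_interval = 1e-4) {
  stopifnot(.is_cell(cell))
  run_family <- function(prepulse) {
    purrr::map_dfr(test_levels, function(lv) {
      prot <- voltage_protocol(
        tibble(level = c(prepulse, lv),
               duration = c(prepulse_duration, step_duration)),
        holding = holding, sample_interval = sample_interval
      )
      sim <- simulate_voltage_clamp(cell, prot)
      sim$step <- lv
      sim
    })
  }
  total <- run_family(prepulse_removing)
  sustained <- run_family(prepulse_inactivating)
  if (!identical(total$time, sustained$time)) {
    abort("Subtraction grids do not match.")
  }
  transient <- tibble(
    step = total$step, time = total$time,
    t_step = total$time - prepulse_duration,
    i = total$i_total - sustained$i_total
  )
  ka_true <- if ("i_ka" %in% names(total)) {
    tibble(step = total$step, time = total$time,
           t_step = total$time - prepulse_duration, i = total$i_ka)
  } else {
    tibble(step = numeric(), time = numeric(), t_step = numeric(),
           i = numeric())
  }
  structure(list(total = total, sustained = sustained,
                 transient = transient, ka_true = ka_true,
                 step_onset = prepulse_duration),
            class = "kv_subtraction")
}

#' Scale one conductance of a cell
#'
#' Multiplies `g_max` of the named conductance by `scale`, leaving the
#' calibrated leak untouched (the scaling emulates a channel knockdown or
#' over-expression on an otherwise identical membrane).
#'
#' @param cell A `kv_cell`.
#' @param name Conductance name.
#' @param scale Non-negative factor.
#' @return The modified cell.
#' @export
scale_conductance <- function(cell, name, scale) {
  stopifnot(.is_cell(cell))
  if (scale < 0) abort("`scale` must be non-negative.")
  if (!name %in% names(cell$conductances)) {
    abort(sprintf("No conductance named '%s'.", name))
  }
  cell$conductances[[name]]$g_max <- cell$conductances[[name]]$g_max * scale
  cell
}

#' Conductance-scaling simulation experiment
#'
#' Reruns a current-clamp light-response simulation with one conductance's
#' maximal value scaled by each factor, and reports how much the voltage
#' trace changes. The leak stays at the reference cell's calibrated value;
#' each scaled run starts from its own equilibrium adapted to the
#' stimulus's initial light conductance (found by root-finding), so no
#' artificial onset transient enters the comparison.
#'
#' Used to probe the functional role of a conductance: scaling the transient
#' KA conductance from zero to ten-fold leaves the light response
#' essentially unchanged (its strong inactivation near rest keeps its
#' current negligible), while scaling the delayed rectifier strongly and
#' monotonically changes the depolarization level.
#'
#' @param cell A calibrated `kv_cell`.
#' @param stim A [stimulus_waveform()].
#' @param name Conductance to scale (e.g. `"KA"` or `"KDR"`).
#' @param scales Non-negative scale factors.
#' @return An object of class `kv_scaling`: list with `traces`
#'   (tibble `scale`, `time`, `v`), `summary` (per-scale resting potential,
#'   mean and peak depolarization over the final 20 % of the run), and
#'   `max_deviation`, the maximum over time of the pairwise voltage spread
#'   across scales (V).
#' @export
conductance_scaling_experiment <- function(cell, stim, name = "KA",
                                           scales = c(0, 1, 2, 10)) {
  stopifnot(.is_cell(cell))
  if (any(scales < 0)) abort("`scales` must be non-negative.")
  runs <- purrr::map(scales, function(s) {
    cs <- scale_conductance(cell, name, s)
    v0 <- resting_equilibrium(cs, g_light = stim$g_light[1])
    sim <- simulate_current_clamp(cs, stim, v0 = v0)
    list(v0 = v0, sim = sim)
  })
  traces <- purrr::map2_dfr(scales, runs, function(s, r) {
    tibble(scale = s, time = r$sim$time, v = r$sim$v)
  })
  vmat <- vapply(runs, function(r) r$sim$v, numeric(nrow(runs[[1]]$sim)))
  spread <- apply(vmat, 1, function(x) diff(range(x)))
  late <- stim$time >= stats::quantile(stim$time, 0.8)
  summary <- purrr::map2_dfr(scales, runs, function(s, r) {
    tibble(scale = s, v_rest = r$v0,
           v_mean_late = mean(r$sim$v[late]),
           v_max = max(r$sim$v))
  })
  structure(list(conductance = name, traces = traces, summary = summary,
                 max_deviation = max(spread)),
            class = "kv_scaling")
}

#' @export
print.kv_scaling <- function(x, ...) {
  cat(sprintf("<kv_scaling> %s scaled over {%s}\n", x$conductance,
              paste(unique(x$traces$scale), collapse = ", ")))
  cat(sprintf("  max pairwise |dV| = %.3f mV\n", x$max_deviation * 1e3))
  print(x$summary)
  invisible(x)
}
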