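# Seeded generators emulating the study's raw inputs. All are pure
# functions of (parameters, seed): the seed is applied locally via
# withr::with_seed so the caller's RNG stream is untouched, and the
# generating ground truth is embedded in the output so closed-loop
# parameter-recovery tests need no external data.

#' Acquisition-artifact specification for synthetic recordings
#'
#' @param sd_current Additive Gaussian current noise SD (A).
#' @param sd_voltage Additive Gaussian voltage noise SD (V).
#' @param capacitive Inject capacitive charging transients at command
#'   transitions (time constant `rs * C`, area `C * dV`)?
#' @param rs Residual (post-compensation) access resistance (ohm).
#' @return A list of class `kv_noise`.
#' @export
noise_spec <- function(sd_current = pA(5), sd_voltage = mV(0.5),
                       capacitive = TRUE, rs = Mohm(5)) {
  if (sd_current < 0 || sd_voltage < 0) abort("Noise SDs must be >= 0.")
  if (rs < 0) abort("`rs` must be non-negative.")
  structure(list(sd_current = sd_current, sd_voltage = sd_voltage,
                 capacitive = capacitive, rs = rs),
            class = "kv_noise")
}

.zero_noise <- function() noise_spec(sd_current = 0, sd_voltage = 0,
                                     capacitive = FALSE, rs = 0)

#' Synthetic voltage-clamp recording family
#'
#' Forward-simulates current families with the model simulator and then
#' injects acquisition artifacts: a capacitive charging transient
#' \eqn{(\Delta V / R_s)\, e^{-t/R_s C}} at every command transition (whose
#' integral is the charge `C * dV`) and additive Gaussian noise.
#' Deterministic for a given seed; the generating cell and protocol are
#' embedded as ground truth.
#'
#' @param cell A calibrated `kv_cell`.
#' @param protocols A [voltage_protocol()] or a list of them (one sweep
#'   each).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A `kv_trace_set`: list with `data` (tibble `sweep`, `time`,
#'   `v_command`, `current`), `sweeps` (per-sweep metadata incl. step
#'   level and access resistance) and `truth` (generator parameters).
#' @export
make_voltage_clamp_dataset <- function(cell, protocols,
                                       noise = noise_spec(), seed = 1) {
  stopifnot(.is_cell(cell))
  if (inherits(protocols, "kv_protocol")) protocols <- list(protocols)
  withr::with_seed(seed, {
    sweeps <- purrr::imap(protocols, function(prot, k) {
      sim <- simulate_voltage_clamp(cell, prot)
      i <- sim$i_total
      if (noise$capacitive && noise$rs > 0) {
        tau_c <- noise$rs * cell$capacitance
        lv <- c(prot$holding, prot$epochs$level)
        starts <- c(0, cumsum(prot$epochs$duration))[seq_len(
          nrow(prot$epochs))]
        for (j in seq_len(nrow(prot$epochs))) {
          dv <- lv[j + 1] - lv[j]
          on <- sim$time >= starts[j]
          i[on] <- i[on] +
            dv / noise$rs * exp(-(sim$time[on] - starts[j]) / tau_c)
        }
      }
      if (noise$sd_current > 0) {
        i <- i + stats::rnorm(length(i), 0, noise$sd_current)
      }
      tibble(sweep = k, time = sim$time, v_command = sim$v, current = i)
    })
    data <- dplyr::bind_rows(sweeps)
  })
  meta <- purrr::imap_dfr(protocols, function(prot, k) {
    tibble(sweep = k, holding = prot$holding,
           prepulse = prot$epochs$level[1],
           step = prot$epochs$level[nrow(prot$epochs)],
           rs = noise$rs, seed = seed)
  })
  structure(list(data = data, sweeps = meta,
                 truth = list(cell = cell_to_config(cell),
                              noise = unclass(noise), seed = seed)),
            class = "kv_trace_set")
}

#' @export
print.kv_trace_set <- function(x, ...) {
  cat(sprintf("<kv_trace_set> %d sweeps, %d samples\n",
              nrow(x$sweeps), nrow(x$data)))
  print(x$sweeps)
  invisible(x)
}

#' @export
as_tibble.kv_trace_set <- function(x, ...) x$data

#' Synthetic steady-state activation/inactivation curve data
#'
#' Generates per-cell (voltage, amplitude) points on an order-`P` Boltzmann
#' with per-cell maximal-amplitude jitter (lognormal, coefficient of
#' variation `cell_cv`) and additive point noise proportional to each
#' cell's maximum. Works for activation curves (conductance amplitudes,
#' positive slope) and inactivation curves (normalized peak currents,
#' negative slope, `g_max = 1`, `cell_cv = 0`).
#'
#' @param gating A [gating_parameters()] ground truth.
#' @param g_max True population-mean maximal amplitude (S, or 1 for
#'   normalized data).
#' @param voltages Test voltages (V), spanning the rise.
#' @param n_cells Number of synthetic cells (replicate curves).
#' @param noise_frac Point noise SD as a fraction of the cell's maximum.
#' @param cell_cv Between-cell coefficient of variation of the maximum.
#' @param seed Integer seed.
#' @return Tibble (`cell`, `voltage`, `conductance`) with the truth in
#'   `attr(, "truth")`.
#' @export
make_activation_dataset <- function(gating, g_max, voltages, n_cells = 6,
                                    noise_frac = 0.05, cell_cv = 0.25,
                                    seed = 1) {
  stopifnot(.is_gating(gating))
  if (length(voltages) < 4) abort("`voltages` must span the rise (>= 4).")
  base <- boltzmann_steady_state(gating, voltages)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(k) {
      gk <- if (cell_cv > 0) {
        sdlog <- sqrt(log(1 + cell_cv^2))
        g_max * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        g_max
      }
      tibble(cell = k, voltage = voltages,
             conductance = gk * base +
               stats::rnorm(length(voltages), 0, noise_frac * gk))
    })
  })
  attr(out, "truth") <- list(v_half = gating$v_half, slope = gating$slope,
                             order = gating$order, g_max = g_max,
                             noise_frac = noise_frac, cell_cv = cell_cv,
                             seed = seed)
  out
}

#' Synthetic tail-current family over external K+ concentrations
#'
#' Per concentration, each synthetic cell's reversal potential follows the
#' configured log-linear relation (default anchored at -68 mV at 5 mM, the
#' measured anchor; use the ideal [nernst_potential()] slope and a -84 mV
#' anchor for a perfectly selective channel) plus between-cell scatter.
#' Tail amplitudes are linear in the driving force,
#' \eqn{A = g_{tail} (V - E_{rev})}, plus current noise.
#'
#' @param concentrations External K+ concentrations (mM).
#' @param test_voltages Tail test voltages (V).
#' @param anchor_e_rev Reversal potential at `anchor_conc` (V).
#' @param anchor_conc Anchor concentration (mM).
#' @param slope_per_decade Reversal-potential slope per tenfold
#'   concentration (V).
#' @param g_tail Instantaneous tail conductance (S).
#' @param n_cells Synthetic cells per concentration.
#' @param sd_e_rev Between-cell reversal-potential SD (V).
#' @param sd_current Amplitude noise SD (A).
#' @param seed Integer seed.
#' @return Tibble (`concentration`, `cell`, `voltage`, `amplitude`) with
#'   truth in `attr(, "truth")`.
#' @export
make_tail_family <- function(concentrations = c(5, 15, 25, 50),
                             test_voltages = mV(seq(-100, -40, by = 10)),
                             anchor_e_rev = mV(-68), anchor_conc = 5,
                             slope_per_decade = mV(52),
                             g_tail = nS(10), n_cells = 6,
                             sd_e_rev = mV(3), sd_current = pA(5),
                             seed = 1) {
  if (any(concentrations <= 0)) abort("Concentrations must be positive.")
  out <- withr::with_seed(seed, {
    purrr::map_dfr(concentrations, function(conc) {
      e_true <- anchor_e_rev +
        slope_per_decade * log10(conc / anchor_conc)
      purrr::map_dfr(seq_len(n_cells), function(k) {
        e_cell <- e_true + stats::rnorm(1, 0, sd_e_rev)
        tibble(concentration = conc, cell = k, voltage = test_voltages,
               amplitude = g_tail * (test_voltages - e_cell) +
                 stats::rnorm(length(test_voltages), 0, sd_current))
      })
    })
  })
  attr(out, "truth") <- list(anchor_e_rev = anchor_e_rev,
                             anchor_conc = anchor_conc,
                             slope_per_decade = slope_per_decade,
                             g_tail = g_tail, sd_e_rev = sd_e_rev,
                             sd_current = sd_current, seed = seed)
  out
}

#' Synthetic fractional-block dose-response points
#'
#' Logistic mean \eqn{1/(1 + (c/IC_{50})^p)} plus Gaussian noise, clipped
#' at zero (fractional currents cannot be negative).
#'
#' @param ic50 True half-inhibition concentration (same unit as `doses`).
#' @param hill True Hill coefficient.
#' @param doses Blocker concentrations.
#' @param n_reps Replicates per dose.
#' @param noise_sd Gaussian noise SD on the fractional response.
#' @param seed Integer seed.
#' @return Tibble (`dose`, `rep`, `response`) with truth in
#'   `attr(, "truth")`.
#' @export
make_dose_response_dataset <- function(ic50 = 32e-6, hill = 0.97,
                                       doses = c(1, 3, 10, 30, 100, 300,
                                                 1000) * 1e-6,
                                       n_reps = 4, noise_sd = 0.05,
                                       seed = 1) {
  if (ic50 <= 0 || hill <= 0) abort("`ic50` and `hill` must be positive.")
  if (any(doses <= 0)) abort("Doses must be positive.")
  mean_f <- 1 / (1 + (doses / ic50)^hill)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      tibble(dose = doses, rep = r,
             response = pmax(0, mean_f +
                               stats::rnorm(length(doses), 0, noise_sd)))
    })
  })
  attr(out, "truth") <- list(ic50 = ic50, hill = hill,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Naturalistic-like fluctuating light conductance
#'
#' A stand-in for a light conductance derived from naturalistic intensity
#' recordings: a log-normal-amplitude waveform with low-pass temporal
#' correlation, built by exponentiating an AR(1) (discretized
#' Ornstein-Uhlenbeck) process. The realized waveform is rescaled to the
#' requested mean, the way stimulus intensities are normalized at the rig.
#' It is positively skewed, non-negative and slowly fluctuating, which is
#' what the simulator needs; it makes no claim of statistical identity
#' with any recorded natural intensity series.
#'
#' @param duration Length (s).
#' @param mean_level Mean conductance (S).
#' @param contrast Coefficient of variation of the log-normal amplitude
#'   distribution (0 gives a constant waveform).
#' @param tau_corr Correlation time of the underlying process (s).
#' @param dt Sample interval (s).
#' @param seed Integer seed.
#' @return A [stimulus_waveform()].
#' @export
make_naturalistic_conductance <- function(duration = 10,
                                          mean_level = nS(5),
                                          contrast = 0.5, tau_corr = 0.1,
                                          dt = 1e-3, seed = 1) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (mean_level < 0 || contrast < 0) {
    abort("`mean_level` and `contrast` must be non-negative.")
  }
  time <- seq(0, duration, by = dt)
  n <- length(time)
  if (contrast == 0) {
    return(stimulus_waveform(time, rep(mean_level, n)))
  }
  g <- withr::with_seed(seed, {
    phi <- exp(-dt / tau_corr)
    innov_sd <- sqrt(1 - phi^2)
    x <- numeric(n)
    x[1] <- stats::rnorm(1)
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
    sdlog <- sqrt(log(1 + contrast^2))
    g <- exp(sdlog * x - sdlog^2 / 2) * mean_level
    g * (mean_level / mean(g))
  })
  stimulus_waveform(time, g)
}

#' Quantum-bump train: discrete single-photon current events
#'
#' Poisson-timed, gamma-shaped inward current events with lognormal
#' amplitude scatter and jittered transduction latency, phenomenologically
#' emulating dim-flash recordings of single-photon responses (and
#' failures). Event times and amplitudes are returned as metadata.
#'
#' @param rate Photon absorption rate (events/s).
#' @param duration Trace length (s).
#' @param amplitude Mean bump peak amplitude (A, negative = inward).
#' @param amplitude_cv Between-bump amplitude coefficient of variation.
#' @param shape Gamma shape of the bump waveform.
#' @param scale Gamma scale (s); bump duration is about `shape * scale`.
#' @param latency_mean,latency_sd Transduction latency mean and jitter (s).
#' @param dt Sample interval (s).
#' @param seed Integer seed.
#' @return Tibble (`time`, `current`) with event table in
#'   `attr(, "events")`.
#' @export
make_quantum_bump_train <- function(rate = 10, duration = 2,
                                    amplitude = pA(-20),
                                    amplitude_cv = 0.3, shape = 3,
                                    scale = ms(10),
                                    latency_mean = ms(25),
                                    latency_sd = ms(10), dt = 1e-3,
                                    seed = 1) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (rate < 0) abort("`rate` must be non-negative.")
  if (amplitude > 0) abort("Bump amplitudes are inward: `amplitude` <= 0.")
  time <- seq(0, duration, by = dt)
  current <- numeric(length(time))
  events <- tibble(onset = numeric(), latency = numeric(),
                   amplitude = numeric())
  if (rate > 0) {
    ev <- withr::with_seed(seed, {
      n_ev <- stats::rpois(1, rate * duration)
      if (n_ev > 0) {
        tibble(
          onset = sort(stats::runif(n_ev, 0, duration)),
          latency = pmax(0, stats::rnorm(n_ev, latency_mean, latency_sd)),
          amplitude = amplitude * stats::rlnorm(
            n_ev, -log(1 + amplitude_cv^2) / 2,
            sqrt(log(1 + amplitude_cv^2)))
        )
      } else {
        events
      }
    })
    events <- ev
    if (nrow(events) > 0) {
      # gamma kernel normalized to unit peak
      t_peak <- (shape - 1) * scale
      peak_val <- stats::dgamma(t_peak, shape = shape, scale = scale)
      for (j in seq_len(nrow(events))) {
        t_rel <- time - events$onset[j] - events$latency[j]
        on <- t_rel >= 0
        current[on] <- current[on] + events$amplitude[j] *
          stats::dgamma(t_rel[on], shape = shape, scale = scale) / peak_val
      }
    }
  }
  out <- tibble(time = time, current = current)
  attr(out, "events") <- events
  attr(out, "truth") <- list(rate = rate, amplitude = amplitude,
                             shape = shape, scale = scale,
                             latency_mean = latency_mean,
                             latency_sd = latency_sd, seed = seed)
  out
}
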