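# Workbench layer: YAML-config driven entry points tying the pipeline
# together (simulate / characterize / recover / synth), used both
# programmatically and from the thin command-line front-end in
# inst/cli/kvworkbench.R. Every run records provenance: config hash, seed
# and package version.

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("Config file '%s' does not exist.", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  config
}

.resolve_cell <- function(spec) {
  if (is.null(spec) || identical(spec, "canonical")) return(canonical_cell())
  if (identical(spec, "validation")) return(validation_cell())
  if (is.character(spec)) return(calibrate_cell(read_cell_config(spec)))
  if (.is_cell(spec)) return(if (is.na(spec$g_leak)) calibrate_cell(spec)
                             else spec)
  abort("Unrecognized cell spec: use 'canonical', 'validation', a config path or a kv_cell.")
}

.provenance <- function(config, seed) {
  list(config_hash = rlang::hash(config), seed = seed,
       package_version = as.character(packageVersion("photoKv")))
}

.resolve_stimulus <- function(cfg, seed) {
  type <- cfg$type %||% "naturalistic"
  if (type == "naturalistic") {
    make_naturalistic_conductance(
      duration = cfg$duration_s %||% 10,
      mean_level = nS(cfg$mean_nS %||% 5),
      contrast = cfg$contrast %||% 0.5,
      tau_corr = ms(cfg$tau_corr_ms %||% 100),
      dt = ms(cfg$dt_ms %||% 1),
      seed = seed)
  } else if (type == "constant") {
    time <- seq(0, cfg$duration_s %||% 1, by = ms(cfg$dt_ms %||% 1))
    stimulus_waveform(time, rep(nS(cfg$g_light_nS %||% 0), length(time)))
  } else {
    abort(sprintf("Unknown stimulus type '%s'.", type))
  }
}

.resolve_protocol <- function(cfg) {
  voltage_protocol(
    epochs = tibble(level = mV(vapply(cfg$epochs, `[[`, numeric(1),
                                      "level_mV")),
                    duration = ms(vapply(cfg$epochs, `[[`, numeric(1),
                                         "duration_ms"))),
    holding = mV(cfg$holding_mV %||% -60),
    sample_interval = ms(cfg$sample_interval_ms %||% 0.1))
}

#' Run a simulation from a config
#'
#' Reads a YAML (or list) config describing a cell and either a
#' voltage-clamp protocol or a current-clamp stimulus, runs the simulation,
#' and writes the result table, a metadata sidecar and a `summary.yaml`
#' reporting the resting potential, the calibrated leak conductance and the
#' instantaneous input resistance at rest, plus provenance (config hash,
#' seed, package version). Reruns with the same config and seed reproduce
#' the outputs bit-identically.
#'
#' @param config A list or YAML file path. Fields: `mode`
#'   (`"current_clamp"` or `"voltage_clamp"`), `cell` (`"canonical"`,
#'   `"validation"` or a cell-config path), `seed`, and `stimulus` or
#'   `protocol` blocks.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the simulation and the summary.
#' @export
wb_simulate <- function(config, out_dir, quiet = FALSE) {
  config <- .load_config(config)
  seed <- config$seed %||% 1
  cell <- .resolve_cell(config$cell)
  mode <- config$mode %||% "current_clamp"
  t0 <- Sys.time()
  if (mode == "current_clamp") {
    stim <- .resolve_stimulus(config$stimulus %||% list(), seed)
    sim <- simulate_current_clamp(cell, stim)
  } else if (mode == "voltage_clamp") {
    prot <- .resolve_protocol(config$protocol)
    sim <- simulate_voltage_clamp(cell, prot)
  } else {
    abort(sprintf("Unknown mode '%s'.", mode))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_simulation(sim, file.path(out_dir, "result"),
                   provenance = .provenance(config, seed))
  summary <- list(
    mode = mode,
    cell = cell$name,
    v_rest_mV = cell$v_rest * 1e3,
    g_leak_nS = cell$g_leak * 1e9,
    g_leak_nS_printed = sprintf("%.1f", cell$g_leak * 1e9),
    r_in_at_rest_Mohm = input_resistance(cell) * 1e-6,
    samples = nrow(sim),
    provenance = .provenance(config, seed)
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"),
                   precision = 17)
  if (!quiet) {
    message(sprintf(
      "simulate: %d samples in %.2f s; g_leak = %s nS, R_in = %.0f Mohm",
      nrow(sim), as.numeric(Sys.time() - t0, units = "secs"),
      summary$g_leak_nS_printed, summary$r_in_at_rest_Mohm))
  }
  invisible(list(sim = sim, summary = summary))
}

#' Characterize the sustained (delayed-rectifier) conductance from a
#' voltage-clamp family
#'
#' The experimental pipeline on a trace set: offline series-resistance
#' correction of each sweep, steady-state current extraction (mean over the
#' final fraction of the step epoch), optional subtraction of the known
#' leak current, conversion to conductance via \eqn{g = I/(V - E_{rev})} at
#' the Rs-corrected voltage, and a first-order Boltzmann fit.
#'
#' @param ts A `kv_trace_set` of step protocols (last epoch = test step).
#' @param e_rev Reversal potential used for the conductance conversion (V).
#' @param g_leak,e_leak Known leak parameters to subtract before the
#'   conversion; `g_leak = NULL` skips leak subtraction (the raw
#'   experimental convention).
#' @param steady_fraction Final fraction of the step epoch averaged as the
#'   steady state.
#' @return A list: `points` (tibble `sweep`, `step`, `v_effective`,
#'   `i_steady`, `conductance`) and `fit` (a `kv_fit`).
#' @export
characterize_kdr <- function(ts, e_rev = mV(-68), g_leak = NULL,
                             e_leak = 0, steady_fraction = 0.1) {
  stopifnot(inherits(ts, "kv_trace_set"))
  if (nrow(ts$data) == 0) abort("Empty trace set.")
  points <- purrr::map_dfr(unique(ts$data$sweep), function(k) {
    d <- ts$data[ts$data$sweep == k, ]
    meta <- ts$sweeps[ts$sweeps$sweep == k, ]
    step_v <- meta$step
    # samples belonging to the final (test) epoch
    in_step <- d$v_command == step_v &
      d$time > max(d$time[d$v_command != step_v])
    seg <- d[in_step, ]
    seg <- correct_series_resistance(
      tibble(time = seg$time, current = seg$current),
      rs = meta$rs, command = step_v)
    n <- nrow(seg)
    late <- seg[seg$time >= stats::quantile(seg$time,
                                            1 - steady_fraction), ]
    i_ss <- mean(late$current)
    v_eff <- mean(late$v_effective)
    i_cond <- if (is.null(g_leak)) i_ss else
      i_ss - g_leak * (v_eff - e_leak)
    tibble(sweep = k, step = step_v, v_effective = v_eff,
           i_steady = i_ss,
           conductance = conductance_from_current(i_cond, v_eff, e_rev))
  })
  fit <- fit_boltzmann(
    tibble(voltage = points$v_effective,
           conductance = points$conductance), order = 1)
  list(points = points, fit = fit)
}

#' Config-driven characterization of a dataset
#'
#' Dispatches the fitting pipeline appropriate to a dataset kind and
#' returns a structured report (tidy estimates plus provenance). Kinds:
#' \describe{
#'   \item{`kdr_activation`}{a trace-set prefix (see [write_trace_set()]);
#'     Rs correction, steady-state extraction and first-order Boltzmann fit
#'     via [characterize_kdr()].}
#'   \item{`activation_points`}{a TSV of (`voltage`, `conductance`)
#'     points, per-cell Boltzmann fits of the configured `order`.}
#'   \item{`dose_response`}{a TSV of (`dose`, `response`),
#'     [fit_dose_response()].}
#'   \item{`tails`}{a TSV of (`concentration`, `voltage`, `amplitude`);
#'     per-concentration reversal potentials then [fit_nernst_relation()].}
#' }
#'
#' @param config A list or YAML path with fields `kind`, `data` (path or
#'   prefix), and kind-specific options.
#' @param out_dir Optional directory for the YAML report.
#' @param quiet Suppress progress messages?
#' @return A list report: `kind`, `fits` (named list of tidy tibbles),
#'   `provenance`.
#' @export
wb_characterize <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- .load_config(config)
  kind <- config$kind %||% abort("Config needs a `kind` field.")
  seed <- config$seed %||% 1
  fits <- list()
  if (kind == "kdr_activation") {
    ts <- read_trace_set(config$data)
    res <- characterize_kdr(
      ts,
      e_rev = mV(config$e_rev_mV %||% -68),
      g_leak = if (is.null(config$g_leak_nS)) NULL
               else nS(config$g_leak_nS))
    fits$boltzmann <- tidy(res$fit)
    fits$points <- res$points
  } else if (kind == "activation_points") {
    d <- readr::read_tsv(config$data, show_col_types = FALSE)
    ord <- config$order %||% 1
    if ("cell" %in% names(d)) {
      fits$boltzmann <- purrr::map_dfr(unique(d$cell), function(k) {
        f <- fit_boltzmann(d[d$cell == k, ], order = ord)
        dplyr::mutate(tidy(f), cell = k)
      })
    } else {
      fits$boltzmann <- tidy(fit_boltzmann(d, order = ord))
    }
  } else if (kind == "dose_response") {
    d <- readr::read_tsv(config$data, show_col_types = FALSE)
    fits$dose_response <- tidy(fit_dose_response(d))
  } else if (kind == "tails") {
    d <- readr::read_tsv(config$data, show_col_types = FALSE)
    revs <- purrr::map_dfr(unique(d$concentration), function(cc) {
      f <- estimate_reversal_potential(d[d$concentration == cc, ])
      tibble(concentration = cc,
             e_rev = fit_estimate(f, "e_rev"),
             std.error = fit_se(f, "e_rev"))
    })
    fits$reversal <- revs
    fits$nernst <- tidy(fit_nernst_relation(revs))
  } else {
    abort(sprintf("Unknown characterization kind '%s'.", kind))
  }
  report <- list(kind = kind, fits = fits,
                 provenance = .provenance(config, seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(
      rapply(report, function(x) if (is.data.frame(x))
        lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])) else x,
        how = "replace"),
      file.path(out_dir, "report.yaml"), precision = 17)
  }
  if (!quiet) message(sprintf("characterize: kind = %s, %d fit table(s)",
                              kind, length(fits)))
  report
}

.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i) %% (.Machine$integer.max - 1) + 1)
}

#' Monte-Carlo recovery of Boltzmann parameters
#'
#' Generates `n_seeds` synthetic steady-state datasets from a known
#' Boltzmann truth, fits each synthetic cell independently, and tabulates
#' the recovered half-point voltages. The grand median across all cells and
#' seeds is the recovery estimate.
#'
#' @inheritParams make_activation_dataset
#' @param order Boltzmann order used for both generation (via `gating`) and
#'   fitting.
#' @param n_seeds Number of independent synthetic datasets.
#' @param seed Base seed; per-dataset seeds are derived from it.
#' @return A list: `estimates` (tibble `seed_index`, `cell`, `v50`,
#'   `slope`, `g_max`, `converged`), and `summary` (one row: grand medians,
#'   bias against truth, SD and SE of the per-cell estimates).
#' @export
recover_boltzmann <- function(gating, g_max, voltages, n_cells,
                              noise_frac = 0.05, cell_cv = 0.25,
                              order = gating$order, n_seeds = 100,
                              seed = 1) {
  est <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    ds <- make_activation_dataset(gating, g_max, voltages,
                                  n_cells = n_cells,
                                  noise_frac = noise_frac,
                                  cell_cv = cell_cv,
                                  seed = .derive_seed(seed, i))
    purrr::map_dfr(unique(ds$cell), function(k) {
      f <- fit_boltzmann(ds[ds$cell == k, ], order = order)
      tibble(seed_index = i, cell = k,
             v50 = fit_estimate(f, "v50"),
             slope = fit_estimate(f, "slope"),
             g_max = fit_estimate(f, "g_max"),
             converged = f$converged)
    })
  })
  ok <- est[est$converged & is.finite(est$v50), ]
  summary <- tibble(
    truth_v50 = gating$v_half,
    v50_median = median(ok$v50),
    bias = median(ok$v50) - gating$v_half,
    v50_sd = sd(ok$v50),
    v50_se = sd(ok$v50) / sqrt(nrow(ok)),
    n_fits = nrow(ok), n_seeds = n_seeds
  )
  list(estimates = est, summary = summary)
}

#' Monte-Carlo recovery of dose-response parameters
#'
#' @inheritParams make_dose_response_dataset
#' @param n_seeds Number of synthetic datasets.
#' @param seed Base seed.
#' @return A list: `estimates` (tibble `seed_index`, `ic50`, `hill`,
#'   `converged`) and `summary` (grand medians and dispersion).
#' @export
recover_dose_response <- function(ic50 = 32e-6, hill = 0.97,
                                  doses = c(1, 3, 10, 30, 100, 300,
                                            1000) * 1e-6,
                                  n_reps = 4, noise_sd = 0.05,
                                  n_seeds = 100, seed = 1) {
  est <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    ds <- make_dose_response_dataset(ic50, hill, doses, n_reps, noise_sd,
                                     seed = .derive_seed(seed, i))
    f <- fit_dose_response(ds)
    tibble(seed_index = i,
           ic50 = fit_estimate(f, "ic50"),
           hill = fit_estimate(f, "hill"),
           converged = f$converged)
  })
  ok <- est[est$converged & is.finite(est$ic50), ]
  summary <- tibble(
    truth_ic50 = ic50,
    ic50_median = median(ok$ic50),
    hill_median = median(ok$hill),
    ic50_sd = sd(ok$ic50),
    n_fits = nrow(ok), n_seeds = n_seeds
  )
  list(estimates = est, summary = summary)
}

#' Config-driven recovery suite
#'
#' Runs the standard parameter-recovery experiments (delayed-rectifier
#' activation, transient-current activation and inactivation, dose-response
#' half-inhibition) and tabulates bias per parameter.
#'
#' @param config List or YAML path; fields `seed`, `n_seeds` and optional
#'   `experiments` (character subset of `"kdr_v50"`, `"ka_act_v50"`,
#'   `"ka_inact_v50"`, `"ic50"`).
#' @param quiet Suppress progress messages?
#' @return A tibble: one row per experiment with truth, grand median,
#'   bias and dispersion.
#' @export
wb_recover <- function(config = list(), quiet = FALSE) {
  config <- .load_config(config)
  seed <- config$seed %||% 1
  n_seeds <- config$n_seeds %||% 100
  wanted <- config$experiments %||% c("kdr_v50", "ka_act_v50",
                                      "ka_inact_v50", "ic50")
  tt <- .kv_table1()
  rows <- list()
  run <- function(name, fn) {
    t0 <- Sys.time()
    res <- fn()
    if (!quiet) message(sprintf("recover: %s done in %.1f s", name,
                                as.numeric(Sys.time() - t0,
                                           units = "secs")))
    res
  }
  if ("kdr_v50" %in% wanted) {
    r <- run("kdr_v50", function() recover_boltzmann(
      tt$kdr_act, g_max = nS(78), voltages = mV(seq(-47, 23, by = 10)),
      n_cells = 6, noise_frac = 0.05, n_seeds = n_seeds, seed = seed))
    rows$kdr <- dplyr::mutate(r$summary, experiment = "kdr_v50",
                              parameter = "v50")
  }
  if ("ka_act_v50" %in% wanted) {
    r <- run("ka_act_v50", function() recover_boltzmann(
      tt$ka_act, g_max = nS(36), voltages = mV(seq(-57, 3, by = 10)),
      n_cells = 5, noise_frac = 0.05, n_seeds = n_seeds, seed = seed))
    rows$ka_act <- dplyr::mutate(r$summary, experiment = "ka_act_v50",
                                 parameter = "v50")
  }
  if ("ka_inact_v50" %in% wanted) {
    r <- run("ka_inact_v50", function() recover_boltzmann(
      tt$ka_inact, g_max = 1, voltages = mV(seq(-130, -40, by = 10)),
      n_cells = 4, noise_frac = 0.03, cell_cv = 0, n_seeds = n_seeds,
      seed = seed))
    rows$ka_inact <- dplyr::mutate(r$summary, experiment = "ka_inact_v50",
                                   parameter = "v50")
  }
  if ("ic50" %in% wanted) {
    r <- run("ic50", function() recover_dose_response(
      n_seeds = n_seeds, seed = seed))
    rows$ic50 <- tibble(truth_v50 = NA_real_,
                        v50_median = NA_real_, bias = r$summary$ic50_median -
                          r$summary$truth_ic50,
                        v50_sd = r$summary$ic50_sd,
                        v50_se = r$summary$ic50_sd /
                          sqrt(r$summary$n_fits),
                        n_fits = r$summary$n_fits, n_seeds = n_seeds,
                        experiment = "ic50", parameter = "ic50")
    rows$ic50$v50_median <- r$summary$ic50_median
    rows$ic50$truth_v50 <- r$summary$truth_ic50
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(
    dplyr::rename(out, truth = "truth_v50", grand_median = "v50_median",
                  sd = "v50_sd", se = "v50_se"),
    "experiment", "parameter", "truth", "grand_median", "bias", "sd",
    "se", "n_fits", "n_seeds")
}

#' Config-driven synthetic dataset generation
#'
#' Generates one of the standard synthetic datasets and writes it (plus
#' ground-truth metadata) to disk.
#'
#' @param config List or YAML path; fields `kind`
#'   (`"voltage_clamp"`, `"activation"`, `"dose_response"`, `"tails"`,
#'   `"naturalistic"`, `"bumps"`), `seed`, and kind-specific options.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages?
#' @return Invisibly, the generated object.
#' @export
wb_synth <- function(config, out_dir, quiet = FALSE) {
  config <- .load_config(config)
  kind <- config$kind %||% abort("Config needs a `kind` field.")
  seed <- config$seed %||% 1
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- switch(
    kind,
    voltage_clamp = {
      cell <- .resolve_cell(config$cell)
      levels <- mV(config$step_levels_mV %||% seq(-47, 3, by = 10))
      prots <- lapply(levels, function(lv) {
        voltage_protocol(
          tibble(level = c(mV(config$prepulse_mV %||% -117), lv),
                 duration = c(ms(config$prepulse_ms %||% 500),
                              ms(config$step_ms %||% 50))),
          holding = mV(config$holding_mV %||% -60))
      })
      ts <- make_voltage_clamp_dataset(cell, prots, seed = seed)
      write_trace_set(ts, file.path(out_dir, "traces"))
      ts
    },
    activation = {
      tt <- .kv_table1()
      ds <- make_activation_dataset(
        tt$kdr_act, g_max = nS(78),
        voltages = mV(config$voltages_mV %||% seq(-47, 23, by = 10)),
        n_cells = config$n_cells %||% 6, seed = seed)
      readr::write_tsv(ds, file.path(out_dir, "activation.tsv"))
      ds
    },
    dose_response = {
      ds <- make_dose_response_dataset(seed = seed)
      readr::write_tsv(ds, file.path(out_dir, "dose_response.tsv"))
      ds
    },
    tails = {
      ds <- make_tail_family(seed = seed)
      readr::write_tsv(ds, file.path(out_dir, "tails.tsv"))
      ds
    },
    naturalistic = {
      stim <- make_naturalistic_conductance(seed = seed)
      readr::write_tsv(
        tibble(time_s = stim$time, g_light_S = stim$g_light),
        file.path(out_dir, "stimulus.tsv"))
      stim
    },
    bumps = {
      tr <- make_quantum_bump_train(seed = seed)
      readr::write_tsv(
        tibble(time_s = tr$time, current_A = tr$current),
        file.path(out_dir, "bumps.tsv"))
      tr
    },
    abort(sprintf("Unknown synth kind '%s'.", kind))
  )
  yaml::write_yaml(.provenance(config, seed),
                   file.path(out_dir, "provenance.yaml"))
  if (!quiet) message(sprintf("synth: kind = %s written to %s", kind,
                              out_dir))
  invisible(obj)
}
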