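test_that("leak calibration zeroes the net current at rest", {
  cell <- canonical_cell(calibrated = FALSE)
  g <- calibrate_leak(cell)
  expect_equal(g * 1e9, REF$g_leak_nS, tolerance = 1e-5)
  expect_equal(sprintf("%.1f", g * 1e9), "0.9")
  cal <- calibrate_cell(cell)
  expect_equal(steady_state_current(cal, mV(-60)), 0, tolerance = 1e-22)
  # nothing to balance without voltage-gated conductances
  bare <- cell_parameters(pF(380))
  expect_equal(calibrate_leak(bare, mV(-60)), 0)
  # the balance is linear in the maximal conductances
  dbl <- cell
  for (nm in names(dbl$conductances)) {
    dbl$conductances[[nm]]$g_max <- 2 * dbl$conductances[[nm]]$g_max
  }
  expect_equal(calibrate_leak(dbl), 2 * g)
  # infeasible balance (net inward Kv current at rest) is rejected
  infeasible <- cell
  infeasible$conductances$KDR$e_rev <- mV(0)
  infeasible$e_leak <- mV(10)
  expect_error(calibrate_leak(infeasible), "infeasible")
})

test_that("instantaneous input resistance and conductance shares", {
  cell <- canonical_cell()
  expect_equal(input_resistance(cell) * 1e-6, REF$r_in_Mohm,
               tolerance = 1e-4)
  expect_equal(round(input_resistance(cell) * 1e-6), 136)
  expect_equal(input_resistance(cell, mV(-84)) * 1e-6, REF$r_in_m84_Mohm,
               tolerance = 1e-3)
  # the delayed rectifier carries almost 90 % of the resting conductance
  share <- conductance_share(cell, "KDR")
  expect_gte(share, 0.85)
  expect_lte(share, 0.90)
  # a leak-only cell is just 1/g_leak
  bare <- cell_parameters(pF(380), g_leak = nS(1))
  expect_equal(input_resistance(bare, mV(-60)) * 1e-6, 1000)
})

test_that("membrane time constant and cut-off frequency", {
  res <- membrane_time_constant(pF(400), Mohm(150))
  expect_equal(res$tau, 0.060)
  expect_equal(res$cutoff, 1 / (2 * pi * 0.06), tolerance = 1e-10)
  expect_equal(membrane_time_constant(1, 1)$tau, 1)
  expect_error(membrane_time_constant(-1, 1), "positive")
})

test_that("voltage clamp reproduces the validation-cell steady state", {
  vc <- validation_cell()
  prot <- voltage_protocol(
    tibble::tibble(level = mV(c(-117, 3)), duration = c(0.5, 0.15)),
    holding = mV(-60), sample_interval = 1e-4)
  sim <- simulate_voltage_clamp(vc, prot)
  # steady-state total current at +3 mV after full KDR activation
  expect_equal(utils::tail(sim$i_total, 1) * 1e9, REF$validation_ss_nA,
               tolerance = 5e-4)
  # commanded voltage honoured sample by sample
  expect_true(all(sim$v[sim$time < 0.5] == mV(-117)))
  expect_true(all(sim$v[sim$time >= 0.5] == mV(3)))
})

test_that("integrated gating matches the closed-form relaxation oracle", {
  vc <- validation_cell()
  prot <- voltage_protocol(
    tibble::tibble(level = mV(c(-117, -27, -57)),
                   duration = c(0.3, 0.05, 0.05)),
    holding = mV(-60), sample_interval = 1e-4)
  sim <- simulate_voltage_clamp(vc, prot)
  gates <- list(act_kdr = vc$conductances$KDR$activation,
                act_ka = vc$conductances$KA$activation,
                inact_ka = vc$conductances$KA$inactivation)
  starts <- c(0, 0.3, 0.35)
  levels <- mV(c(-117, -27, -57))
  for (col in names(gates)) {
    gp <- gates[[col]]
    x0 <- photoKv:::.gate_steady(gp, mV(-60))
    worst <- 0
    for (j in seq_along(starts)) {
      seg <- sim$time >= starts[j] &
        (j == length(starts) | sim$time < c(starts[-1], Inf)[j])
      tloc <- sim$time[seg] - starts[j]
      oracle <- gating_relaxation(gp, levels[j], x0, tloc)
      worst <- max(worst, max(abs(sim[[col]][seg] - oracle)))
      # closed-form state at the epoch end seeds the next epoch
      x0 <- gating_relaxation(gp, levels[j], x0,
                              c(0.3, 0.05, 0.05)[j])
    }
    expect_lt(worst, 1e-6)
  }
})

test_that("potassium currents vanish at the reversal potential", {
  cell <- canonical_cell(calibrated = FALSE)
  cell$g_leak <- 0
  prot <- voltage_protocol(
    tibble::tibble(level = mV(-68), duration = 0.5),
    holding = mV(-117), sample_interval = 1e-3)
  sim <- simulate_voltage_clamp(cell, prot)
  expect_true(all(abs(sim$i_kdr) < 1e-18))
  expect_true(all(abs(sim$i_ka) < 1e-18))
})

test_that("current clamp holds the calibrated fixed point in darkness", {
  cell <- canonical_cell()
  sim <- simulate_current_clamp(cell, constant_stim(0, duration = 1))
  expect_lt(max(abs(sim$v - mV(-60))), 1e-6)
})

test_that("current clamp converges to the algebraic balance under a step", {
  cell <- canonical_cell()
  sim <- simulate_current_clamp(cell, constant_stim(nS(5), duration = 2))
  # independent scalar root of the steady-state current balance
  target <- uniroot(function(v) {
    gl <- 5e-9 * (v - cell$e_light)
    ik <- sum(vapply(cell$conductances, function(cs) {
      a <- (1 + exp((cs$activation$v_half - v) / cs$activation$slope))^(-1)
      h <- if (is.null(cs$inactivation)) 1 else
        (1 + exp((cs$inactivation$v_half - v) /
                   cs$inactivation$slope))^(-1)
      cs$g_max * a^cs$activation$order * h * (v - cs$e_rev)
    }, numeric(1)))
    gl + ik + cell$g_leak * v
  }, c(mV(-67.9), mV(9.9)), tol = 1e-12)$root
  expect_equal(utils::tail(sim$v, 1), target, tolerance = 1e-4)
})

test_that("membrane voltage stays within the reversal-potential bounds", {
  cell <- canonical_cell()
  stim <- make_naturalistic_conductance(duration = 2, mean_level = nS(20),
                                        contrast = 1, seed = 5)
  sim <- simulate_current_clamp(cell, stim)
  expect_true(all(sim$v >= mV(-68) - 1e-9))
  expect_true(all(sim$v <= mV(10) + 1e-9))
})

test_that("current-clamp runs conserve charge at every sample", {
  cell <- canonical_cell()
  stim <- make_naturalistic_conductance(duration = 2, seed = 42)
  sim <- simulate_current_clamp(cell, stim)
  i_tot <- sim$i_light + sim$i_kdr + sim$i_ka + sim$i_leak
  dvdt <- diff(sim$v) / diff(sim$time)
  mid <- (i_tot[-1] + i_tot[-length(i_tot)]) / 2
  resid <- cell$capacitance * dvdt + mid
  # finite-difference residual well below the nA scale of the currents
  expect_lt(max(abs(resid)), 5e-12)
})

test_that("subtraction protocol isolates the transient current", {
  vc <- validation_cell()
  sub <- simulate_subtraction_protocol(vc, test_levels = mV(3),
                                       sample_interval = 5e-5)
  # the model's true KA transient peaks near 1 nA about 2.2 ms after the
  # step; semi-analytic oracle maximizes G a(t)^2 h(t) (V - E_K)
  ka <- vc$conductances$KA
  aI <- photoKv:::.gate_steady(ka$activation, mV(3))
  a0 <- photoKv:::.gate_steady(ka$activation, mV(-117))
  hI <- photoKv:::.gate_steady(ka$inactivation, mV(3))
  h0 <- photoKv:::.gate_steady(ka$inactivation, mV(-117))
  ti <- bell_time_constant(ka$inactivation, mV(3))
  oracle <- optimize(function(t) {
    a <- aI - (aI - a0) * exp(-t / ms(1.5))
    h <- hI + (h0 - hI) * exp(-t / ti)
    ka$g_max * a^2 * h * (mV(3) - ka$e_rev)
  }, c(0, 0.05), maximum = TRUE)
  pk <- which.max(sub$ka_true$i)
  expect_equal(sub$ka_true$i[pk], oracle$objective, tolerance = 0.01)
  expect_equal(sub$ka_true$t_step[pk], oracle$maximum, tolerance = 0.1)
  # transient family decays back to baseline beyond 10 inactivation taus
  late <- sub$transient$t_step > 10 * ti
  expect_lt(abs(mean(sub$transient$i[late])), 0.01 * max(sub$transient$i))
  # without a transient conductance the subtraction vanishes over the
  # shared test step (the prepulse epochs differ by construction)
  ka_only <- cell_parameters(
    pF(380), conductances = list(vc$conductances$KA), g_leak = nS(0.9))
  sub0 <- simulate_subtraction_protocol(
    scale_conductance(ka_only, "KA", 0), test_levels = mV(3))
  on_step <- sub0$transient$t_step >= 0
  expect_true(all(abs(sub0$transient$i[on_step]) < 1e-15))
})

test_that("matched-history subtraction recovers the true KA current", {
  # total from the full cell, sustained from the same cell with the
  # transient conductance removed, identical prepulse history: the
  # isolation an experimenter cannot do but the simulator can
  vc <- validation_cell()
  prot <- voltage_protocol(
    tibble::tibble(level = mV(c(-117, 3)), duration = c(0.5, 0.05)),
    holding = mV(-60), sample_interval = 5e-5)
  total <- simulate_voltage_clamp(vc, prot)
  sustained <- simulate_voltage_clamp(scale_conductance(vc, "KA", 0), prot)
  iso <- isolate_transient_current(
    tibble::tibble(time = total$time, current = total$i_total),
    tibble::tibble(time = sustained$time, current = sustained$i_total))
  err <- max(abs(iso$current - total$i_ka))
  expect_lt(err, 0.02 * max(total$i_ka))
})

test_that("conductance scaling: KDR sets the depolarization level", {
  cell <- canonical_cell()
  stim <- make_naturalistic_conductance(duration = 2, seed = 42)
  kdr <- conductance_scaling_experiment(cell, stim, "KDR",
                                        scales = c(0.1, 1, 10))
  # more delayed rectifier, less depolarization - strictly monotone
  expect_true(all(diff(kdr$summary$v_mean_late) < 0))
  # identical scales produce identical traces
  same <- conductance_scaling_experiment(
    cell, constant_stim(nS(5), duration = 0.2), "KA", scales = c(1, 1))
  expect_equal(same$max_deviation, 0)
})

test_that("KA currents stay small under naturalistic stimulation", {
  cell <- canonical_cell()
  stim <- make_naturalistic_conductance(duration = 2, seed = 42)
  sim <- simulate_current_clamp(cell, stim)
  expect_lt(max(abs(sim$i_ka)) / max(abs(sim$i_kdr)), 0.1)
})

test_that("protocol and stimulus validation rejects malformed input", {
  expect_error(voltage_protocol(tibble::tibble(level = mV(-50),
                                               duration = -1),
                                holding = mV(-60)), "positive")
  expect_error(stimulus_waveform(c(0, 1e-3, 3e-3), rep(0, 3)), "uniform")
  expect_error(stimulus_waveform(c(0, 1e-3), c(-1e-9, 0)), "non-negative")
  cell <- canonical_cell()
  expect_error(scale_conductance(cell, "KX", 1), "No conductance")
  expect_error(scale_conductance(cell, "KA", -1), "non-negative")
})
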