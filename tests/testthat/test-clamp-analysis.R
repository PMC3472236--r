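test_that("series-resistance correction follows Ohm's law above threshold", {
  tr <- tibble::tibble(time = c(0, 1e-3, 2e-3),
                       current = pA(c(500, 100, -500)))
  out <- correct_series_resistance(tr, rs = Mohm(5), command = mV(-20))
  # 500 pA across 5 Mohm drops 2.5 mV
  expect_equal(out$v_effective[1], mV(-20) - mV(2.5))
  expect_equal(out$v_effective[3], mV(-20) + mV(2.5))
  # sub-threshold samples are left at the command
  expect_equal(out$v_effective[2], mV(-20))
  # zero residual resistance is the identity
  id <- correct_series_resistance(tr, rs = 0, command = mV(-20))
  expect_true(all(id$v_effective == mV(-20)))
  expect_error(correct_series_resistance(
    tibble::tibble(time = 0, voltage = 1), rs = 0, command = 0),
    "current trace")
})

test_that("conductance extraction divides by the driving force", {
  # -100 pA at -74 mV against a +10 mV reversal: driving force -84 mV
  expect_equal(conductance_from_current(pA(-100), mV(-74), mV(10)) * 1e9,
               1.19048, tolerance = 1e-5)
  expect_equal(conductance_from_current(0, mV(-40), mV(-68)), 0)
  # outward current above the reversal potential: positive conductance
  expect_gt(conductance_from_current(pA(200), mV(-40), mV(-68)), 0)
  expect_error(conductance_from_current(pA(1), mV(-68), mV(-68)), "driving")
  # inverse of the current model: g o (I = g (V - E)) is the identity
  g <- nS(7.3)
  expect_equal(conductance_from_current(g * (mV(-30) - mV(-68)),
                                        mV(-30), mV(-68)), g)
})

test_that("Boltzmann fits recover noiseless curves exactly", {
  vs <- mV(seq(-47, 23, by = 10))
  g1 <- nS(78) * boltzmann_steady_state(kdr_gate, vs)
  f1 <- fit_boltzmann(tibble::tibble(voltage = vs, conductance = g1),
                      order = 1)
  expect_true(f1$converged)
  expect_equal(fit_estimate(f1, "v50"), mV(-31), tolerance = 1e-8)
  expect_equal(fit_estimate(f1, "slope"), mV(12), tolerance = 1e-8)
  expect_equal(fit_estimate(f1, "g_max"), nS(78), tolerance = 1e-8)
  expect_lt(glance(f1)$rss, 1e-30)
  # second order: fitted v50 is not the half-maximum voltage
  vs2 <- mV(seq(-57, 3, by = 10))
  g2 <- nS(36) * boltzmann_steady_state(ka_act_gate, vs2)
  f2 <- fit_boltzmann(tibble::tibble(voltage = vs2, conductance = g2),
                      order = 2)
  expect_equal(fit_estimate(f2, "v50"), mV(-43), tolerance = 1e-8)
  half_v <- uniroot(function(v) {
    boltzmann_steady_state(ka_act_gate, v) - 0.5
  }, mV(c(-60, 0)))$root
  expect_gt(half_v, fit_estimate(f2, "v50"))
  # negative-slope inactivation curve
  vs3 <- mV(seq(-130, -40, by = 10))
  g3 <- boltzmann_steady_state(ka_inact_gate, vs3)
  f3 <- fit_boltzmann(tibble::tibble(voltage = vs3, conductance = g3),
                      order = 1)
  expect_equal(fit_estimate(f3, "v50"), mV(-85), tolerance = 1e-8)
  expect_equal(fit_estimate(f3, "slope"), mV(-11.3), tolerance = 1e-8)
  expect_error(fit_boltzmann(tibble::tibble(voltage = vs[1:3],
                                            conductance = g1[1:3])),
               "4 points")
})

test_that("Boltzmann fits recover truth from noisy multi-cell data", {
  ds <- make_activation_dataset(kdr_gate, nS(78), mV(seq(-47, 23, 10)),
                                n_cells = 6, noise_frac = 0.05, seed = 21)
  v50s <- vapply(unique(ds$cell), function(k) {
    fit_estimate(fit_boltzmann(ds[ds$cell == k, ], order = 1), "v50")
  }, numeric(1))
  # within twice the reported between-cell SE of the half-activation
  expect_lt(abs(median(v50s) - mV(-31)), 2 * mV(9) / sqrt(6))
  ds2 <- make_activation_dataset(ka_inact_gate, 1, mV(seq(-130, -40, 10)),
                                 n_cells = 4, noise_frac = 0.03,
                                 cell_cv = 0, seed = 22)
  v50s2 <- vapply(unique(ds2$cell), function(k) {
    fit_estimate(fit_boltzmann(ds2[ds2$cell == k, ], order = 1), "v50")
  }, numeric(1))
  expect_lt(abs(median(v50s2) - mV(-85)), 2 * mV(1) / sqrt(4))
})

test_that("exponential relaxation fits", {
  tm <- seq(0, 0.1, by = 1e-4)
  y <- pA(200) + pA(300) * exp(-tm / ms(15))
  f <- fit_exponential_relaxation(tibble::tibble(time = tm, value = y))
  expect_equal(fit_estimate(f, "tau"), ms(15), tolerance = 1e-8)
  expect_equal(fit_estimate(f, "amplitude"), pA(300), tolerance = 1e-8)
  # simulated delayed-rectifier activation at -43 mV relaxes with the
  # bell-law time constant (first-order gate -> exponential current)
  cell <- canonical_cell(calibrated = FALSE)
  cell$g_leak <- 0
  prot <- voltage_protocol(
    tibble::tibble(level = mV(-43), duration = 0.12),
    holding = mV(-90), sample_interval = 1e-4)
  sim <- simulate_voltage_clamp(cell, prot)
  fa <- fit_exponential_relaxation(
    tibble::tibble(time = sim$time, value = sim$i_kdr))
  expect_equal(fit_estimate(fa, "tau") * 1e3, REF$tau_kdr_m43_ms,
               tolerance = 1e-3)
  # flat segments are flagged rather than inventing a time constant
  flat <- fit_exponential_relaxation(
    tibble::tibble(time = tm, value = rep(pA(100), length(tm))))
  expect_true(length(flat$flags) > 0)
})

test_that("pulse-function fits recover transient kinetics", {
  tm <- seq(0, 0.08, by = 5e-5)
  ip <- pA(500) * (1 - exp(-tm / ms(1.5)))^2 * exp(-tm / ms(20))
  f <- fit_pulse_function(tibble::tibble(time = tm, current = ip))
  expect_true(f$converged)
  expect_equal(fit_estimate(f, "i_max"), pA(500), tolerance = 1e-6)
  expect_equal(fit_estimate(f, "tau_act"), ms(1.5), tolerance = 1e-6)
  expect_equal(fit_estimate(f, "tau_inact"), ms(20), tolerance = 1e-6)
  # fitted peak time agrees with a 1-D optimization oracle on the shape
  oracle <- optimize(function(t) {
    (1 - exp(-t / ms(1.5)))^2 * exp(-t / ms(20))
  }, c(0, 0.05), maximum = TRUE)$maximum
  fitted_peak <- optimize(f$fitted_fn, c(0, 0.05), maximum = TRUE)$maximum
  expect_equal(fitted_peak, oracle, tolerance = 1e-4)
  # sustained-only segments are flagged
  sus <- fit_pulse_function(tibble::tibble(
    time = tm, current = pA(400) * (1 - exp(-tm / ms(5)))))
  expect_true("sustained-only" %in% sus$flags)
  # Monte-Carlo: inactivation tau nearly unbiased at bench-like noise
  taus <- withr::with_seed(31, {
    vapply(1:20, function(i) {
      noisy <- ip + rnorm(length(ip), 0, pA(5))
      fit_estimate(fit_pulse_function(
        tibble::tibble(time = tm, current = noisy)), "tau_inact")
    }, numeric(1))
  })
  expect_lt(abs(median(taus) - ms(20)) / ms(20), 0.05)
})

test_that("bell-function fits recover the time-constant law", {
  vs <- mV(seq(-80, 0, by = 5))
  taus <- bell_time_constant(kdr_gate, vs)
  f <- fit_bell_time_constant(tibble::tibble(voltage = vs, tau = taus))
  expect_equal(fit_estimate(f, "alpha"), 4, tolerance = 1e-6)
  expect_equal(fit_estimate(f, "beta"), 156, tolerance = 1e-6)
  expect_equal(fit_estimate(f, "tau_slope"), 43, tolerance = 1e-6)
  peak <- log(fit_estimate(f, "alpha") / fit_estimate(f, "beta")) /
    (2 * fit_estimate(f, "tau_slope"))
  expect_equal(peak * 1e3, REF$bell_peak_mV, tolerance = 1e-4)
  # noisy inactivation data still pin the -70 mV time constant
  vsi <- mV(seq(-110, -20, by = 10))
  ti <- bell_time_constant(ka_inact_gate, vsi)
  noisy <- withr::with_seed(13, ti * (1 + rnorm(length(ti), 0, 0.05)))
  fi <- fit_bell_time_constant(tibble::tibble(voltage = vsi, tau = noisy))
  expect_lt(abs(fi$fitted_fn(mV(-70)) * 1e3 - REF$tau_ka_inact_m70_ms) /
              REF$tau_ka_inact_m70_ms, 0.10)
  # monotone data: peak outside the sampled range is flagged, fit returned
  vm <- mV(seq(-80, -30, by = 10))
  fm <- fit_bell_time_constant(tibble::tibble(
    voltage = vm, tau = bell_time_constant(ka_inact_gate, vm)))
  expect_true(fm$converged)
  expect_error(fit_bell_time_constant(tibble::tibble(
    voltage = vs[1:4], tau = taus[1:4])), "5 points")
})

test_that("transient-current subtraction is a pointwise difference", {
  tm <- seq(0, 0.05, by = 1e-4)
  a <- tibble::tibble(time = tm, current = sin(tm * 100) * 1e-9)
  z <- isolate_transient_current(a, a)
  expect_true(all(z$current == 0))
  b <- tibble::tibble(time = tm + 1e-3, current = a$current)
  expect_error(isolate_transient_current(a, b), "grids")
  # cross-check against the simulator's own subtraction family
  vc <- validation_cell()
  sub <- simulate_subtraction_protocol(vc, test_levels = mV(3))
  iso <- isolate_transient_current(
    tibble::tibble(time = sub$total$time, current = sub$total$i_total),
    tibble::tibble(time = sub$sustained$time,
                   current = sub$sustained$i_total))
  expect_equal(iso$current, sub$transient$i)
})

test_that("tail amplitudes are measured by exponential extrapolation", {
  tm <- seq(0.1, 0.2, by = 1e-4)
  base <- pA(-40)
  tail_tr <- tibble::tibble(
    time = tm, current = base + pA(300) * exp(-(tm - 0.1) / ms(8)))
  amp <- measure_tail_amplitude(tail_tr, at = 0.1)
  expect_equal(amp, pA(300), tolerance = 0.01)
  # the fixed-latency read underestimates a decaying tail
  amp_fl <- measure_tail_amplitude(tail_tr, at = 0.1,
                                   method = "fixed_latency",
                                   latency = ms(2))
  expect_lt(abs(amp_fl), abs(amp))
  # a tail at the reversal potential has no deactivating component
  flat <- tibble::tibble(time = tm, current = rep(base, length(tm)))
  expect_error(measure_tail_amplitude(flat, at = 0.3), "outside")
})

test_that("reversal potential from tail families", {
  # amplitudes exactly linear through (-68 mV, 0)
  vs <- mV(seq(-100, -40, by = 10))
  amp <- nS(10) * (vs - mV(-68))
  f <- estimate_reversal_potential(tibble::tibble(voltage = vs,
                                                  amplitude = amp))
  expect_equal(fit_estimate(f, "e_rev"), mV(-68), tolerance = 1e-10)
  # a constant offset shifts the crossing by -offset/slope
  off <- pA(50)
  f2 <- estimate_reversal_potential(tibble::tibble(voltage = vs,
                                                   amplitude = amp + off))
  expect_equal(fit_estimate(f2, "e_rev"), mV(-68) - off / nS(10),
               tolerance = 1e-10)
  # synthetic family generated at -68 mV is recovered within a millivolt
  fam <- make_tail_family(concentrations = 5, n_cells = 8,
                          sd_e_rev = mV(1), seed = 17)
  f3 <- estimate_reversal_potential(fam)
  expect_lt(abs(fit_estimate(f3, "e_rev") - mV(-68)), mV(1))
  # no sign change: flagged as extrapolation
  f4 <- estimate_reversal_potential(tibble::tibble(
    voltage = vs[1:3], amplitude = abs(amp[1:3]) + pA(10)))
  expect_true("extrapolated" %in% f4$flags)
})

test_that("Nernst-relation fits", {
  conc <- c(5, 15, 25, 50)
  ideal <- nernst_potential(140, conc, 1, 293.15)
  f <- fit_nernst_relation(tibble::tibble(concentration = conc,
                                          e_rev = ideal))
  expect_equal(fit_estimate(f, "slope_per_decade") * 1e3,
               REF$slope_decade_mV, tolerance = 1e-6)
  # duplicating points leaves the slope unchanged
  f2 <- fit_nernst_relation(tibble::tibble(
    concentration = rep(conc, 2), e_rev = rep(ideal, 2)))
  expect_equal(fit_estimate(f2, "slope_per_decade"),
               fit_estimate(f, "slope_per_decade"))
  # synthetic reversal potentials built on the measured 52 mV/decade
  fam <- make_tail_family(seed = 29)
  revs <- purrr::map_dfr(unique(fam$concentration), function(cc) {
    ff <- estimate_reversal_potential(fam[fam$concentration == cc, ])
    tibble::tibble(concentration = cc, e_rev = fit_estimate(ff, "e_rev"))
  })
  fn <- fit_nernst_relation(revs)
  expect_lt(abs(fit_estimate(fn, "slope_per_decade") - mV(52)),
            2 * fit_se(fn, "slope_per_decade") + mV(4) * 2)
  expect_error(fit_nernst_relation(tibble::tibble(
    concentration = c(5, 5), e_rev = mV(c(-68, -68)))), "distinct")
})

test_that("dose-response fits recover the logistic block curve", {
  d <- c(1, 3, 10, 30, 100, 300, 1000) * 1e-6
  r <- 1 / (1 + (d / 32e-6)^0.97)
  f <- fit_dose_response(tibble::tibble(dose = d, response = r))
  expect_equal(fit_estimate(f, "ic50"), 32e-6, tolerance = 1e-6)
  expect_equal(fit_estimate(f, "hill"), 0.97, tolerance = 1e-6)
  # model value at the half-inhibition concentration is one half
  expect_equal(f$fitted_fn(fit_estimate(f, "ic50")), 0.5)
  # closed form at 10x IC50 with unit Hill coefficient
  f1 <- fit_dose_response(tibble::tibble(
    dose = d, response = 1 / (1 + d / 32e-6)))
  expect_equal(f1$fitted_fn(10 * fit_estimate(f1, "ic50")), 1 / 11,
               tolerance = 1e-6)
  # noisy replicate data: recovery within twice the reported SE
  ds <- make_dose_response_dataset(seed = 37)
  fn <- fit_dose_response(ds)
  expect_lt(abs(fit_estimate(fn, "ic50") - 32e-6), 2 * 3e-6)
  # saturated designs are flagged
  sat <- fit_dose_response(tibble::tibble(
    dose = d[1:4] / 1e3, response = c(0.99, 1.0, 0.98, 1.01)))
  expect_true("all-saturated" %in% sat$flags)
})

test_that("test-pulse passive properties are recovered", {
  r_a <- Mohm(10); r_in <- Mohm(1000); cm <- pF(380); dv <- mV(-10)
  tau <- cm * r_a * r_in / (r_a + r_in)
  tm <- seq(0, 0.05, by = 1e-5)
  i_ss <- dv / (r_a + r_in)
  tr <- tibble::tibble(
    time = tm, current = i_ss + (dv / r_a - i_ss) * exp(-tm / tau))
  pp <- passive_properties_from_test_pulse(tr, dv)
  expect_false(pp$flagged)
  expect_equal(pp$r_access, r_a, tolerance = 0.02)
  expect_equal(pp$r_input, r_in, tolerance = 0.02)
  expect_equal(pp$capacitance, cm, tolerance = 0.02)
  # estimates are invariant to the step size (linearity)
  tr2 <- tibble::tibble(time = tm, current = tr$current / 2)
  pp2 <- passive_properties_from_test_pulse(tr2, dv / 2)
  expect_equal(pp2$r_access, pp$r_access, tolerance = 1e-6)
  expect_equal(pp2$capacitance, pp$capacitance, tolerance = 1e-6)
  # no resolvable transient: input resistance only, capacitance flagged
  flat <- tibble::tibble(time = tm, current = rep(i_ss, length(tm)))
  ppf <- passive_properties_from_test_pulse(flat, dv)
  expect_true(ppf$flagged)
  expect_true(is.na(ppf$capacitance))
  expect_equal(ppf$r_input, r_a + r_in, tolerance = 1e-6)
})

test_that("fit objects expose broom-style summaries", {
  vs <- mV(seq(-47, 23, by = 10))
  g <- nS(78) * boltzmann_steady_state(kdr_gate, vs)
  f <- fit_boltzmann(tibble::tibble(voltage = vs, conductance = g))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$nobs, length(vs))
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
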