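#' Offline series-resistance correction
#'
#' The access (series) resistance drops part of the command voltage whenever
#' current flows: the membrane actually sees \eqn{V_{cmd} - I R_s}. Whole
#' traces are corrected offline, but only samples whose current exceeds the
#' threshold (default 200 pA) are adjusted; smaller currents leave a voltage
#' error below the measurement noise.
#'
#' @param data Current trace: tibble with columns `time` (s) and
#'   `current` (A).
#' @param rs Residual access resistance after compensation (ohm),
#'   non-negative.
#' @param command Command voltage (V): a scalar or a per-sample vector.
#' @param threshold Absolute current above which the correction is applied
#'   (A).
#' @return The input tibble with an added `v_effective` column.
#' @export
correct_series_resistance <- function(data, rs, command,
                                      threshold = pA(200)) {
  data <- as_tibble(data)
  if (!all(c("time", "current") %in% names(data))) {
    abort("`data` must be a current trace with columns `time` and `current`.")
  }
  .check_number(rs, "rs")
  if (rs < 0) abort("`rs` must be non-negative.")
  command <- rep_len(command, nrow(data))
  adjust <- abs(data$current) > threshold
  data$v_effective <- command - ifelse(adjust, data$current * rs, 0)
  data
}

#' Conductance from current and driving force
#'
#' \eqn{g = I / (V - E_{rev})}. An outward (positive) current above the
#' reversal potential, or an inward current below it, gives a positive
#' conductance.
#'
#' @param i Current (A).
#' @param v Membrane voltage (V).
#' @param e_rev Reversal potential (V).
#' @return Conductance (S).
#' @export
conductance_from_current <- function(i, v, e_rev) {
  .check_number(i, "i")
  .check_number(v, "v")
  .check_number(e_rev, "e_rev")
  if (any(v == e_rev)) {
    abort("Zero driving force: `v` equals `e_rev`.")
  }
  i / (v - e_rev)
}

#' Fit a Boltzmann steady-state curve
#'
#' Least-squares fit of \eqn{g(V) = g_{max} / (1 + e^{(V_{50}-V)/s})^P}
#' for fixed order `P`. For P = 1 the fitted \eqn{V_{50}} is the
#' half-maximum voltage; for P = 2 it is not (the half-point of the squared
#' curve sits depolarized of \eqn{V_{50}}). A negative fitted slope
#' describes an inactivation curve. The `conductance` column may hold any
#' amplitude measure on the Boltzmann shape (peak conductance, normalized
#' peak current, ...).
#'
#' @param data Tibble with columns `voltage` (V) and `conductance`.
#' @param order Boltzmann order `P` (positive integer), held fixed.
#' @return A [`kv_fit`][tidy.kv_fit] with terms `g_max`, `v50`, `slope`.
#'   Flags: `slope-sign-flip` when the fitted slope sign contradicts the
#'   data trend.
#' @export
fit_boltzmann <- function(data, order = 1) {
  data <- as_tibble(data)
  if (!all(c("voltage", "conductance") %in% names(data))) {
    abort("`data` needs columns `voltage` and `conductance`.")
  }
  d <- tibble(v = data$voltage, g = data$conductance)
  n <- nrow(d)
  if (n < 4) abort("Need at least 4 points spanning the rise.")
  increasing <- stats::cor(d$v, d$g) >= 0
  sgn <- if (increasing) 1 else -1
  gmax0 <- max(d$g) * 1.02
  target <- gmax0 * 2^(-order)
  ix <- order(d$v)
  v50_0 <- tryCatch(
    stats::approx(d$g[ix], d$v[ix], xout = target, ties = mean)$y,
    warning = function(w) NA_real_, error = function(e) NA_real_)
  if (!is.finite(v50_0)) v50_0 <- stats::median(d$v)
  slope0 <- sgn * diff(range(d$v)) / 4
  ord <- order
  res <- .try_nlsLM(
    g ~ gmax / (1 + exp((v50 - v) / slope))^ord,
    data = d,
    start = list(gmax = gmax0, v50 = v50_0, slope = slope0),
    lower = c(gmax = 0, v50 = -Inf, slope = -Inf)
  )
  label <- sprintf("Boltzmann (order %d)", order)
  if (!res$ok) {
    return(.failed_fit(label, c("g_max", "v50", "slope"), data, n,
                       res$error))
  }
  fit <- res$fit
  est <- .nls_estimates(fit)
  est$term <- c("g_max", "v50", "slope")
  cf <- coef(fit)
  flags <- character()
  if (sign(cf[["slope"]]) != sgn) flags <- c(flags, "slope-sign-flip")
  new_kv_fit(
    label, est, rss = sum(stats::resid(fit)^2), converged = TRUE,
    flags = flags, cov = vcov(fit),
    fitted_fn = function(v) {
      cf[["gmax"]] / (1 + exp((cf[["v50"]] - v) / cf[["slope"]]))^ord
    },
    data = data[c("voltage", "conductance")], n = n
  )
}

#' Fit a single-exponential relaxation
#'
#' \eqn{y(t) = y_\infty + A\, e^{-t/\tau}} with `t` measured from the start
#' of the segment (the epoch transition). Used for activating currents and
#' deactivating tail currents.
#'
#' @param data Tibble with columns `time` (s) and `value`; time need not
#'   start at zero (it is re-based internally).
#' @return A [`kv_fit`][tidy.kv_fit] with terms `offset`, `amplitude`,
#'   `tau`. Flags: `amplitude-negligible` when the relaxing component is
#'   indistinguishable from noise (tau is then unidentifiable).
#' @export
fit_exponential_relaxation <- function(data) {
  data <- as_tibble(data)
  if (!all(c("time", "value") %in% names(data))) {
    abort("`data` needs columns `time` and `value`.")
  }
  n <- nrow(data)
  if (n < 4) abort("Need at least 4 samples.")
  t0 <- data$time[1]
  d <- tibble(t = data$time - t0, y = data$value)
  n_tail <- max(3L, ceiling(n / 5))
  offset0 <- mean(d$y[(n - n_tail + 1):n])
  amp0 <- d$y[1] - offset0
  span <- diff(range(d$t))
  tau0 <- span / 3
  if (abs(amp0) > 0) {
    yy <- (d$y - offset0) / amp0
    below <- which(yy <= exp(-1))
    if (length(below) > 0 && below[1] > 1) tau0 <- d$t[below[1]]
  }
  res <- .try_nlsLM(
    y ~ offset + amplitude * exp(-t / tau),
    data = d,
    start = list(offset = offset0, amplitude = amp0,
                 tau = max(tau0, span / 100)),
    lower = c(offset = -Inf, amplitude = -Inf, tau = span * 1e-6)
  )
  label <- "single exponential"
  if (!res$ok) {
    return(.failed_fit(label, c("offset", "amplitude", "tau"), data, n,
                       res$error))
  }
  fit <- res$fit
  est <- .nls_estimates(fit)
  cf <- coef(fit)
  rss <- sum(stats::resid(fit)^2)
  sigma <- sqrt(rss / max(1, n - 3))
  flags <- character()
  if (abs(cf[["amplitude"]]) < 2 * sigma ||
      (sigma == 0 && cf[["amplitude"]] == 0)) {
    flags <- c(flags, "amplitude-negligible")
  }
  new_kv_fit(
    label, est, rss = rss, converged = TRUE, flags = flags,
    cov = vcov(fit),
    fitted_fn = function(t) {
      cf[["offset"]] + cf[["amplitude"]] * exp(-(t - t0) / cf[["tau"]])
    },
    data = data[c("time", "value")], n = n
  )
}

#' Fit the pulse function to a transient current
#'
#' The m^2 h transient shape
#' \deqn{I(t) = I_{max}\,(1 - e^{-t/\tau_{act}})^2\, e^{-t/\tau_{inact}}}
#' (second-order activation, first-order inactivation), fitted to a
#' subtraction-protocol current segment starting at the step onset.
#'
#' @param data Tibble with columns `time` (s, from step onset or re-based
#'   internally) and `current` (A).
#' @return A [`kv_fit`][tidy.kv_fit] with terms `i_max`, `tau_act`,
#'   `tau_inact`. Flags: `sustained-only` when the segment shows no interior
#'   peak with subsequent decay.
#' @export
fit_pulse_function <- function(data) {
  data <- as_tibble(data)
  if (!all(c("time", "current") %in% names(data))) {
    abort("`data` needs columns `time` and `current`.")
  }
  n <- nrow(data)
  if (n < 6) abort("Need at least 6 samples.")
  t0 <- data$time[1]
  d <- tibble(t = data$time - t0, i = data$current)
  ipk_ix <- which.max(abs(d$i))
  ipk <- d$i[ipk_ix]
  tp <- d$t[ipk_ix]
  flags <- character()
  late <- abs(d$i[n])
  if (ipk_ix >= n - 1 || late > 0.9 * abs(ipk)) {
    flags <- c(flags, "sustained-only")
  }
  span <- diff(range(d$t))
  # crude decay time constant from the post-peak fall
  tau_i0 <- span / 4
  if (ipk_ix < n) {
    post <- d[ipk_ix:n, ]
    rel <- abs(post$i) / abs(ipk)
    below <- which(rel <= exp(-1))
    if (length(below) > 0 && below[1] > 1) {
      tau_i0 <- post$t[below[1]] - tp
    }
  }
  tau_a0 <- max(tp / 3, span / 200)
  res <- .try_nlsLM(
    i ~ imax * (1 - exp(-t / tau_act))^2 * exp(-t / tau_inact),
    data = d,
    start = list(imax = ipk * exp(tp / max(tau_i0, 1e-9)) /
                   max((1 - exp(-tp / tau_a0))^2, 0.1),
                 tau_act = tau_a0, tau_inact = max(tau_i0, 1e-9)),
    lower = c(imax = -Inf, tau_act = span * 1e-6, tau_inact = span * 1e-6)
  )
  label <- "pulse function (m^2 h)"
  if (!res$ok) {
    return(.failed_fit(label, c("i_max", "tau_act", "tau_inact"), data, n,
                       res$error))
  }
  fit <- res$fit
  est <- .nls_estimates(fit)
  est$term <- c("i_max", "tau_act", "tau_inact")
  cf <- coef(fit)
  new_kv_fit(
    label, est, rss = sum(stats::resid(fit)^2), converged = TRUE,
    flags = flags, cov = vcov(fit),
    fitted_fn = function(t) {
      tt <- t - t0
      cf[["imax"]] * (1 - exp(-tt / cf[["tau_act"]]))^2 *
        exp(-tt / cf[["tau_inact"]])
    },
    data = data[c("time", "current")], n = n
  )
}

#' Fit the bell-function time-constant law
#'
#' Least squares on
#' \eqn{\tau(V) = 1/(\alpha e^{-s_\tau V} + \beta e^{s_\tau V}) + \tau_0}
#' over (voltage, time-constant) points; \eqn{\tau_0} is fixed at zero by
#' default (the registry convention) but can be freed.
#'
#' @param data Tibble with columns `voltage` (V) and `tau` (s).
#' @param fix_tau0 If `TRUE` (default) fit with \eqn{\tau_0 = 0}.
#' @return A [`kv_fit`][tidy.kv_fit] with terms `alpha`, `beta`,
#'   `tau_slope` (and `tau0` when freed). Flags: `peak-outside-range` when
#'   the fitted bell peak falls outside the data's voltage range (monotone
#'   tau-V data); the fit is still returned.
#' @export
fit_bell_time_constant <- function(data, fix_tau0 = TRUE) {
  data <- as_tibble(data)
  if (!all(c("voltage", "tau") %in% names(data))) {
    abort("`data` needs columns `voltage` and `tau`.")
  }
  n <- nrow(data)
  if (n < 5) abort("Need at least 5 points.")
  d <- tibble(v = data$voltage, tau = data$tau)
  tmax <- max(d$tau)
  vstar <- d$v[which.max(d$tau)]
  s0 <- 40
  a0 <- exp(s0 * vstar) / (2 * tmax)
  b0 <- exp(-s0 * vstar) / (2 * tmax)
  if (fix_tau0) {
    res <- .try_nlsLM(
      tau ~ 1 / (alpha * exp(-s * v) + beta * exp(s * v)),
      data = d, start = list(alpha = a0, beta = b0, s = s0),
      lower = c(alpha = 1e-12, beta = 1e-12, s = -Inf)
    )
    terms <- c("alpha", "beta", "tau_slope")
  } else {
    res <- .try_nlsLM(
      tau ~ 1 / (alpha * exp(-s * v) + beta * exp(s * v)) + tau0,
      data = d, start = list(alpha = a0, beta = b0, s = s0, tau0 = 0),
      lower = c(alpha = 1e-12, beta = 1e-12, s = -Inf, tau0 = 0)
    )
    terms <- c("alpha", "beta", "tau_slope", "tau0")
  }
  label <- "bell time constant"
  if (!res$ok) return(.failed_fit(label, terms, data, n, res$error))
  fit <- res$fit
  est <- .nls_estimates(fit)
  est$term <- terms
  cf <- coef(fit)
  peak <- log(cf[["alpha"]] / cf[["beta"]]) / (2 * cf[["s"]])
  flags <- character()
  if (peak < min(d$v) || peak > max(d$v)) {
    flags <- c(flags, "peak-outside-range")
  }
  tau0 <- if (fix_tau0) 0 else cf[["tau0"]]
  new_kv_fit(
    label, est, rss = sum(stats::resid(fit)^2), converged = TRUE,
    flags = flags, cov = vcov(fit),
    fitted_fn = function(v) {
      1 / (cf[["alpha"]] * exp(-cf[["s"]] * v) +
             cf[["beta"]] * exp(cf[["s"]] * v)) + tau0
    },
    data = data[c("voltage", "tau")], n = n
  )
}

#' Isolate the transient current by subtraction
#'
#' Pointwise difference of a total-current trace (inactivation-removing
#' prepulse) and a sustained-current trace (inactivating prepulse) on an
#' identical grid: the experimental isolation of the transient A-type
#' current.
#'
#' @param total,sustained Tibbles with columns `time` and `current`, on
#'   identical grids (and identical `step` columns if present).
#' @return A tibble with columns `time` and `current` (the transient).
#' @export
isolate_transient_current <- function(total, sustained) {
  total <- as_tibble(total)
  sustained <- as_tibble(sustained)
  for (d in list(total, sustained)) {
    if (!all(c("time", "current") %in% names(d))) {
      abort("Traces need columns `time` and `current`.")
    }
  }
  if (nrow(total) != nrow(sustained) ||
      max(abs(total$time - sustained$time)) > 1e-12) {
    abort("Trace grids do not match.")
  }
  if ("step" %in% names(total) && "step" %in% names(sustained) &&
      !isTRUE(all.equal(total$step, sustained$step))) {
    abort("Step levels do not match.")
  }
  out <- tibble(time = total$time,
                current = total$current - sustained$current)
  if ("step" %in% names(total)) out$step <- total$step
  out
}

#' Measure a tail-current amplitude
#'
#' After repolarization the deactivating channels carry a tail current that
#' decays exponentially. The default method fits the decay and extrapolates
#' the deactivating component back to the repolarization instant, which is
#' unbiased by deactivation during the measurement latency; the
#' `fixed_latency` method instead reads the (baseline-subtracted) value at a
#' configured delay, as a faster but biased convention.
#'
#' @param data Tibble with columns `time` and `current`.
#' @param at Repolarization instant (s); must lie inside the trace.
#' @param method `"extrapolate"` (default) or `"fixed_latency"`.
#' @param latency Read delay for `fixed_latency` (s).
#' @param window Length of trace after `at` used for the fit (s); default
#'   uses everything.
#' @return Tail amplitude in amperes (the instantaneous deactivating
#'   component, baseline excluded).
#' @export
measure_tail_amplitude <- function(data, at,
                                   method = c("extrapolate",
                                              "fixed_latency"),
                                   latency = ms(1), window = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (!all(c("time", "current") %in% names(data))) {
    abort("`data` needs columns `time` and `current`.")
  }
  if (at < min(data$time) || at >= max(data$time)) {
    abort("No tail epoch: `at` is outside the trace.")
  }
  seg <- data[data$time >= at, ]
  if (!is.null(window)) seg <- seg[seg$time <= at + window, ]
  if (method == "extrapolate") {
    fit <- fit_exponential_relaxation(
      tibble(time = seg$time, value = seg$current))
    if (!fit$converged) abort("Tail exponential fit failed.")
    # amplitude term is the deactivating component at t = at
    fit_estimate(fit, "amplitude")
  } else {
    baseline <- mean(seg$current[seg$time >=
                                   stats::quantile(seg$time, 0.8)])
    ix <- which.min(abs(seg$time - (at + latency)))
    seg$current[ix] - baseline
  }
}

#' Reversal potential from a tail-current family
#'
#' Linear fit of tail amplitude against test voltage; the zero crossing is
#' the reversal potential. The standard error comes from the delta method on
#' the regression coefficients.
#'
#' @param data Tibble with columns `voltage` (V) and `amplitude` (A); one
#'   row per test voltage (replicates allowed).
#' @return A [`kv_fit`][tidy.kv_fit] with terms `e_rev`, `slope`
#'   (conductance, S). Flags: `extrapolated` when the amplitudes do not
#'   bracket zero.
#' @export
estimate_reversal_potential <- function(data) {
  data <- as_tibble(data)
  if (!all(c("voltage", "amplitude") %in% names(data))) {
    abort("`data` needs columns `voltage` and `amplitude`.")
  }
  n <- nrow(data)
  if (n < 2) abort("Need at least two test voltages.")
  fit <- lm(amplitude ~ voltage, data = data)
  cf <- coef(fit)
  V <- suppressWarnings(vcov(fit))  # zero-residual fits warn harmlessly
  e_rev <- -cf[[1]] / cf[[2]]
  # delta method on -a/b
  grad <- c(-1 / cf[[2]], cf[[1]] / cf[[2]]^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  slope_se <- sqrt(V[2, 2])
  flags <- character()
  if (min(data$amplitude) > 0 || max(data$amplitude) < 0) {
    flags <- c(flags, "extrapolated")
  }
  new_kv_fit(
    "tail reversal potential",
    tibble(term = c("e_rev", "slope"),
           estimate = c(e_rev, cf[[2]]),
           std.error = c(se, slope_se)),
    rss = sum(stats::resid(fit)^2), converged = TRUE, flags = flags,
    cov = V,
    fitted_fn = function(v) cf[[1]] + cf[[2]] * v,
    data = data[c("voltage", "amplitude")], n = n
  )
}

#' Fit the Nernst relation of reversal potentials
#'
#' Linear regression of reversal potential against log10 of the external
#' concentration. The slope has units of volts per tenfold concentration
#' change and is compared against the ideal [nernst_slope_per_decade()]
#' (about 58 mV/decade for potassium at room temperature); a shallower
#' slope indicates imperfect ionic selectivity.
#'
#' @param data Tibble with columns `concentration` (external, any unit,
#'   positive) and `e_rev` (V).
#' @return A [`kv_fit`][tidy.kv_fit] with terms `slope_per_decade` (V) and
#'   `intercept` (V at 1 concentration unit).
#' @export
fit_nernst_relation <- function(data) {
  data <- as_tibble(data)
  if (!all(c("concentration", "e_rev") %in% names(data))) {
    abort("`data` needs columns `concentration` and `e_rev`.")
  }
  if (any(data$concentration <= 0)) {
    abort("Concentrations must be positive.")
  }
  if (length(unique(data$concentration)) < 2) {
    abort("Need at least two distinct concentrations.")
  }
  d <- tibble(lc = log10(data$concentration), e = data$e_rev)
  fit <- lm(e ~ lc, data = d)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  new_kv_fit(
    "Nernst relation",
    tibble(term = c("slope_per_decade", "intercept"),
           estimate = c(cf["lc", "Estimate"],
                        cf["(Intercept)", "Estimate"]),
           std.error = c(cf["lc", "Std. Error"],
                         cf["(Intercept)", "Std. Error"])),
    rss = sum(stats::resid(fit)^2), converged = TRUE,
    cov = suppressWarnings(vcov(fit)),
    fitted_fn = function(conc) {
      coef(fit)[[1]] + coef(fit)[[2]] * log10(conc)
    },
    data = tibble(concentration = data$concentration, e_rev = data$e_rev),
    n = nrow(data)
  )
}

#' Fit a logistic dose-response (fractional block)
#'
#' \deqn{f(c) = \frac{1}{1 + (c / IC_{50})^{p}}}
#' fitted to fractional remaining current against blocker concentration;
#' `IC50` is the half-inhibition concentration and `p` the Hill coefficient.
#'
#' @param data Tibble with columns `dose` (concentration, positive) and
#'   `response` (fractional current, about 0-1).
#' @return A [`kv_fit`][tidy.kv_fit] with terms `ic50`, `hill`. Flags:
#'   `all-saturated` when the responses do not span the transition.
#' @export
fit_dose_response <- function(data) {
  data <- as_tibble(data)
  if (!all(c("dose", "response") %in% names(data))) {
    abort("`data` needs columns `dose` and `response`.")
  }
  if (any(data$dose <= 0)) abort("Doses must be positive.")
  n <- nrow(data)
  if (n < 4) abort("Need at least 4 points.")
  d <- tibble(c = data$dose, f = data$response)
  flags <- character()
  if (min(d$f) > 0.8 || max(d$f) < 0.2) flags <- c(flags, "all-saturated")
  mean_f <- tapply(d$f, d$c, mean)
  lcs <- log(as.numeric(names(mean_f)))
  ic0 <- tryCatch(
    exp(stats::approx(as.numeric(mean_f), lcs, xout = 0.5,
                      ties = mean)$y),
    warning = function(w) NA_real_, error = function(e) NA_real_)
  if (!is.finite(ic0)) ic0 <- exp(stats::median(lcs))
  res <- .try_nlsLM(
    f ~ 1 / (1 + (c / ic50)^p),
    data = d, start = list(ic50 = ic0, p = 1),
    lower = c(ic50 = min(d$c) * 1e-6, p = 1e-3)
  )
  label <- "logistic dose-response"
  if (!res$ok) {
    failed <- .failed_fit(label, c("ic50", "hill"), data, n, res$error)
    failed$flags <- c(flags, failed$flags)
    return(failed)
  }
  fit <- res$fit
  est <- .nls_estimates(fit)
  est$term <- c("ic50", "hill")
  cf <- coef(fit)
  new_kv_fit(
    label, est, rss = sum(stats::resid(fit)^2), converged = TRUE,
    flags = flags, cov = vcov(fit),
    fitted_fn = function(c) 1 / (1 + (c / cf[["ic50"]])^cf[["p"]]),
    data = data[c("dose", "response")], n = n
  )
}

#' Passive properties from a hyperpolarizing test pulse
#'
#' The test-pulse method: a small voltage step `step` across the
#' access-resistance/membrane RC circuit produces a current with
#' instantaneous peak \eqn{I_{peak} = \Delta V / R_a}, steady state
#' \eqn{I_{ss} = \Delta V / (R_a + R_{in})}, and a transient decaying with
#' \eqn{\tau = C\, R_a R_{in} / (R_a + R_{in})}. The transient is fitted
#' with a single exponential; the peak is the extrapolation to the step
#' onset.
#'
#' @param data Tibble with columns `time` (s, starting at the step onset)
#'   and `current` (A).
#' @param step Command voltage step (V), typically negative
#'   (hyperpolarizing).
#' @return One-row tibble with `r_access`, `r_input` (ohm), `capacitance`
#'   (F), `tau` (s) and `flagged` (logical: `TRUE` when no transient could
#'   be resolved, in which case `capacitance` and `r_access` are `NA`).
#' @export
passive_properties_from_test_pulse <- function(data, step) {
  data <- as_tibble(data)
  if (!all(c("time", "current") %in% names(data))) {
    abort("`data` needs columns `time` and `current`.")
  }
  .check_number(step, "step")
  if (step == 0) abort("`step` must be non-zero.")
  fit <- fit_exponential_relaxation(
    tibble(time = data$time, value = data$current))
  no_transient <- !fit$converged ||
    "amplitude-negligible" %in% fit$flags
  if (no_transient) {
    i_ss <- mean(data$current[data$time >=
                                stats::quantile(data$time, 0.8)])
    return(tibble(r_access = NA_real_,
                  r_input = step / i_ss,
                  capacitance = NA_real_, tau = NA_real_,
                  flagged = TRUE))
  }
  i_ss <- fit_estimate(fit, "offset")
  i_peak <- i_ss + fit_estimate(fit, "amplitude")
  tau <- fit_estimate(fit, "tau")
  r_access <- step / i_peak
  r_input <- step / i_ss - r_access
  capacitance <- tau * (r_access + r_input) / (r_access * r_input)
  tibble(r_access = r_access, r_input = r_input,
         capacitance = capacitance, tau = tau, flagged = FALSE)
}
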