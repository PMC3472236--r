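#' Plot a simulation result
#'
#' Membrane voltage on top, per-species currents below, on a shared time
#' axis.
#'
#' @param object A `kv_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kv_sim
#' @export
autoplot.kv_sim <- function(object, ...) {
  d <- as_tibble(object)
  long <- tidyr::pivot_longer(
    d, cols = c("v", dplyr::starts_with("i_")),
    names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series == "v", "voltage (V)", "current (A)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s simulation", attr(object, "mode")))
}

#' Plot a synthetic voltage-clamp trace family
#'
#' @param object A `kv_trace_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kv_trace_set
#' @export
autoplot.kv_trace_set <- function(object, ...) {
  d <- object$data
  d$step <- object$sweeps$step[match(d$sweep, object$sweeps$sweep)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$current,
                                  group = .data$sweep,
                                  colour = factor(.data$step * 1e3))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "current (A)",
                  colour = "step (mV)")
}

#' Plot a subtraction-protocol result
#'
#' Total, sustained and transient (subtraction) current families on the
#' step-relative time axis.
#'
#' @param object A `kv_subtraction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kv_subtraction
#' @export
autoplot.kv_subtraction <- function(object, ...) {
  mk <- function(d, lab, col) {
    tibble(step = d$step, t_step = d$time - object$step_onset,
           i = d[[col]], family = lab)
  }
  long <- dplyr::bind_rows(
    mk(object$total, "total", "i_total"),
    mk(object$sustained, "sustained", "i_total"),
    tibble(step = object$transient$step,
           t_step = object$transient$t_step,
           i = object$transient$i, family = "transient"))
  long <- long[long$t_step >= -0.005, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_step, y = .data$i,
                                     group = interaction(.data$step,
                                                         .data$family),
                                     colour = factor(.data$step * 1e3))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~family, ncol = 1) +
    ggplot2::labs(x = "time from step (s)", y = "current (A)",
                  colour = "step (mV)")
}

#' Plot a conductance-scaling experiment
#'
#' @param object A `kv_scaling`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kv_scaling
#' @export
autoplot.kv_scaling <- function(object, ...) {
  ggplot2::ggplot(object$traces,
                  ggplot2::aes(x = .data$time, y = .data$v,
                               colour = factor(.data$scale))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "membrane voltage (V)",
                  colour = sprintf("%s scale", object$conductance))
}
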