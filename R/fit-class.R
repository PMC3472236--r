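# Common container for every curve fit in the package: broom-style tidy()
# and glance() methods, the fitted prediction function for plotting, and a
# character vector of quality flags. Estimates are reported even for flagged
# fits; `converged` records whether the optimizer finished.

new_kv_fit <- function(model, estimates, rss = NA_real_, converged = FALSE,
                       flags = character(), cov = NULL, fitted_fn = NULL,
                       data = NULL, n = NA_integer_) {
  structure(
    list(model = model, estimates = estimates, rss = rss,
         converged = converged, flags = flags, cov = cov,
         fitted_fn = fitted_fn, data = data, n = n),
    class = "kv_fit"
  )
}

# wrap minpack.lm::nlsLM; returns list(ok, fit) without throwing
.try_nlsLM <- function(formula, data, start, lower = NULL, upper = NULL,
                       maxiter = 500) {
  args <- list(formula = formula, data = data, start = start,
               control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    list(ok = FALSE, error = conditionMessage(fit))
  } else {
    list(ok = TRUE, fit = fit)
  }
}

.nls_estimates <- function(fit) {
  sm <- summary(fit)
  tibble(term = rownames(sm$coefficients),
         estimate = unname(sm$coefficients[, "Estimate"]),
         std.error = unname(sm$coefficients[, "Std. Error"]))
}

.failed_fit <- function(model, terms, data, n, msg) {
  new_kv_fit(model,
             tibble(term = terms, estimate = NA_real_,
                    std.error = NA_real_),
             converged = FALSE,
             flags = c("not-converged", msg),
             data = data, n = n)
}

#' @export
print.kv_fit <- function(x, ...) {
  cat(sprintf("<kv_fit> %s (%s%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              if (length(x$flags)) paste0("; ", paste(x$flags,
                                                      collapse = ", "))
              else ""))
  print(x$estimates)
  if (is.finite(x$rss)) cat(sprintf("  RSS = %.4g, n = %d\n", x$rss, x$n))
  invisible(x)
}

#' Tidy a photoKv curve fit
#'
#' @param x A `kv_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy kv_fit
#' @export
tidy.kv_fit <- function(x, ...) x$estimates

#' One-row summary of a photoKv curve fit
#'
#' @param x A `kv_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `model`, `rss`, `sigma`, `converged`,
#'   `flagged`, `nobs`.
#' @method glance kv_fit
#' @export
glance.kv_fit <- function(x, ...) {
  npar <- sum(!is.na(x$estimates$estimate))
  tibble(model = x$model, rss = x$rss,
         sigma = if (is.finite(x$rss) && x$n > npar)
           sqrt(x$rss / (x$n - npar)) else NA_real_,
         converged = x$converged,
         flagged = length(x$flags) > 0,
         nobs = x$n)
}

#' Extract one estimate from a fit
#'
#' @param x A `kv_fit`.
#' @param term Parameter name.
#' @return Numeric estimate.
#' @export
fit_estimate <- function(x, term) {
  stopifnot(inherits(x, "kv_fit"))
  i <- match(term, x$estimates$term)
  if (is.na(i)) abort(sprintf("No term '%s' in this fit.", term))
  unname(x$estimates$estimate[i])
}

#' @rdname fit_estimate
#' @export
fit_se <- function(x, term) {
  stopifnot(inherits(x, "kv_fit"))
  i <- match(term, x$estimates$term)
  if (is.na(i)) abort(sprintf("No term '%s' in this fit.", term))
  unname(x$estimates$std.error[i])
}

#' Plot a curve fit over its data
#'
#' @param object A `kv_fit` carrying its data and prediction function.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kv_fit
#' @export
autoplot.kv_fit <- function(object, n_grid = 200, ...) {
  if (is.null(object$data) || is.null(object$fitted_fn)) {
    abort("This fit does not carry data/prediction for plotting.")
  }
  d <- object$data
  xn <- names(d)[1]
  yn <- names(d)[2]
  grid <- tibble(x = seq(min(d[[xn]]), max(d[[xn]]), length.out = n_grid))
  grid$y <- object$fitted_fn(grid$x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xn]], y = .data[[yn]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "firebrick") +
    ggplot2::labs(title = object$model)
}
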