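#' Rate reconstruction result
#'
#' Container shared by all four estimators. The inverse method stores a
#' [basis_profile()]; the direct and indirect baselines store the rate
#' sampled on the measurement grid. `rate_at()` evaluates either kind at
#' arbitrary times (grid profiles are linearly interpolated, clamped at
#' the ends).
#'
#' @param profile A [basis_profile()] or a tibble (`time`, `rate`).
#' @param init_value Fitted initial condition (`B0` or `y0`); `NA` for
#'   methods that do not estimate one.
#' @param lambda_reg Tikhonov regularization weight used (or `NA`).
#' @param delta Basis spacing in hours (or `NA` for grid methods).
#' @param residual_norm `||data - model||_2` at the solution, in the
#'   method's own fitting domain.
#' @param method One of `"inverse"`, `"direct"`, `"indirect_sg"`,
#'   `"indirect_zerophase"`.
#' @param converged Logical convergence flag.
#' @param data Tibble of the ingested data used for the fit.
#' @return An object of class `rate_fit`.
#' @keywords internal
new_rate_fit <- function(profile, init_value, lambda_reg, delta,
                         residual_norm, method, converged, data = NULL) {
  structure(list(profile = profile, init_value = init_value,
                 lambda_reg = lambda_reg, delta = delta,
                 residual_norm = residual_norm, method = method,
                 converged = converged, data = data),
            class = "rate_fit")
}

#' Evaluate a fitted rate profile
#'
#' @param fit A `rate_fit`.
#' @param t Times (hours).
#' @return Rate value(s) at `t`.
#' @export
rate_at <- function(fit, t) {
  stopifnot(inherits(fit, "rate_fit"))
  if (inherits(fit$profile, "basis_profile")) {
    basis_eval(fit$profile, t)
  } else {
    interp(fit$profile$time, fit$profile$rate, t)
  }
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> method = %s, residual = %.4g%s%s\n",
              x$method, x$residual_norm,
              if (is.finite(x$lambda_reg)) sprintf(", lambda = %g", x$lambda_reg) else "",
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' @rdname tidy.rate_fit
#' @export
tidy.rate_fit <- function(x, ...) {
  tm <- if (!is.null(x$data)) x$data$time else
    seq(0, if (inherits(x$profile, "basis_profile")) x$profile$t_end else
      max(x$profile$time), length.out = 101L)
  tibble::tibble(time = tm, rate = rate_at(x, tm))
}

#' Tidiers for rate fits
#'
#' `tidy()` returns the reconstructed rate on the data's time grid;
#' `glance()` returns a one-row fit summary.
#'
#' @param x A `rate_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.rate_fit <- function(x, ...) {
  tibble::tibble(method = x$method, lambda_reg = x$lambda_reg,
                 delta = x$delta, init_value = x$init_value,
                 residual_norm = x$residual_norm, converged = x$converged)
}

#' Plot a rate fit
#'
#' @param object A `rate_fit`.
#' @param truth Optional tibble (`time`, `rate`) of the true profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_fit <- function(object, truth = NULL, ...) {
  df <- tidy.rate_fit(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rate)) +
    ggplot2::geom_line(color = "#1b9e91", linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "rate",
                  title = paste0("Reconstructed rate (", object$method, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(data = truth, linetype = "dashed", color = "black")
  }
  p
}
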