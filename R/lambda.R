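truth_on_grid <- function(truth, t) {
  if (is.function(truth)) return(truth(t))
  if (inherits(truth, "gompertz_params")) return(gompertz_growth_rate(truth, t))
  if (inherits(truth, "basis_profile")) return(basis_eval(truth, t))
  if (is.data.frame(truth)) {
    ycol <- if ("rate" %in% names(truth)) "rate" else "value"
    return(interp(truth$time, truth[[ycol]], t))
  }
  abort("Cannot interpret truth profile.")
}

fit_one <- function(inst, which, delta, lambda_reg, gamma = 0) {
  if (which == "growth") {
    fit_growth(inst$biomass, delta = delta, lambda_reg = lambda_reg)
  } else {
    fit_expression(inst$fluor, inst$biomass, gamma = gamma, delta = delta,
                   lambda_reg = lambda_reg)
  }
}

#' Oracle grid scan for the regularization weight
#'
#' Simulation-mode hyperparameter selection: for each candidate
#' `lambda` the estimator is run on every instance and the mean squared
#' error against the known truth is averaged across the dataset; the
#' `lambda` minimizing the mean MSE is returned together with the full
#' `lambda -> MSE` table. Requires ground truth, so it applies only to
#' simulated data; use [lambda_lcurve()] for experimental data.
#'
#' @param instances List of instances. For growth each element needs
#'   `$biomass` (data frame `time`, `value`) and `$truth`; for
#'   expression additionally `$fluor`. Truths may be functions,
#'   [gompertz_params()], [basis_profile()]s or data frames.
#' @param lambda_grid Candidate regularization weights (nonempty).
#' @param which `"growth"` or `"expression"`.
#' @param delta Basis spacing, hours.
#' @param gamma Reporter degradation rate (expression only).
#' @return A list of class `lambda_scan`: `lambda` (the argmin) and
#'   `table` (tibble `lambda`, `mean_mse`).
#' @export
scan_lambda <- function(instances, lambda_grid, which = c("growth", "expression"),
                        delta = 1, gamma = 0) {
  which <- match.arg(which)
  if (length(lambda_grid) == 0) abort("`lambda_grid` must be nonempty.")
  mean_mse <- vapply(lambda_grid, function(lam) {
    mses <- vapply(instances, function(inst) {
      fit <- fit_one(inst, which, delta, lam, gamma)
      grid <- fit$data$time
      mean((rate_at(fit, grid) - truth_on_grid(inst$truth, grid))^2)
    }, numeric(1))
    mean(mses)
  }, numeric(1))
  structure(list(lambda = lambda_grid[which.min(mean_mse)],
                 table = tibble::tibble(lambda = lambda_grid, mean_mse = mean_mse)),
            class = "lambda_scan")
}

#' @export
print.lambda_scan <- function(x, ...) {
  cat("<lambda_scan> best lambda =", format(x$lambda), "\n")
  print(x$table)
  invisible(x)
}

#' L-curve selection of the regularization weight
#'
#' Experimental-mode hyperparameter selection, used when no ground
#' truth exists. The estimator is run at each `lambda` on a log-spaced
#' grid; the L-curve plots log residual norm `||data - model||` against
#' log solution norm `||Theta||`, and the returned `lambda` sits at the
#' point of maximum curvature (the "corner"), estimated by central
#' finite differences along the grid.
#'
#' @param series Data frame (`time`, `value`) to fit (biomass for
#'   growth; fluorescence for expression).
#' @param lambda_grid Log-spaced grid of at least 5 values.
#' @param which `"growth"` or `"expression"`.
#' @param delta Basis spacing, hours.
#' @param biomass Companion biomass series (expression only).
#' @param gamma Reporter degradation rate (expression only).
#' @return The selected `lambda` (scalar), with the L-curve table as
#'   attribute `"lcurve"`.
#' @export
lambda_lcurve <- function(series, lambda_grid, which = c("growth", "expression"),
                          delta = 1, biomass = NULL, gamma = 0) {
  which <- match.arg(which)
  if (length(lambda_grid) < 5) {
    abort("`lambda_grid` must contain at least 5 values (curvature undefined).")
  }
  lambda_grid <- sort(lambda_grid)
  inst <- if (which == "growth") list(biomass = series) else
    list(fluor = series, biomass = biomass)
  fits <- lapply(lambda_grid, function(lam) fit_one(inst, which, delta, lam, gamma))
  rho <- vapply(fits, function(f) f$residual_norm, numeric(1))
  eta <- vapply(fits, function(f)
    sqrt(f$init_value^2 + sum(f$profile$weights^2)), numeric(1))
  if (max(rho) - min(rho) < 1e-12 && max(eta) - min(eta) < 1e-12) {
    warn("Degenerate L-curve (all points identical); falling back to median lambda.")
    return(stats::median(lambda_grid))
  }
  x <- log(pmax(rho, 1e-300)); y <- log(pmax(eta, 1e-300))
  k <- length(x); i <- 2:(k - 1)
  dx <- (x[i + 1] - x[i - 1]) / 2; dy <- (y[i + 1] - y[i - 1]) / 2
  ddx <- x[i + 1] - 2 * x[i] + x[i - 1]; ddy <- y[i + 1] - 2 * y[i] + y[i - 1]
  kappa <- abs(dx * ddy - dy * ddx) / (dx^2 + dy^2)^1.5
  kappa[!is.finite(kappa)] <- -Inf
  out <- lambda_grid[i[which.max(kappa)]]
  attr(out, "lcurve") <- tibble::tibble(lambda = lambda_grid, residual_norm = rho,
                                        solution_norm = eta)
  out
}
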