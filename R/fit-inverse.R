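#' Reconstruct a growth rate by regularized inversion
#'
#' Solves the growth-rate inverse problem
#' \deqn{\min_\Theta \; \|\bar B - F(\Theta)\|_2^2 + \lambda \|\Theta\|_2^2,
#'       \qquad \Theta = [B_0, \hat\mu],}
#' where `F` is the closed-form biomass forward model on the Gaussian
#' basis ([forward_biomass()]). The Tikhonov penalty is implemented as
#' appended residuals `sqrt(lambda) * Theta` (it includes the initial
#' condition, exactly as the objective is written) and the problem is
#' solved by bound-constrained Levenberg-Marquardt least squares with an
#' analytic Jacobian; bounds enforce `B0 > 1e-12` and nonnegative basis
#' weights, realizing the assumption that rates are nonnegative. The
#' data may contain noise and near-zero or negative entries; no
#' positivity is required of the measurements.
#'
#' The solve is two-stage: an unconstrained Levenberg-Marquardt pass
#' locates the basin quickly, the result is projected onto the bounds,
#' and a bounded pass polishes it there (projection steps alone stall
#' when many weights sit on the nonnegativity bound).
#'
#' @param biomass Data frame with columns `time` (hours) and `value`
#'   (background-corrected OD). The first time defines `t = 0`.
#' @param delta Basis spacing in hours (default 1, the typical
#'   timescale of protein synthesis).
#' @param lambda_reg Tikhonov weight `lambda >= 0`.
#' @param max_iter,tol Optimizer iteration cap and tolerance.
#' @return A [new_rate_fit()] with `method = "inverse"`.
#' @examples
#' b <- tibble::tibble(time = seq(0, 6, 0.25), value = 0.01 * exp(0.5 * seq(0, 6, 0.25)))
#' fit <- fit_growth(b, lambda_reg = 0)
#' rate_at(fit, 3) # ~0.5
#' @export
fit_growth <- function(biomass, delta = 1, lambda_reg = 0,
                       max_iter = 200L, tol = 1e-8) {
  check_series(biomass, "biomass")
  check_scalar(delta, "delta", 0, strict = TRUE)
  check_scalar(lambda_reg, "lambda_reg", 0)
  biomass <- shift_origin(biomass)
  t <- biomass$time; v <- biomass$value
  t_end <- max(t)
  n <- floor(t_end / delta) + 1L
  if (length(t) < n + 1L) {
    abort("Under-determined: fewer data points than parameters; increase `delta`.")
  }
  C <- basis_integral_matrix(t, delta, t_end)
  lower <- c(1e-12, rep(0, n))
  # crude scale-aware start: spread the log-range of the data (the
  # total growth-rate integral) uniformly over the basis, since each
  # unit bump contributes ~sqrt(2*pi*delta) to the integral
  vpos <- pmax(v, 1e-6)
  lrange <- max(0.1, log(max(vpos) / vpos[1]))
  par0 <- pmax(c(v[1], rep(lrange / (n * sqrt(2 * pi * delta)), n)), lower)
  sqrtl <- sqrt(lambda_reg)

  # exponent clamp keeps wild optimizer excursions finite
  fn <- function(p) {
    model <- p[1] * exp(pmin(drop(C %*% p[-1]), 500))
    c(v - model, sqrtl * p)
  }
  jac <- function(p) {
    e <- exp(pmin(drop(C %*% p[-1]), 500))
    Jd <- -cbind(e, (p[1] * e) * C)
    rbind(Jd, diag(sqrtl, length(p)))
  }
  sol <- solve_bounded_lm(par0, lower, fn, jac, max_iter, tol)
  if (!sol$converged) warn("Growth-rate fit did not converge; result flagged.")
  p <- sol$par
  model <- p[1] * exp(drop(C %*% p[-1]))
  new_rate_fit(profile = basis_profile(p[-1], delta, t_end),
               init_value = p[1], lambda_reg = lambda_reg, delta = delta,
               residual_norm = sqrt(sum((v - model)^2)),
               method = "inverse", converged = sol$converged, data = biomass)
}

# Bound-constrained nonlinear least squares in two stages: an
# unconstrained Levenberg-Marquardt pass locates the basin quickly;
# the projected result is then polished by Gauss-Newton steps whose
# bound-constrained linear subproblems are solved exactly by
# Lawson-Hanson nonnegative least squares (simple gradient projection
# stalls when many weights sit on the nonnegativity bound). With
# linear residuals the polish is exact after one step.
solve_bounded_lm <- function(par0, lower, fn, jac, max_iter, tol) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter, ftol = tol,
                                     ptol = tol, gtol = 0)
  s1 <- suppressWarnings(minpack.lm::nls.lm(par = par0, fn = fn, jac = jac,
                                            control = ctrl))
  p1 <- ifelse(is.finite(s1$par), s1$par, par0)
  if (all(p1 >= lower) && s1$info %in% 1:4) {
    return(list(par = p1, converged = TRUE))
  }
  p <- pmax(p1, lower)
  cost <- sum(fn(p)^2)
  converged <- FALSE
  for (it in seq_len(50L)) {
    J <- jac(p); r <- fn(p)
    # q = p + dp - lower >= 0; minimize ||J q + (r - J (p - lower))||^2
    c0 <- r - drop(J %*% (p - lower))
    q <- nnls_safe(J, -c0)
    p_new <- lower + q
    step <- 1
    repeat {
      cand <- p + step * (p_new - p)
      cost_new <- sum(fn(cand)^2)
      if (cost_new <= cost || step < 1e-4) break
      step <- step / 2
    }
    moved <- max(abs(cand - p))
    improve <- cost - cost_new
    p <- cand; cost <- cost_new
    if (improve <= tol * (cost + tol) && moved <= tol * (1 + max(abs(p)))) {
      converged <- TRUE
      break
    }
  }
  list(par = p, converged = converged || s1$info %in% 1:4)
}

# Lawson-Hanson active-set nonnegative least squares, hardened for
# ill-conditioned Jacobians: rank-deficient passive-set solves fall
# back to a tiny ridge, and iteration caps return the best iterate
# found (the caller line-searches on the true cost, so an inexact
# subproblem solution only slows, never breaks, the outer loop).
nnls_safe <- function(A, b) {
  n <- ncol(A)
  ls_sub <- function(Ap, b) {
    out <- tryCatch(qr.solve(Ap, b), error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
    lam <- 1e-10 * sum(Ap^2)
    drop(solve(crossprod(Ap) + diag(lam, ncol(Ap)), crossprod(Ap, b)))
  }
  x <- numeric(n)
  passive <- logical(n)
  tol <- 1e-10 * max(abs(crossprod(A, b)))
  w <- drop(crossprod(A, b - A %*% x))
  outer_max <- 5L * n
  for (it in seq_len(outer_max)) {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    for (inner in seq_len(n)) {
      s <- numeric(n)
      s[passive] <- ls_sub(A[, passive, drop = FALSE], b)
      if (all(s[passive] > 0)) break
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > .Machine$double.eps
    }
    x <- pmax(s, 0)
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Reconstruct an expression rate by regularized inversion
#'
#' Solves the expression-rate inverse problem
#' \deqn{\min_\Theta \; \|\bar y - G(\Theta, \bar B)\|_2^2 +
#'       \lambda \|\Theta\|_2^2, \qquad \Theta = [y_0, \hat\phi],}
#' where `G` is the fluorescence forward model
#' ([forward_fluorescence()]) driven by the *measured* biomass series.
#' Same solver, bounds and penalty convention as [fit_growth()].
#'
#' @param fluor Data frame (`time`, `value`): background-corrected
#'   fluorescence.
#' @param biomass Data frame (`time`, `value`) on the same time grid.
#' @param gamma Reporter degradation rate per hour (default 0).
#' @inheritParams fit_growth
#' @return A [new_rate_fit()] with `method = "inverse"`.
#' @export
fit_expression <- function(fluor, biomass, gamma = 0, delta = 1,
                           lambda_reg = 0, max_iter = 200L, tol = 1e-8) {
  check_series(fluor, "fluor")
  check_series(biomass, "biomass")
  check_scalar(gamma, "gamma", 0)
  check_scalar(lambda_reg, "lambda_reg", 0)
  if (length(fluor$time) != length(biomass$time) ||
      max(abs(fluor$time - biomass$time)) > 1e-8) {
    abort("`fluor` and `biomass` must share the same time grid.")
  }
  fluor <- shift_origin(fluor); biomass <- shift_origin(biomass)
  t <- fluor$time; v <- fluor$value
  t_end <- max(t)
  n <- floor(t_end / delta) + 1L
  if (length(t) < n + 1L) {
    abort("Under-determined: fewer data points than parameters; increase `delta`.")
  }
  des <- expression_design(biomass, t, delta, t_end, gamma)
  lower <- rep(0, n + 1L)
  par0 <- pmax(c(v[1], rep((max(v) - min(v)) / (n * delta), n)), lower)
  sqrtl <- sqrt(lambda_reg)
  Jd <- -cbind(des$decay, des$decay * des$M)

  fn <- function(p) {
    model <- des$decay * (p[1] + drop(des$M %*% p[-1]))
    c(v - model, sqrtl * p)
  }
  jac <- function(p) rbind(Jd, diag(sqrtl, length(p)))
  sol <- solve_bounded_lm(par0, lower, fn, jac, max_iter, tol)
  if (!sol$converged) warn("Expression-rate fit did not converge; result flagged.")
  p <- sol$par
  model <- des$decay * (p[1] + drop(des$M %*% p[-1]))
  new_rate_fit(profile = basis_profile(p[-1], delta, t_end),
               init_value = p[1], lambda_reg = lambda_reg, delta = delta,
               residual_norm = sqrt(sum((v - model)^2)),
               method = "inverse", converged = sol$converged, data = fluor)
}
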