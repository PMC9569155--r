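#' Direct linear-inversion configuration
#'
#' The direct baseline discretizes the rate on the measurement grid and
#' solves a linear Tikhonov-regularized least squares with a
#' difference-operator penalty. Its single hyperparameter is the
#' "insignificant value" `eps_insignificant`: the regularization weight
#' is taken as the largest value whose squared-residual increase over
#' the (essentially zero) unregularized residual, relative to the
#' squared data norm, stays below it.
#'
#' @param eps_insignificant Relative residual-increase tolerance (> 0).
#' @param penalty_order Order of the difference penalty (default 1).
#' @param floor_eps Positive floor applied to non-positive biomass
#'   before taking logs (growth only). This floor is precisely where
#'   the method is fragile at low biomass.
#' @return An object of class `direct_config`.
#' @export
direct_config <- function(eps_insignificant = 1e-3, penalty_order = 1L,
                          floor_eps = 1e-6) {
  check_scalar(eps_insignificant, "eps_insignificant", 0, strict = TRUE)
  structure(list(eps_insignificant = eps_insignificant,
                 penalty_order = as.integer(penalty_order),
                 floor_eps = floor_eps),
            class = "direct_config")
}

# Lower-triangular matrix of trapezoid weights: row j integrates a
# grid function from t[1] to t[j].
cumulative_trapz_matrix <- function(t) {
  m <- length(t)
  Tm <- matrix(0, m, m)
  dt <- diff(t)
  for (j in 2:m) {
    w <- numeric(m)
    w[1] <- dt[1] / 2
    if (j > 2) w[2:(j - 1)] <- (t[3:j] - t[1:(j - 2)]) / 2
    w[j] <- dt[j - 1] / 2
    Tm[j, ] <- w
  }
  Tm
}

# Solve min ||z - A x||^2 + alpha^2 ||L x||^2.
reg_solve <- function(AtA, Atz, LtL, alpha) {
  solve(AtA + alpha^2 * LtL, Atz)
}

# Largest alpha whose squared-residual increase over the minimal-alpha
# solve, relative to ||z||^2, is below eps; log-grid then bisection.
choose_alpha <- function(A, z, L, eps) {
  AtA <- crossprod(A); Atz <- crossprod(A, z); LtL <- crossprod(L)
  r2 <- function(alpha) {
    x <- tryCatch(reg_solve(AtA, Atz, LtL, alpha), error = function(e) NULL)
    if (is.null(x)) return(Inf)
    sum((z - drop(A %*% x))^2)
  }
  z2 <- sum(z^2)
  # With one more unknown than equations the unregularized residual is
  # the (essentially zero) least-squares floor; take it from a QR solve.
  base <- sum(qr.resid(qr(A), z)^2)
  ok <- function(alpha) (r2(alpha) - base) / z2 <= eps
  grid <- 10^seq(-6, 6, length.out = 25)
  pass <- vapply(grid, ok, logical(1))
  if (all(pass)) return(list(alpha = grid[length(grid)], AtA = AtA, Atz = Atz, LtL = LtL))
  if (!pass[1]) return(list(alpha = grid[1], AtA = AtA, Atz = Atz, LtL = LtL))
  lo <- grid[max(which(pass))]; hi <- grid[min(which(!pass))]
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    if (ok(mid)) lo <- mid else hi <- mid
  }
  list(alpha = lo, AtA = AtA, Atz = Atz, LtL = LtL)
}

#' Direct linear inversion of the growth rate
#'
#' Baseline estimator: linearizes the biomass ODE in the log domain,
#' `log B(t_j) = log B0 + int_0^{t_j} mu`, with the integral as
#' trapezoid weights on the measurement grid, and solves the resulting
#' linear system with a first-difference Tikhonov penalty whose weight
#' is set by the insignificant-value rule. Non-positive biomass values
#' (common after background correction at low biomass) are floored at
#' a small positive epsilon before the log — the documented fragility
#' of this method.
#'
#' @param biomass Data frame (`time`, `value`).
#' @param config A [direct_config()].
#' @return A [new_rate_fit()] with `method = "direct"`; the rate is not
#'   constrained nonnegative.
#' @export
direct_growth <- function(biomass, config = direct_config()) {
  check_series(biomass, "biomass")
  biomass <- shift_origin(biomass)
  t <- biomass$time; v <- biomass$value
  m <- length(t)
  if (any(v <= config$floor_eps)) {
    warn("Non-positive biomass floored before log; expect noise amplification.")
    v <- pmax(v, config$floor_eps)
  }
  z <- log(v)
  A <- cbind(1, cumulative_trapz_matrix(t))
  D <- diff(diag(m), differences = config$penalty_order)
  L <- cbind(0, D)
  ch <- choose_alpha(A, z, L, config$eps_insignificant)
  x <- drop(reg_solve(ch$AtA, ch$Atz, ch$LtL, ch$alpha))
  resid <- z - drop(A %*% x)
  new_rate_fit(profile = tibble::tibble(time = t, rate = x[-1]),
               init_value = exp(x[1]), lambda_reg = ch$alpha^2, delta = NA_real_,
               residual_norm = sqrt(sum(resid^2)), method = "direct",
               converged = TRUE, data = biomass)
}

#' Direct linear inversion of the expression rate
#'
#' Baseline estimator: the reporter model is linear in `(y0, phi)` once
#' phi is discretized on the measurement grid —
#' `y(t_j) = y0 + int_0^{t_j} Bbar phi` by trapezoid (integrating-factor
#' form when `gamma > 0`) — and is solved with the same regularized
#' linear least squares and insignificant-value rule as
#' [direct_growth()]. The rate is deliberately left unconstrained (the
#' baseline's known weakness is preserved, not repaired).
#'
#' @param fluor,biomass Data frames (`time`, `value`) on a shared grid.
#' @param gamma Reporter degradation rate per hour.
#' @param config A [direct_config()].
#' @return A [new_rate_fit()] with `method = "direct"`.
#' @export
direct_expression <- function(fluor, biomass, gamma = 0,
                              config = direct_config()) {
  check_series(fluor, "fluor"); check_series(biomass, "biomass")
  if (length(fluor$time) != length(biomass$time) ||
      max(abs(fluor$time - biomass$time)) > 1e-8) {
    abort("`fluor` and `biomass` must share the same time grid.")
  }
  fluor <- shift_origin(fluor); biomass <- shift_origin(biomass)
  t <- fluor$time; z <- fluor$value; bbar <- biomass$value
  m <- length(t)
  Tm <- cumulative_trapz_matrix(t)
  if (gamma > 0) {
    A <- cbind(exp(-gamma * t),
               exp(-gamma * t) * sweep(Tm, 2, bbar * exp(gamma * t), "*"))
  } else {
    A <- cbind(1, sweep(Tm, 2, bbar, "*"))
  }
  D <- diff(diag(m), differences = config$penalty_order)
  L <- cbind(0, D)
  ch <- choose_alpha(A, z, L, config$eps_insignificant)
  x <- drop(reg_solve(ch$AtA, ch$Atz, ch$LtL, ch$alpha))
  resid <- z - drop(A %*% x)
  new_rate_fit(profile = tibble::tibble(time = t, rate = x[-1]),
               init_value = x[1], lambda_reg = ch$alpha^2, delta = NA_real_,
               residual_norm = sqrt(sum(resid^2)), method = "direct",
               converged = TRUE, data = fluor)
}
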