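#' Gaussian basis representation of a nonnegative rate profile
#'
#' Time-varying growth and expression rates are represented as a weighted
#' sum of Gaussian bumps placed regularly at intervals `delta` over the
#' observation window,
#' \deqn{f(t) \approx \sum_{k=0}^{n-1} \hat f_k \, G_k(t), \qquad
#'       G_k(t) = \exp\!\left(\frac{-(t - k\Delta)^2}{2\Delta}\right),}
#' with `n = floor(t_end / delta) + 1` centers at `k * delta`,
#' `k = 0, ..., n - 1`, so that both endpoints of the window carry a
#' center. `delta` sets the timescale of variation the basis can express:
#' the steepest achievable slope of a unit basis function scales as
#' `1/sqrt(delta)`. Note the variance term of each bump is `delta`
#' itself, in hours, so the bump standard deviation is `sqrt(delta)`.
#'
#' @param weights Numeric vector of nonnegative basis weights.
#' @param delta Basis spacing (and variance parameter) in hours.
#' @param t_end Length of the represented time window in hours.
#' @return An object of class `basis_profile`.
#' @examples
#' p <- basis_profile(rep(0.5, 25), delta = 1, t_end = 24)
#' basis_eval(p, c(0, 1.5, 24))
#' @export
basis_profile <- function(weights, delta, t_end) {
  check_scalar(delta, "delta", 0, strict = TRUE)
  check_scalar(t_end, "t_end", 0, strict = TRUE)
  n <- floor(t_end / delta) + 1L
  if (!is.numeric(weights) || length(weights) != n) {
    abort(paste0("`weights` must have length floor(t_end/delta) + 1 = ", n, "."))
  }
  if (anyNA(weights) || any(weights < 0)) {
    abort("`weights` must be finite and nonnegative.")
  }
  structure(
    list(weights = as.numeric(weights), delta = delta, t_end = t_end),
    class = "basis_profile"
  )
}

#' @export
print.basis_profile <- function(x, ...) {
  cat("<basis_profile> ", length(x$weights), " Gaussian bumps, delta = ",
      x$delta, " h over [0, ", x$t_end, "] h\n", sep = "")
  invisible(x)
}

basis_centers <- function(delta, t_end) {
  n <- floor(t_end / delta) + 1L
  (seq_len(n) - 1L) * delta
}

# n_t x n_k matrix of G_k(t).
basis_matrix <- function(t, delta, t_end) {
  centers <- basis_centers(delta, t_end)
  exp(-outer(t, centers, "-")^2 / (2 * delta))
}

# n_t x n_k matrix of \int_0^t G_k(s) ds, closed form via erf.
basis_integral_matrix <- function(t, delta, t_end) {
  centers <- basis_centers(delta, t_end)
  s <- sqrt(2 * delta)
  sqrt(pi * delta / 2) *
    (erf(outer(t, centers, "-") / s) -
       matrix(erf(-centers / s), nrow = length(t), ncol = length(centers),
              byrow = TRUE))
}

#' Evaluate a Gaussian basis profile
#'
#' @param profile A [basis_profile()].
#' @param t Time(s) in hours; must be finite.
#' @return Nonnegative value(s) of the represented rate at `t`.
#' @export
basis_eval <- function(profile, t) {
  stopifnot(inherits(profile, "basis_profile"))
  if (!is.numeric(t) || length(t) == 0 || anyNA(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.")
  }
  drop(basis_matrix(t, profile$delta, profile$t_end) %*% profile$weights)
}

#' Cumulative integral of a Gaussian basis profile
#'
#' Closed-form \eqn{\int_0^t \sum_k w_k G_k(s)\,ds} via the error
#' function; used to integrate the growth rate in the biomass forward
#' model.
#'
#' @inheritParams basis_eval
#' @param t Time(s) in hours, `t >= 0`.
#' @return Nonnegative, nondecreasing value(s) of the integral.
#' @export
basis_cumulative_integral <- function(profile, t) {
  stopifnot(inherits(profile, "basis_profile"))
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be finite and >= 0.")
  }
  drop(basis_integral_matrix(t, profile$delta, profile$t_end) %*% profile$weights)
}
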