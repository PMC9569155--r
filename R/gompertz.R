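#' Gompertz growth model parameters
#'
#' The simulated ground-truth biomass follows the Gompertz law
#' \deqn{\log(B/B_0) = A \exp\!\big(-\exp(\tfrac{\mu^* e}{A}(\lambda_{lag}-t)+1)\big)}
#' with maximal growth rate `mu_star` (per hour), lag-phase length `lag`
#' (hours), minimum biomass `b0` and maximal biomass `b_max`;
#' `a = log(b_max / b0)` is derived. Defaults reproduce the study
#' conditions: `b0 = 0.01`, `b_max = 1`, so `a = log(100)`.
#'
#' @param mu_star Maximal growth rate, per hour.
#' @param lag Lag-phase length, hours.
#' @param b0 Minimum (initial-scale) biomass, OD units.
#' @param b_max Maximal biomass, OD units.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(mu_star, lag, b0 = 0.01, b_max = 1) {
  check_scalar(mu_star, "mu_star", 0, strict = TRUE)
  check_scalar(lag, "lag", 0)
  check_scalar(b0, "b0", 0, strict = TRUE)
  if (b_max <= b0) abort("`b_max` must exceed `b0`.")
  structure(
    list(mu_star = mu_star, lag = lag, b0 = b0, b_max = b_max,
         a = log(b_max / b0)),
    class = "gompertz_params"
  )
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("<gompertz_params> mu* = %.3f /h, lag = %.2f h, B0 = %g, B* = %g\n",
              x$mu_star, x$lag, x$b0, x$b_max))
  invisible(x)
}

#' Gompertz biomass curve
#'
#' @param params A [gompertz_params()].
#' @param t Time(s), hours, `>= 0`.
#' @return Biomass (OD units) at `t`.
#' @export
gompertz_biomass <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  u <- params$mu_star * exp(1) * (params$lag - t) / params$a
  params$b0 * exp(params$a * exp(-exp(u + 1)))
}

#' Gompertz specific growth rate
#'
#' The growth rate implied by the Gompertz biomass law,
#' \deqn{\mu(t) = \mu^* \exp\!\big[u - \exp(u+1) + 2\big], \quad
#'       u = \tfrac{\mu^* e}{A}(\lambda_{lag} - t),}
#' which equals `d log B / dt` of [gompertz_biomass()]. Its maximum over
#' `t` is exactly `mu_star`, attained at `t = lag + a / (mu_star * e)`.
#'
#' @inheritParams gompertz_biomass
#' @return Growth rate (per hour) at `t`.
#' @export
gompertz_growth_rate <- function(params, t) {
  stopifnot(inherits(params, "gompertz_params"))
  u <- params$mu_star * exp(1) * (params$lag - t) / params$a
  params$mu_star * exp(u - exp(u + 1) + 2)
}

#' Draw random Gompertz parameters
#'
#' Study conditions for the simulation benchmark:
#' `mu_star ~ U[0.5, 1]` per hour, `lag ~ U[0, 4]` hours, fixed
#' `b0 = 0.01` and `b_max = 1`.
#'
#' @param seed Optional integer seed for reproducibility.
#' @return A [gompertz_params()].
#' @export
sample_gompertz <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gompertz_params(mu_star = stats::runif(1, 0.5, 1),
                  lag = stats::runif(1, 0, 4))
}
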