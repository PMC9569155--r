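# Internal helpers shared across modules.

#' @importFrom rlang abort warn
#' @importFrom stats approx pnorm sd setNames
NULL

# Gauss error function.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Validate a kinetic series data frame: columns `time`, `value`,
# strictly increasing times, at least `min_points` rows.
check_series <- function(x, arg = "series", min_points = 3L) {
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns `time` and `value`."))
  }
  t <- x$time
  if (length(t) < min_points) {
    abort(paste0("`", arg, "` needs at least ", min_points, " points."))
  }
  if (anyNA(t) || any(!is.finite(t))) abort(paste0("`", arg, "` has non-finite times."))
  if (any(diff(t) <= 0)) abort(paste0("`", arg, "` times must be strictly increasing."))
  invisible(x)
}

# Shift a series so the first retained measurement defines t = 0.
shift_origin <- function(x) {
  x$time <- x$time - x$time[[1]]
  x
}

check_scalar <- function(x, arg, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", arg, "` must be a finite numeric scalar."))
  }
  if (strict && x <= lower) abort(paste0("`", arg, "` must be > ", lower, "."))
  if (!strict && x < lower) abort(paste0("`", arg, "` must be >= ", lower, "."))
  invisible(x)
}

# Linear interpolation clamped to the support ends.
interp <- function(time, value, xout) {
  stats::approx(time, value, xout = xout, rule = 2)$y
}

# Refine a (possibly irregular) grid by `factor` subdivisions per interval.
refine_grid <- function(t, factor = 10L) {
  m <- length(t)
  out <- vapply(seq_len(m - 1L), function(i) {
    seq(t[i], t[i + 1L], length.out = factor + 1L)[-(factor + 1L)]
  }, numeric(factor))
  c(as.vector(out), t[m])
}

# Cumulative trapezoid integral of y over x, same length as x.
cum_trapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}
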