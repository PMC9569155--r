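values_on_grid <- function(x, t) {
  if (inherits(x, "rate_fit")) return(rate_at(x, t))
  truth_on_grid(x, t)
}

# Non-finite entries in a grid-valued profile (linear interpolation
# would silently skip them).
profile_nonfinite <- function(x) {
  if (inherits(x, "rate_fit")) x <- x$profile
  if (is.data.frame(x)) {
    ycol <- if ("rate" %in% names(x)) "rate" else "value"
    return(any(!is.finite(x[[ycol]])))
  }
  FALSE
}

#' Mean squared error between two rate profiles
#'
#' @param estimated,truth Profiles: `rate_fit`, function,
#'   [gompertz_params()], [basis_profile()] or data frame.
#' @param t_grid Times (hours) over which to average.
#' @return Mean of squared differences; `NA` if the estimate contains
#'   non-finite values (the instance should then be flagged failed).
#' @export
profile_mse <- function(estimated, truth, t_grid) {
  if (profile_nonfinite(estimated)) return(NA_real_)
  e <- values_on_grid(estimated, t_grid)
  tr <- values_on_grid(truth, t_grid)
  if (any(!is.finite(e))) return(NA_real_)
  mean((e - tr)^2)
}

#' Squared reconstruction error at time zero
#'
#' Early-time accuracy metric: the squared difference between estimate
#' and truth at `t = 0`, where low biomass makes reconstruction
#' hardest.
#'
#' @inheritParams profile_mse
#' @return `(estimated(0) - truth(0))^2`, or `NA` if non-finite.
#' @export
initial_error <- function(estimated, truth) {
  if (profile_nonfinite(estimated)) return(NA_real_)
  e <- values_on_grid(estimated, 0)
  if (!is.finite(e)) return(NA_real_)
  (e - values_on_grid(truth, 0))^2
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom, used
#' to compare per-instance MSE distributions between methods. The
#' degenerate case (both samples constant and equal) returns
#' `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors, length >= 2.
#' @return A list with `statistic` and `p_value`.
#' @export
welch_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("Need >= 2 finite values per sample.")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf * sign(mean(a) - mean(b)), p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}

# Generate the benchmark substrate: n instances per noise level.
# Returns a list of instances with background-corrected series and truths.
generate_instances <- function(which, n, noise_levels, seed, gamma_true = 0,
                               config = sim_config()) {
  t_euler <- seq(0, config$horizon, by = config$dt)
  tm <- t_euler[seq(1L, length(t_euler), by = config$sample_every)]
  insts <- list()
  counter <- 0L
  for (li in seq_along(noise_levels)) {
    sig <- noise_levels[li]
    for (i in seq_len(n)) {
      counter <- counter + 1L
      iseed <- derive_seed(seed, counter)
      set.seed(iseed)
      params <- sample_gompertz()
      if (which == "expression") {
        phi_v <- random_expression_profile(length(tm), config)
        phi <- tibble::tibble(time = tm, value = phi_v)
      } else {
        phi <- 0
      }
      wl <- simulate_well(params, phi, gamma = gamma_true,
                          noise = noise_spec(sig), config = config)
      biomass <- wl$biomass
      biomass$value <- biomass$value - wl$noise$bg_biomass
      inst <- list(id = counter, seed = iseed, noise_level = sig,
                   params = params, biomass = biomass)
      if (which == "expression") {
        fluor <- wl$fluor
        fluor$value <- fluor$value - wl$noise$bg_fluor
        inst$fluor <- fluor
        inst$truth <- tibble::tibble(time = tm, rate = phi$value)
      } else {
        inst$truth <- params
      }
      insts[[counter]] <- inst
    }
  }
  insts
}

fit_method <- function(inst, which, method, delta, lambda, gamma,
                       dcfg, icfg_sg, icfg_zp) {
  switch(method,
    inverse = if (which == "growth") {
      fit_growth(inst$biomass, delta = delta, lambda_reg = lambda)
    } else {
      fit_expression(inst$fluor, inst$biomass, gamma = gamma, delta = delta,
                     lambda_reg = lambda)
    },
    direct = if (which == "growth") {
      suppressWarnings(direct_growth(inst$biomass, dcfg))
    } else {
      direct_expression(inst$fluor, inst$biomass, gamma = gamma, config = dcfg)
    },
    indirect_sg = if (which == "growth") {
      indirect_growth(inst$biomass, icfg_sg)
    } else {
      indirect_expression(inst$fluor, inst$biomass, gamma = gamma, config = icfg_sg)
    },
    indirect_zerophase = if (which == "growth") {
      indirect_growth(inst$biomass, icfg_zp)
    } else {
      indirect_expression(inst$fluor, inst$biomass, gamma = gamma, config = icfg_zp)
    },
    abort(paste0("Unknown method: ", method)))
}

#' Method-comparison benchmark on simulated data
#'
#' Reproduces the simulation benchmark: `n` random instances per noise
#' level (Gompertz growth models for the growth task; smoothed
#' lognormal random-walk expression truths paired with random Gompertz
#' biomass for the expression task), simulated with background and
#' multiplicative noise, background-corrected, reconstructed by each
#' method, and scored by mean squared error against the truth on the
#' measurement grid. Hyperparameters (`lambda` for the inverse method,
#' Savitzky-Golay window for the indirect method, the insignificant
#' value for the direct method) are selected by an error-minimizing
#' grid scan on a calibration subset, then held fixed. Summaries
#' include per-method mean MSE with normal-approximation 95% CIs,
#' pairwise fold changes of mean MSE and two-sided Welch t-tests on the
#' per-instance MSEs. Instances whose estimate is non-finite are
#' excluded with counts reported; a method failing on more than 10% of
#' instances aborts.
#'
#' @param which `"growth"` or `"expression"`.
#' @param n Instances per noise level.
#' @param noise_levels Multiplicative noise standard deviations.
#' @param methods Subset of `c("inverse", "direct", "indirect_sg",
#'   "indirect_zerophase")`.
#' @param seed Integer seed; per-instance sub-seeds are derived from it
#'   and recorded for exact replay.
#' @param delta Basis spacing for the inverse method, hours.
#' @param lambda `"scan"` (default) or a fixed numeric weight.
#' @param lambda_grid Grid for the lambda scan.
#' @param sg_window `"scan"` or a fixed odd window.
#' @param window_grid Grid of odd windows for the scan.
#' @param eps_insignificant `"scan"` or a fixed value for the direct
#'   method.
#' @param eps_grid Grid for the insignificant-value scan.
#' @param n_calib Calibration instances per noise level used by the
#'   scans.
#' @param gamma_true Degradation rate used in simulation.
#' @param gamma_assumed Degradation rate assumed by the estimators
#'   (differs from `gamma_true` in mismatch sweeps).
#' @param config A [sim_config()].
#' @return An object of class `rate_benchmark`: list with `results`
#'   (per-instance tibble), `summary`, `pairwise`, `hyperparameters`,
#'   `excluded`, and the call configuration.
#' @export
run_benchmark <- function(which = c("growth", "expression"), n = 100L,
                          noise_levels = c(0.01, 0.05, 0.1),
                          methods = c("inverse", "direct", "indirect_sg",
                                      "indirect_zerophase"),
                          seed = 1L, delta = 1, lambda = "scan",
                          lambda_grid = 10^seq(-6, 2), sg_window = "scan",
                          window_grid = seq(5L, 41L, by = 4L),
                          eps_insignificant = "scan",
                          eps_grid = 10^seq(-6, -1),
                          n_calib = 12L, gamma_true = 0, gamma_assumed = 0,
                          config = sim_config()) {
  which <- match.arg(which)
  methods <- match.arg(methods, several.ok = TRUE)
  insts <- generate_instances(which, n, noise_levels, seed, gamma_true, config)

  calib_ids <- unlist(lapply(seq_along(noise_levels) - 1L,
                             function(li) li * n + seq_len(min(n_calib, n))))
  calib <- insts[calib_ids]

  hyper <- list(delta = delta)
  if ("inverse" %in% methods) {
    hyper$lambda <- if (identical(lambda, "scan")) {
      scan_lambda(calib, lambda_grid, which, delta = delta,
                  gamma = gamma_assumed)$lambda
    } else lambda
  }
  if ("indirect_sg" %in% methods) {
    hyper$sg_window <- if (identical(sg_window, "scan")) {
      mses <- vapply(window_grid, function(w) {
        cfg <- indirect_config(sg_window = w)
        mean(vapply(calib, function(inst) {
          fit <- if (which == "growth") indirect_growth(inst$biomass, cfg)
            else indirect_expression(inst$fluor, inst$biomass, gamma_assumed, cfg)
          m <- profile_mse(fit, inst$truth, fit$data$time)
          if (is.na(m)) Inf else m
        }, numeric(1)))
      }, numeric(1))
      window_grid[which.min(mses)]
    } else sg_window
  }
  if ("direct" %in% methods) {
    hyper$eps_insignificant <- if (identical(eps_insignificant, "scan")) {
      mses <- vapply(eps_grid, function(e) {
        cfg <- direct_config(eps_insignificant = e)
        mean(vapply(calib, function(inst) {
          fit <- if (which == "growth")
            suppressWarnings(direct_growth(inst$biomass, cfg))
            else direct_expression(inst$fluor, inst$biomass, gamma_assumed, cfg)
          m <- profile_mse(fit, inst$truth, fit$data$time)
          if (is.na(m)) Inf else m
        }, numeric(1)))
      }, numeric(1))
      eps_grid[which.min(mses)]
    } else eps_insignificant
  }

  dcfg <- direct_config(eps_insignificant = hyper$eps_insignificant %||% 1e-3)
  icfg_sg <- indirect_config(sg_window = hyper$sg_window %||% 11L)
  icfg_zp <- indirect_config(filter_kind = "zerophase_butterworth")

  rows <- vector("list", length(insts) * length(methods))
  k <- 0L
  for (inst in insts) {
    for (m in methods) {
      k <- k + 1L
      t0 <- proc.time()[["elapsed"]]
      fit <- fit_method(inst, which, m, delta,
                        hyper$lambda %||% 0, gamma_assumed,
                        dcfg, icfg_sg, icfg_zp)
      rt <- proc.time()[["elapsed"]] - t0
      rows[[k]] <- tibble::tibble(
        instance = inst$id, seed = inst$seed, noise_level = inst$noise_level,
        method = m,
        mse = profile_mse(fit, inst$truth, fit$data$time),
        mse_at_t0 = initial_error(fit, inst$truth),
        runtime = rt)
    }
  }
  results <- dplyr::bind_rows(rows)

  excluded <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_failed = sum(is.na(.data$mse)), n_total = dplyr::n(),
                     .groups = "drop")
  bad <- excluded$n_failed / excluded$n_total > 0.1
  if (any(bad)) {
    abort(paste0("Method(s) failed on > 10% of instances: ",
                 paste(excluded$method[bad], collapse = ", ")))
  }

  summary <- results |>
    dplyr::filter(is.finite(.data$mse)) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(), mean_mse = mean(.data$mse),
      ci_half = 1.96 * stats::sd(.data$mse) / sqrt(dplyr::n()),
      mean_mse_t0 = mean(.data$mse_at_t0, na.rm = TRUE),
      .groups = "drop")

  pairs <- expand.grid(method_a = methods, method_b = methods,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$method_a != pairs$method_b, ]
  pairwise <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$method_a[i]; b <- pairs$method_b[i]
    xa <- results$mse[results$method == a & is.finite(results$mse)]
    xb <- results$mse[results$method == b & is.finite(results$mse)]
    wt <- welch_test(xa, xb)
    tibble::tibble(method_a = a, method_b = b,
                   fold_change = mean(xa) / mean(xb),
                   welch_t = wt$statistic, p_value = wt$p_value)
  }))

  structure(list(results = results, summary = summary, pairwise = pairwise,
                 hyperparameters = hyper, excluded = excluded,
                 which = which, n = n, noise_levels = noise_levels,
                 methods = methods, seed = seed),
            class = "rate_benchmark")
}

#' @export
print.rate_benchmark <- function(x, ...) {
  cat("<rate_benchmark> task =", x$which, "| n =", x$n, "per level x",
      length(x$noise_levels), "noise levels\n")
  print(x$summary)
  invisible(x)
}

#' @rdname tidy.rate_benchmark
#' @export
glance.rate_benchmark <- function(x, ...) {
  inv <- x$summary$mean_mse[x$summary$method == "inverse"]
  out <- tibble::tibble(task = x$which, n_instances = x$n * length(x$noise_levels))
  for (m in setdiff(x$methods, "inverse")) {
    if (length(inv)) {
      out[[paste0("fold_", m)]] <-
        x$summary$mean_mse[x$summary$method == m] / inv
    }
  }
  out
}

#' Tidiers for benchmark results
#'
#' `tidy()` returns the per-instance MSE table; `glance()` a one-row
#' summary with fold changes of each baseline's mean MSE over the
#' inverse method's.
#'
#' @param x A `rate_benchmark`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rate_benchmark <- function(x, ...) x$results

#' Plot benchmark error distributions
#'
#' Mean MSE per method with 95% confidence intervals, log scale.
#'
#' @param object A `rate_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$method, .data$mean_mse)) +
    ggplot2::geom_col(fill = "#1b9e91", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_mse - .data$ci_half, .Machine$double.xmin),
      ymax = .data$mean_mse + .data$ci_half), width = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "mean MSE (log scale)",
                  title = paste("Reconstruction error:", object$which)) +
    ggplot2::theme_minimal()
}

#' Hyperparameter and robustness sensitivity sweep
#'
#' Reruns a reduced benchmark at each grid value of one parameter,
#' holding everything else fixed. For `"gamma_mismatch"` the simulator
#' uses the grid value as the true degradation rate while estimators
#' assume `gamma = 0`, probing the cost of underestimating reporter
#' degradation.
#'
#' @param parameter One of `"delta"`, `"gamma_mismatch"`,
#'   `"sg_window"`, `"eps_L"`, `"lambda"`.
#' @param grid Values to sweep (nonempty).
#' @param which `"growth"` or `"expression"`.
#' @param n Instances per noise level per grid point (default 20).
#' @param ... Passed to [run_benchmark()].
#' @return Tibble with `parameter`, `value`, `method`, `mean_mse`.
#' @export
sensitivity_sweep <- function(parameter = c("delta", "gamma_mismatch",
                                            "sg_window", "eps_L", "lambda"),
                              grid, which = "growth", n = 20L, ...) {
  parameter <- match.arg(parameter)
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  rows <- lapply(grid, function(v) {
    args <- list(which = which, n = n, ...)
    args[[switch(parameter,
                 delta = "delta", lambda = "lambda", sg_window = "sg_window",
                 eps_L = "eps_insignificant", gamma_mismatch = "gamma_true")]] <- v
    if (parameter == "gamma_mismatch") args$gamma_assumed <- 0
    if (is.null(args$methods)) {
      args$methods <- switch(parameter,
                             sg_window = "indirect_sg",
                             eps_L = "direct",
                             c("inverse"))
    }
    bm <- do.call(run_benchmark, args)
    dplyr::mutate(bm$summary[, c("method", "mean_mse")],
                  parameter = parameter, value = v, .before = 1)
  })
  dplyr::bind_rows(rows)
}
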