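#' Growth-rate peak time
#'
#' Argmax of a reconstructed growth rate on a dense grid (step 0.01 h),
#' used to synchronize expression profiles across wells and
#' experiments; ties break to the earliest time.
#'
#' @param fit A `rate_fit` for the growth rate.
#' @param t_range Search interval in hours; defaults to the fit's data
#'   span.
#' @return The peak time `t0` in hours.
#' @export
peak_time <- function(fit, t_range = NULL) {
  stopifnot(inherits(fit, "rate_fit"))
  if (is.null(t_range)) {
    t_range <- if (!is.null(fit$data)) range(fit$data$time) else
      c(0, if (inherits(fit$profile, "basis_profile")) fit$profile$t_end
        else max(fit$profile$time))
  }
  grid <- seq(t_range[1], t_range[2], by = 0.01)
  v <- rate_at(fit, grid)
  if (max(v) - min(v) < 1e-9) abort("No identifiable peak: profile is flat.")
  grid[which.max(v)]
}

#' Synchronize and z-normalize a rate profile
#'
#' Shifts time to `tau = t - t0` (so `tau = 0` is the growth-rate peak)
#' and standardizes the rate by subtracting its mean and dividing by
#' its population (divide-by-n) standard deviation over the full
#' reconstructed window.
#'
#' @param profile Data frame with columns `time` and `rate` (or
#'   `value`).
#' @param t0 Synchronization time in hours.
#' @return A tibble (`tau`, `z`) with mean(z) = 0 and sd_n(z) = 1.
#' @export
normalize_profile <- function(profile, t0) {
  ycol <- if ("rate" %in% names(profile)) "rate" else "value"
  v <- profile[[ycol]]
  if (length(v) < 3) abort("Need at least 3 points.")
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-300) abort("Zero variance: cannot z-normalize.")
  tibble::tibble(tau = profile$time - t0, z = (v - mean(v)) / s)
}

fit_growth_by_method <- function(series, method, delta, lambda, lambda_grid,
                                 dcfg, icfg) {
  switch(method,
    inverse = {
      lam <- if (identical(lambda, "lcurve")) {
        as.numeric(lambda_lcurve(series, lambda_grid, "growth", delta = delta))
      } else lambda
      fit_growth(series, delta = delta, lambda_reg = lam)
    },
    direct = suppressWarnings(direct_growth(series, dcfg)),
    indirect_sg = indirect_growth(series, icfg),
    indirect_zerophase = indirect_growth(
      series, indirect_config(filter_kind = "zerophase_butterworth")))
}

fit_expression_by_method <- function(fluor, biomass, method, gamma, delta,
                                     lambda, lambda_grid, dcfg, icfg) {
  switch(method,
    inverse = {
      lam <- if (identical(lambda, "lcurve")) {
        as.numeric(lambda_lcurve(fluor, lambda_grid, "expression", delta = delta,
                                 biomass = biomass, gamma = gamma))
      } else lambda
      fit_expression(fluor, biomass, gamma = gamma, delta = delta,
                     lambda_reg = lam)
    },
    direct = direct_expression(fluor, biomass, gamma, dcfg),
    indirect_sg = indirect_expression(fluor, biomass, gamma, icfg),
    indirect_zerophase = indirect_expression(
      fluor, biomass, gamma,
      indirect_config(filter_kind = "zerophase_butterworth")))
}

#' Characterize one sample's expression dynamics
#'
#' The per-well pipeline: background-corrected OD is fitted for the
#' growth rate, the growth-rate peak gives the synchronization time
#' `t0`, the reporter channel is fitted for the expression rate, and
#' the expression profile is shifted to `tau = t - t0` and
#' z-normalized. Wells are fitted independently and their normalized
#' profiles aggregated (mean and standard deviation) on a common `tau`
#' grid (intersection of replicate ranges, step 0.1 h, linear
#' interpolation). Replicate-level failures are logged and excluded;
#' with fewer than 3 surviving replicates the sample is marked
#' unreliable.
#'
#' @param ds A background-corrected [plate_dataset()] (uncorrected
#'   input is corrected automatically).
#' @param sample Sample identifier present in the metadata.
#' @param channel Fluorescence channel to characterize.
#' @param method One of `"inverse"`, `"direct"`, `"indirect_sg"`,
#'   `"indirect_zerophase"`.
#' @param delta Basis spacing (inverse method), hours.
#' @param lambda Regularization: numeric, or `"lcurve"` to select per
#'   well by the L-curve method.
#' @param lambda_grid Grid used when `lambda = "lcurve"`.
#' @param gamma Reporter degradation rate per hour.
#' @param direct_cfg,indirect_cfg Baseline configurations.
#' @return An object of class `sample_profile`: `mean` (tibble `tau`,
#'   `z_mean`, `z_sd`, `n`), `replicates` (long tibble), `growth_fits`,
#'   `t0`, and flags.
#' @export
characterize_sample <- function(ds, sample, channel, method = "inverse",
                                delta = 1, lambda = "lcurve",
                                lambda_grid = 10^seq(-6, 2), gamma = 0,
                                direct_cfg = direct_config(),
                                indirect_cfg = indirect_config()) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (!isTRUE(attr(ds, "corrected"))) ds <- subtract_background(ds)
  wells <- unique(ds$measurements$well[ds$measurements$sample == sample])
  if (!length(wells)) abort(paste0("Sample not found: ", sample))

  reps <- list(); fits <- list(); t0s <- numeric(0); failures <- character(0)
  for (w in wells) {
    res <- tryCatch({
      od <- well_series(ds, w, "OD")
      fl <- well_series(ds, w, channel)
      gfit <- fit_growth_by_method(od, method, delta, lambda, lambda_grid,
                                   direct_cfg, indirect_cfg)
      t0 <- peak_time(gfit)
      efit <- fit_expression_by_method(fl, od, method, gamma, delta, lambda,
                                       lambda_grid, direct_cfg, indirect_cfg)
      grid <- fl$time
      prof <- tibble::tibble(time = grid, rate = rate_at(efit, grid))
      nz <- normalize_profile(prof, t0)
      list(nz = nz, gfit = gfit, t0 = t0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(w, ": ", conditionMessage(res)))
      next
    }
    reps[[w]] <- dplyr::mutate(res$nz, replicate = w, .before = 1)
    fits[[w]] <- res$gfit
    t0s[w] <- res$t0
  }
  if (length(failures)) {
    warn(paste0("Excluded replicate(s):\n  ", paste(failures, collapse = "\n  ")))
  }
  if (!length(reps)) abort("All replicates failed.")
  reliable <- length(reps) >= 3

  lo <- max(vapply(reps, function(r) min(r$tau), numeric(1)))
  hi <- min(vapply(reps, function(r) max(r$tau), numeric(1)))
  tau_grid <- seq(ceiling(lo * 10) / 10, floor(hi * 10) / 10, by = 0.1)
  zmat <- vapply(reps, function(r) interp(r$tau, r$z, tau_grid),
                 numeric(length(tau_grid)))
  zmat <- matrix(zmat, nrow = length(tau_grid))
  mean_tbl <- tibble::tibble(
    tau = tau_grid,
    z_mean = rowMeans(zmat),
    z_sd = apply(zmat, 1, stats::sd),
    n = length(reps))

  structure(list(mean = mean_tbl, replicates = dplyr::bind_rows(reps),
                 growth_fits = fits, t0 = t0s, sample = sample,
                 channel = channel, method = method, reliable = reliable,
                 failures = failures),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s / %s via %s: %d replicates%s\n",
              x$sample, x$channel, x$method, length(x$t0),
              if (x$reliable) "" else " [unreliable: < 3 replicates]"))
  invisible(x)
}

#' @rdname tidy.sample_profile
#' @export
glance.sample_profile <- function(x, ...) {
  tibble::tibble(sample = x$sample, channel = x$channel, method = x$method,
                 n_replicates = length(x$t0), reliable = x$reliable,
                 t0_mean = mean(x$t0), t0_sd = stats::sd(x$t0))
}

#' Tidiers for sample characterizations
#'
#' `tidy()` returns the mean normalized profile; `glance()` a one-row
#' summary.
#'
#' @param x A `sample_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sample_profile <- function(x, ...) {
  dplyr::mutate(x$mean, sample = x$sample, channel = x$channel,
                method = x$method)
}

#' Plot a normalized expression profile
#'
#' Mean z-normalized expression rate against `tau` (hours from the
#' growth-rate peak), with a +/- 1 sd ribbon across replicates.
#'
#' @param object A `sample_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_profile <- function(object, ...) {
  ggplot2::ggplot(object$mean, ggplot2::aes(.data$tau, .data$z_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$z_mean - .data$z_sd,
                                      ymax = .data$z_mean + .data$z_sd),
                         fill = "#1b9e91", alpha = 0.25) +
    ggplot2::geom_line(color = "#1b9e91") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = expression(tau ~ "(h from growth-rate peak)"),
                  y = "z-normalized expression rate",
                  title = paste0(object$sample, " / ", object$channel)) +
    ggplot2::theme_minimal()
}

#' Compare a normalized profile to a reference
#'
#' Ratiometric characterization: interpolates both z-profiles to a
#' common `tau` grid (step 0.1 h over the overlap, which must span at
#' least 4 h) and reports the RMSD and Pearson correlation. A negative
#' correlation indicates the profile inverted its relationship with
#' growth relative to the reference.
#'
#' @param profile,reference `sample_profile` objects, or tibbles with
#'   columns `tau` and `z` (or `z_mean`).
#' @return One-row tibble: `rmsd`, `correlation`, `overlap_h`,
#'   `n_points`.
#' @export
compare_to_reference <- function(profile, reference) {
  as_tz <- function(x) {
    if (inherits(x, "sample_profile")) x <- x$mean
    zc <- if ("z" %in% names(x)) "z" else "z_mean"
    tibble::tibble(tau = x$tau, z = x[[zc]])
  }
  p <- as_tz(profile); r <- as_tz(reference)
  lo <- max(min(p$tau), min(r$tau)); hi <- min(max(p$tau), max(r$tau))
  if (hi - lo < 4) abort("Insufficient overlap: need >= 4 h of shared tau support.")
  grid <- seq(lo, hi, by = 0.1)
  zp <- interp(p$tau, p$z, grid); zr <- interp(r$tau, r$z, grid)
  tibble::tibble(rmsd = sqrt(mean((zp - zr)^2)),
                 correlation = stats::cor(zp, zr),
                 overlap_h = hi - lo, n_points = length(grid))
}
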