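test_that("exponential growth data recover rate and initial biomass", {
  tg <- seq(0, 6, by = 0.25)
  b <- tibble::tibble(time = tg, value = 0.01 * exp(0.5 * tg))
  fit <- fit_growth(b, lambda_reg = 0)
  expect_true(fit$converged)
  expect_equal(fit$init_value, 0.01, tolerance = 0.05)
  interior <- seq(1, 5, by = 0.25)
  expect_true(all(abs(rate_at(fit, interior) - 0.5) / 0.5 < 0.10))
})

test_that("constant biomass yields a zero growth rate", {
  tg <- seq(0, 24, by = 0.24)
  b <- tibble::tibble(time = tg, value = rep(0.3, length(tg)))
  fit <- fit_growth(b, lambda_reg = 0)
  expect_lt(max(rate_at(fit, tg)), 1e-6)
})

test_that("noiseless Gompertz growth is recovered to MSE below 1e-3", {
  gp <- gp_mid()
  fit <- fit_growth(noiseless_biomass(gp), lambda_reg = 0)
  expect_lt(profile_mse(fit, gp, MEAS_GRID), 1e-3)
})

test_that("basis-representable truths are recovered essentially exactly", {
  tg <- MEAS_GRID
  mu_true <- basis_profile(c(rep(0, 3), 0.2, 0.6, 0.7, 0.5, 0.3,
                             rep(0.05, 17)), 1, 24)
  b <- tibble::tibble(time = tg, value = forward_biomass(0.01, mu_true, tg))
  gfit <- fit_growth(b, lambda_reg = 0)
  expect_lt(profile_mse(gfit, mu_true, tg), 1e-6)

  phi_true <- basis_profile(c(rep(0.1, 8), 0.8, 1.2, 0.9, rep(0.2, 14)), 1, 24)
  y <- forward_fluorescence(0.05, phi_true, b, 0, tg)
  efit <- fit_expression(tibble::tibble(time = tg, value = y), b, lambda_reg = 0)
  expect_lt(profile_mse(efit, phi_true, tg), 1e-6)
})

test_that("zero fluorescence gives a zero expression rate", {
  b <- noiseless_biomass()
  f <- tibble::tibble(time = b$time, value = rep(0, nrow(b)))
  fit <- fit_expression(f, b, lambda_reg = 0)
  expect_lt(max(rate_at(fit, b$time)), 1e-8)
  expect_lt(fit$init_value, 1e-8)
})

test_that("linear fluorescence over constant biomass gives a constant rate", {
  tg <- seq(0, 24, by = 0.24)
  b <- tibble::tibble(time = tg, value = rep(1, length(tg)))
  f <- tibble::tibble(time = tg, value = 0.1 + 0.5 * tg)
  fit <- fit_expression(f, b, lambda_reg = 0)
  interior <- seq(3, 21, by = 0.5)
  expect_true(all(abs(rate_at(fit, interior) - 0.5) / 0.5 < 0.10))
})

test_that("noiseless random-walk expression is recovered to MSE below 1e-3", {
  for (seed in c(3, 7, 11)) {
    inst <- expression_instance(sigma = 0, seed = seed)
    fit <- fit_expression(inst$fluor, inst$biomass, lambda_reg = 0)
    expect_lt(profile_mse(fit, inst$truth, MEAS_GRID), 1e-3)
  }
})

test_that("mismatched grids and under-determination are rejected", {
  tg <- seq(0, 24, by = 0.24)
  b <- tibble::tibble(time = tg, value = rep(1, length(tg)))
  f <- tibble::tibble(time = tg + 0.01, value = rep(1, length(tg)))
  expect_error(fit_expression(f, b), "time grid")
  short <- tibble::tibble(time = 0:5, value = exp(0:5))
  expect_error(fit_growth(short, delta = 0.2), "Under-determined")
})

test_that("solution norm is non-increasing in the regularization weight", {
  set.seed(21)
  wl <- simulate_well(gp_mid(), 0, noise = noise_spec(0.05))
  b <- wl$biomass; b$value <- b$value - 0.1
  lams <- 10^seq(-5, 2)
  norms <- vapply(lams, function(l) {
    fit <- fit_growth(b, lambda_reg = l)
    sqrt(fit$init_value^2 + sum(fit$profile$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= abs(norms[-length(norms)]) * 0.01))
})

test_that("lambda grid scan returns the error-minimizing weight", {
  set.seed(22)
  insts <- lapply(1:5, function(i) {
    gp <- sample_gompertz()
    wl <- simulate_well(gp, 0, noise = noise_spec(0.05))
    b <- wl$biomass; b$value <- b$value - 0.1
    list(biomass = b, truth = gp)
  })
  one <- scan_lambda(insts[1], lambda_grid = 0.37, which = "growth")
  expect_equal(one$lambda, 0.37)

  dom <- scan_lambda(insts, lambda_grid = c(0, 1e30), which = "growth")
  expect_equal(dom$lambda, 0)

  sc <- scan_lambda(insts, lambda_grid = 10^seq(-5, 1), which = "growth")
  expect_equal(min(sc$table$mean_mse),
               sc$table$mean_mse[sc$table$lambda == sc$lambda])
  expect_error(scan_lambda(insts, numeric(0), "growth"), "nonempty")
})

test_that("L-curve selection behaves on clean data and rejects tiny grids", {
  b <- noiseless_biomass()
  grid <- 10^seq(-6, 2)
  lam <- lambda_lcurve(b, grid, which = "growth")
  expect_lte(as.numeric(lam), 1e-5)
  expect_error(lambda_lcurve(b, c(1e-3, 1), which = "growth"), "at least 5")
})

test_that("L-curve selection regularizes more as noise grows", {
  # With nonnegative basis weights the solution norm never explodes at
  # small lambda, so the L-curve has no sharp under-regularization
  # corner; what it reliably does is move the selection up with noise.
  set.seed(23)
  grid <- 10^seq(-6, 2)
  gp <- sample_gompertz()
  lam0 <- as.numeric(lambda_lcurve(noiseless_biomass(gp), grid,
                                   which = "growth"))
  picks <- vapply(1:5, function(i) {
    wl <- simulate_well(gp, 0, noise = noise_spec(0.1))
    b <- wl$biomass; b$value <- b$value - 0.1
    as.numeric(lambda_lcurve(b, grid, which = "growth"))
  }, numeric(1))
  expect_true(all(picks %in% grid))
  expect_true(all(picks > lam0))
})
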