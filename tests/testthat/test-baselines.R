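test_that("direct growth inversion recovers smooth closed forms", {
  tg <- seq(0, 6, by = 0.25)
  b <- tibble::tibble(time = tg, value = 0.01 * exp(0.5 * tg))
  fit <- direct_growth(b)
  interior <- fit$profile$rate[5:20]
  expect_true(all(abs(interior - 0.5) / 0.5 < 0.05))

  bc <- tibble::tibble(time = tg, value = rep(0.4, length(tg)))
  expect_lt(max(abs(direct_growth(bc)$profile$rate)), 1e-3)

  gp <- gp_mid()
  fitg <- direct_growth(noiseless_biomass(gp))
  expect_lt(profile_mse(fitg, gp, MEAS_GRID), 1e-2)
})

test_that("direct expression inversion recovers closed forms", {
  tg <- seq(0, 6, by = 0.25)
  b1 <- tibble::tibble(time = tg, value = rep(1, length(tg)))
  fconst <- tibble::tibble(time = tg, value = rep(0.2, length(tg)))
  expect_lt(max(abs(direct_expression(fconst, b1)$profile$rate)), 1e-3)

  flin <- tibble::tibble(time = tg, value = 0.1 + 0.5 * tg)
  fit <- direct_expression(flin, b1)
  expect_true(all(abs(fit$profile$rate[5:20] - 0.5) / 0.5 < 0.05))

  inst <- expression_instance(sigma = 0, seed = 3)
  fitx <- direct_expression(inst$fluor, inst$biomass)
  expect_lt(profile_mse(fitx, inst$truth, MEAS_GRID), 1e-2)
})

test_that("indirect growth estimation recovers closed forms", {
  tg <- seq(0, 6, by = 0.25)
  b <- tibble::tibble(time = tg, value = 0.01 * exp(0.5 * tg))
  fit <- indirect_growth(b)
  expect_true(all(abs(fit$profile$rate[5:20] - 0.5) / 0.5 < 0.05))

  bc <- tibble::tibble(time = tg, value = rep(0.4, length(tg)))
  expect_lt(max(abs(indirect_growth(bc)$profile$rate)), 1e-9)

  expect_error(indirect_growth(b, indirect_config(sg_window = 51)), "window")
})

test_that("indirect early-phase growth estimates dip below zero under noise", {
  set.seed(31)
  neg <- 0
  for (i in 1:100) {
    gp <- sample_gompertz()
    wl <- simulate_well(gp, 0, noise = noise_spec(0.1))
    b <- wl$biomass; b$value <- b$value - 0.1
    fit <- indirect_growth(b)
    early <- fit$profile$rate[fit$profile$time < 5]
    if (min(early) < 0) neg <- neg + 1
  }
  expect_gte(neg / 100, 0.5)
})

test_that("indirect expression estimation recovers closed forms", {
  tg <- seq(0, 6, by = 0.25)
  b1 <- tibble::tibble(time = tg, value = rep(1, length(tg)))
  fconst <- tibble::tibble(time = tg, value = rep(0.2, length(tg)))
  expect_lt(max(abs(indirect_expression(fconst, b1)$profile$rate)), 1e-9)

  flin <- tibble::tibble(time = tg, value = 0.1 + 0.5 * tg)
  fit <- indirect_expression(flin, b1)
  expect_true(all(abs(fit$profile$rate[5:20] - 0.5) / 0.5 < 0.05))

  # pure reporter decay with a known gamma has zero synthesis rate
  tg2 <- seq(0, 24, by = 0.24)
  b2 <- tibble::tibble(time = tg2, value = rep(1, length(tg2)))
  fdec <- tibble::tibble(time = tg2, value = exp(-0.3 * tg2))
  fitd <- indirect_expression(fdec, b2, gamma = 0.3)
  expect_lt(max(abs(fitd$profile$rate[10:90])), 0.03)
})

test_that("zero-phase filter passes DC, kills high frequency, keeps ramps", {
  expect_equal(zerophase_filter(rep(3, 50)), rep(3, 50), tolerance = 1e-9)

  x <- rep(c(1, -1), 100)
  y <- zerophase_filter(x)
  expect_lt(max(abs(y[50:150])), 1 / 100)

  r <- seq(0, 10, length.out = 60)
  zr <- zerophase_filter(r)
  expect_lt(max(abs(zr[10:50] - r[10:50]) / r[10:50]), 0.01)

  expect_error(zerophase_filter(c(1, 2, 3), order = 2), "too short")
})

test_that("all methods agree on a noiseless slowly varying truth", {
  tg <- MEAS_GRID
  mu_true <- basis_profile(0.08 + 0.04 * sin(seq(0, 2 * pi, length.out = 25)),
                           1, 24)
  b <- tibble::tibble(time = tg, value = forward_biomass(0.05, mu_true, tg))
  interior <- tg[tg >= 3 & tg <= 21]
  truth <- basis_eval(mu_true, interior)
  scale2 <- mean(truth^2)
  fits <- list(inverse = fit_growth(b, lambda_reg = 0),
               direct = direct_growth(b),
               indirect_sg = indirect_growth(b),
               indirect_zerophase = indirect_growth(
                 b, indirect_config(filter_kind = "zerophase_butterworth")))
  for (m in names(fits)) {
    mse <- mean((rate_at(fits[[m]], interior) - truth)^2)
    expect_lt(mse / scale2, 0.10)
  }
})
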