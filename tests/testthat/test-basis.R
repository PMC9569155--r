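test_that("basis evaluation matches the Gaussian-sum definition", {
  p0 <- basis_profile(rep(0, 25), delta = 1, t_end = 24)
  expect_equal(basis_eval(p0, c(0, 3.7, 24)), c(0, 0, 0))

  w <- c(1, rep(0, 24))
  p1 <- basis_profile(w, delta = 1, t_end = 24)
  expect_equal(basis_eval(p1, 0), 1)
  expect_equal(basis_eval(p1, 1), exp(-1 / 2))

  expect_error(basis_eval(p1, NaN), "finite")
  expect_error(basis_eval(p1, Inf), "finite")
  expect_error(basis_profile(c(-1, rep(0, 24)), 1, 24), "nonnegative")
  expect_error(basis_profile(rep(1, 10), 1, 24), "length")
})

test_that("basis is nonnegative for nonnegative weights", {
  set.seed(1)
  tg <- seq(0, 24, length.out = 500)
  for (i in 1:20) {
    delta <- sample(c(0.5, 1, 2), 1)
    n <- floor(24 / delta) + 1
    p <- basis_profile(runif(n, 0, 3), delta, 24)
    expect_true(all(basis_eval(p, tg) >= 0))
  }
})

test_that("cumulative integral agrees with quadrature and is nondecreasing", {
  p0 <- basis_profile(rep(0, 25), 1, 24)
  expect_equal(basis_cumulative_integral(p0, c(0, 5, 24)), c(0, 0, 0))
  p <- basis_profile(runif(25), 1, 24)
  expect_equal(basis_cumulative_integral(p, 0), 0)
  expect_error(basis_cumulative_integral(p, -1), ">= 0")

  set.seed(2)
  tq <- seq(0, 24, by = 1e-3)
  for (i in 1:100) {
    delta <- sample(c(0.5, 1, 2), 1)
    n <- floor(24 / delta) + 1
    p <- basis_profile(runif(n, 0, 2), delta, 24)
    ci <- basis_cumulative_integral(p, c(3, 11, 24))
    expect_true(all(diff(basis_cumulative_integral(p, c(0, 3, 11, 24))) >= 0))
    f <- basis_eval(p, tq)
    quad <- c(0, cumsum(diff(tq) * (f[-length(f)] + f[-1]) / 2))
    ref <- quad[match(c(3, 11, 24), tq)]
    expect_lt(max(abs(ci - ref) / pmax(ref, 1e-12)), 1e-6)
  }
})

test_that("single-bump integral matches fine brute-force quadrature", {
  p <- basis_profile(c(1, rep(0, 24)), 1, 24)
  tq <- seq(0, 20, by = 1e-5)
  f <- exp(-tq^2 / 2)
  quad <- sum(diff(tq) * (f[-length(f)] + f[-1]) / 2)
  expect_lt(abs(basis_cumulative_integral(p, 20) - quad), 1e-8)
})

test_that("steepest basis slope scales as 1/sqrt(delta)", {
  for (delta in c(0.25, 1, 4)) {
    tg <- seq(-4 * sqrt(delta), 4 * sqrt(delta), by = 1e-4)
    g <- exp(-tg^2 / (2 * delta))
    slope <- max(abs(diff(g) / diff(tg)))
    expect_equal(slope, exp(-1 / 2) / sqrt(delta), tolerance = 1e-6)
  }
})

test_that("forward biomass matches closed forms and an Euler oracle", {
  tg <- MEAS_GRID
  p0 <- basis_profile(rep(0, 25), 1, 24)
  expect_equal(forward_biomass(0.05, p0, tg), rep(0.05, length(tg)))
  expect_error(forward_biomass(-1, p0, tg), "> 0")

  # flat-weight basis approximates a constant rate away from the ends
  pflat <- basis_profile(rep(0.2, 25), 1, 24)
  cval <- basis_eval(pflat, 12)
  interior <- tg[tg >= 4 & tg <= 20]
  Bc <- forward_biomass(0.01, pflat, interior)
  # compare growth increments to the exponential closed form
  expect_lt(max(abs(log(Bc / Bc[1]) - cval * (interior - interior[1]))) /
              (cval * 16), 0.01)

  set.seed(3)
  for (i in 1:5) {
    p <- basis_profile(runif(25, 0, 0.5), 1, 24)
    B <- forward_biomass(0.01, p, tg)
    dt <- 1e-3
    te <- seq(0, 24, by = dt)
    mu <- basis_eval(p, te)
    Be <- 0.01 * exp(c(0, cumsum((mu[-length(mu)] + mu[-1]) / 2 * dt)))
    idx <- round(tg / dt) + 1L
    expect_lt(max(abs(B - Be[idx]) / Be[idx]), 1e-3)
  }
})

test_that("forward fluorescence matches closed forms and an Euler oracle", {
  tg <- MEAS_GRID
  bconst <- tibble::tibble(time = tg, value = rep(1, length(tg)))
  p0 <- basis_profile(rep(0, 25), 1, 24)
  expect_equal(forward_fluorescence(0.2, p0, bconst, 0, tg), rep(0.2, length(tg)))

  # reporter decay closed form
  y <- forward_fluorescence(1, p0, bconst, gamma = 0.3, t_grid = tg)
  expect_lt(max(abs(y - exp(-0.3 * tg)) / exp(-0.3 * tg)), 1e-6)

  # constant biomass, near-constant rate: linear accumulation
  pflat <- basis_profile(rep(0.2, 25), 1, 24)
  cval <- basis_eval(pflat, 12)
  interior <- tg[tg >= 4 & tg <= 20]
  yl <- forward_fluorescence(0.1, pflat, bconst, 0, interior)
  expect_lt(max(abs(diff(yl) - cval * diff(interior))) / (cval * 0.24), 0.01)

  expect_error(forward_fluorescence(0.1, p0, bconst, 0, seq(0, 30, 1)),
               "support")

  # Euler oracle with a Gompertz biomass driver
  gp <- gp_mid()
  bio <- tibble::tibble(time = tg, value = gompertz_biomass(gp, tg))
  set.seed(4)
  for (gamma in c(0, 0.4)) {
    p <- basis_profile(runif(25, 0, 1), 1, 24)
    y <- forward_fluorescence(0.05, p, bio, gamma, tg)
    dt <- 1e-3
    te <- seq(0, 24, by = dt)
    bb <- approx(bio$time, bio$value, te)$y
    ph <- basis_eval(p, te)
    ye <- numeric(length(te)); ye[1] <- 0.05
    drive <- dt * bb * ph
    ye <- c(0.05, 0.05 * (1 - gamma * dt)^(seq_len(length(te) - 1)) +
              stats::filter(drive[-length(te)], 1 - gamma * dt, "recursive"))
    ref <- ye[round(tg / dt) + 1L]
    expect_lt(max(abs(y - ref) / pmax(abs(ref), 1e-6)), 1e-3)
  }
})
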