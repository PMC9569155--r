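make_plate <- function(sigma = 0, seed = 51, n_replicates = 4) {
  gp <- gp_mid()
  set.seed(seed)
  phi_v <- random_expression_profile(length(MEAS_GRID))
  simulate_plate(gp, tibble::tibble(time = MEAS_GRID, value = phi_v),
                 noise = noise_spec(sigma, seed = seed),
                 n_replicates = n_replicates)
}

test_that("plate CSV round-trips and ingestion is order-insensitive", {
  ds <- make_plate(sigma = 0.02)
  tmp <- file.path(tempdir(), "plate.csv")
  write_plate_csv(ds, tmp)
  back <- read_plate_csv(tmp)
  expect_equal(back$measurements, ds$measurements, tolerance = 1e-12)
  expect_equal(back$metadata$sample, ds$metadata$sample)

  shuf <- ds$measurements[sample(nrow(ds$measurements)), ]
  ds2 <- plate_dataset(shuf, ds$metadata)
  expect_equal(ds2$measurements, ds$measurements)

  expect_error(plate_dataset(ds$measurements[, -1], ds$metadata), "missing")
  dup <- rbind(ds$measurements, ds$measurements[1, ])
  expect_error(plate_dataset(dup, ds$metadata), "Duplicate")
})

test_that("channel names are canonicalized on ingestion", {
  ds <- make_plate()
  m <- ds$measurements
  m$channel[m$channel == "OD"] <- "od600"
  ds2 <- plate_dataset(m, ds$metadata)
  expect_true("OD" %in% ds2$measurements$channel)
  expect_false("OD600" %in% ds2$measurements$channel)
})

test_that("plates without controls load but refuse background correction", {
  ds <- make_plate()
  keep <- ds$metadata$sample[!ds$metadata$is_media_blank &
                               !ds$metadata$is_no_reporter_control]
  m <- ds$measurements[ds$measurements$sample %in% keep, ]
  md <- ds$metadata[ds$metadata$sample %in% keep, ]
  ds_nc <- plate_dataset(m, md)
  expect_s3_class(ds_nc, "plate_dataset")
  expect_error(subtract_background(ds_nc), "control")
})

test_that("noise-free plates background-correct exactly, and only once", {
  ds <- make_plate(sigma = 0)
  cor <- subtract_background(ds)
  blanks <- cor$measurements[cor$measurements$sample == "media_blank", ]
  expect_equal(blanks$value, rep(0, nrow(blanks)))
  norep_fl <- cor$measurements[cor$measurements$sample == "no_reporter" &
                                 cor$measurements$channel != "OD", ]
  expect_equal(norep_fl$value, rep(0, nrow(norep_fl)))
  expect_error(subtract_background(cor), "already")
})

test_that("corrected control wells scatter around zero", {
  set.seed(53)
  ctrl <- simulate_controls(noise_spec(0.05), n_wells = 100)
  cor <- subtract_background(ctrl)
  bl <- cor$measurements[cor$measurements$sample == "media_blank" &
                           cor$measurements$channel == "OD", ]
  se <- sd(bl$value) / sqrt(nrow(bl))
  expect_lt(abs(mean(bl$value)), 3 * se)
})

test_that("peak time finds the growth-rate maximum", {
  gp <- gp_mid()
  fit <- fit_growth(noiseless_biomass(gp), lambda_reg = 0)
  t_peak <- gp$lag + gp$a / (gp$mu_star * exp(1))
  expect_lt(abs(peak_time(fit) - t_peak), 0.25)

  one <- basis_profile(c(rep(0, 7), 1, rep(0, 17)), 1, 24)
  f1 <- kinverse:::new_rate_fit(one, NA, NA, 1, 0, "inverse", TRUE,
                                tibble::tibble(time = MEAS_GRID,
                                               value = NA_real_))
  expect_equal(peak_time(f1), 7, tolerance = 1e-8)

  dec <- tibble::tibble(time = MEAS_GRID, rate = exp(-MEAS_GRID))
  f2 <- kinverse:::new_rate_fit(dec, NA, NA, NA, 0, "direct", TRUE,
                                tibble::tibble(time = MEAS_GRID,
                                               value = NA_real_))
  expect_equal(peak_time(f2), 0)

  flat <- tibble::tibble(time = MEAS_GRID, rate = rep(1, length(MEAS_GRID)))
  f3 <- kinverse:::new_rate_fit(flat, NA, NA, NA, 0, "direct", TRUE, NULL)
  expect_error(peak_time(f3, c(0, 24)), "peak")
})

test_that("profile normalization is a synchronized z-score", {
  tg <- seq(0, 24, 0.24)
  prof <- tibble::tibble(time = tg, rate = sin(tg / 4) + 2)
  nz <- normalize_profile(prof, t0 = 5)
  expect_lt(abs(mean(nz$z)), 1e-8)
  expect_equal(sqrt(mean(nz$z^2)), 1, tolerance = 1e-8)
  expect_equal(nz$tau, tg - 5)

  aff <- prof; aff$rate <- 3.2 * prof$rate + 7
  expect_equal(normalize_profile(aff, 5)$z, nz$z, tolerance = 1e-10)
  neg <- prof; neg$rate <- -prof$rate
  expect_equal(normalize_profile(neg, 5)$z, -nz$z, tolerance = 1e-10)

  const <- tibble::tibble(time = tg, rate = rep(2, length(tg)))
  expect_error(normalize_profile(const, 5), "variance")
})

z_truth_profile <- function(seed = 51) {
  gp <- gp_mid()
  set.seed(seed)
  phi_v <- random_expression_profile(length(MEAS_GRID))
  t0 <- gp$lag + gp$a / (gp$mu_star * exp(1))
  normalize_profile(tibble::tibble(time = MEAS_GRID, rate = phi_v), t0)
}

test_that("low-noise synthetic plates recover the z-normalized truth", {
  ds <- make_plate(sigma = 0.01, n_replicates = 10)
  sp <- characterize_sample(ds, "sampleA", "RFP", method = "inverse",
                            lambda = 1e-4)
  expect_true(sp$reliable)
  ztruth <- z_truth_profile(51)
  cmp <- compare_to_reference(sp, tibble::tibble(tau = ztruth$tau,
                                                 z = ztruth$z))
  expect_lt(cmp$rmsd, 0.2)
  expect_gt(cmp$correlation, 0.9)
})

test_that("noise-free end-to-end characterization recovers the truth shape", {
  ds <- make_plate(sigma = 0, n_replicates = 3)
  sp <- characterize_sample(ds, "sampleA", "RFP", method = "inverse",
                            lambda = 0)
  # per-well reconstruction in rate units is at the noiseless-recovery
  # floor; the aggregated z-profile then matches the z-scored truth
  ztruth <- z_truth_profile(51)
  cmp <- compare_to_reference(sp, tibble::tibble(tau = ztruth$tau,
                                                 z = ztruth$z))
  expect_lt(cmp$rmsd, 0.2)
  expect_gt(cmp$correlation, 0.98)
})

test_that("a uniformly delayed plate yields the same normalized profiles", {
  ds <- make_plate(sigma = 0.01, n_replicates = 3, seed = 52)
  delayed <- ds$measurements
  delayed$time <- delayed$time + 1
  ds1 <- plate_dataset(delayed, ds$metadata)
  sp0 <- characterize_sample(ds, "sampleA", "RFP", lambda = 1e-4)
  sp1 <- characterize_sample(ds1, "sampleA", "RFP", lambda = 1e-4)
  cmp <- compare_to_reference(sp0, sp1)
  expect_lt(cmp$rmsd, 0.05)
})

test_that("all-zero fluorescence is excluded rather than normalized", {
  ds <- make_plate(sigma = 0, n_replicates = 3)
  m <- ds$measurements
  m$value[m$sample == "sampleA" & m$channel == "RFP"] <- 0
  ds0 <- plate_dataset(m, ds$metadata)
  expect_error(suppressWarnings(
    characterize_sample(ds0, "sampleA", "RFP", lambda = 0)), "failed")
})

test_that("reference comparison has the right fixed points and null", {
  ztruth <- z_truth_profile(51)
  self <- compare_to_reference(ztruth, ztruth)
  expect_equal(self$rmsd, 0)
  expect_equal(self$correlation, 1)
  flip <- ztruth; flip$z <- -flip$z
  expect_equal(compare_to_reference(ztruth, flip)$correlation, -1)

  short <- ztruth[ztruth$tau < min(ztruth$tau) + 2, ]
  expect_error(compare_to_reference(ztruth, short), "overlap")

  set.seed(54)
  tau <- seq(-5, 5, by = 0.1)
  hits <- 0; n_trial <- 1000
  for (i in seq_len(n_trial)) {
    a <- tibble::tibble(tau = tau, z = scale(rnorm(length(tau)))[, 1])
    b <- tibble::tibble(tau = tau, z = scale(rnorm(length(tau)))[, 1])
    if (abs(compare_to_reference(a, b)$correlation) < 0.5) hits <- hits + 1
  }
  expect_gte(hits / n_trial, 0.95)
})
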