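# Shared fixtures. Heavy benchmark runs are computed once per session
# and memoized for the acceptance blocks.

MEAS_GRID <- seq(0, 24, by = 0.24)

# A mid-box Gompertz model used across tests.
gp_mid <- function() gompertz_params(mu_star = 0.8, lag = 2)

# Background-corrected noiseless Gompertz biomass measurements.
noiseless_biomass <- function(params = gp_mid()) {
  wl <- simulate_well(params, 0, noise = noise_spec(0))
  b <- wl$biomass
  b$value <- b$value - 0.1
  b
}

# Background-corrected (biomass, fluor, truth) for a random-walk
# expression profile over Gompertz growth.
expression_instance <- function(sigma = 0, seed = 3, params = gp_mid()) {
  set.seed(seed)
  phi_v <- random_expression_profile(length(MEAS_GRID))
  wl <- simulate_well(params, tibble::tibble(time = MEAS_GRID, value = phi_v),
                      noise = noise_spec(sigma))
  b <- wl$biomass; b$value <- b$value - 0.1
  f <- wl$fluor; f$value <- f$value - 0.1
  list(biomass = b, fluor = f,
       truth = tibble::tibble(time = MEAS_GRID, rate = phi_v))
}

# Memoized full-scale benchmarks shared by the acceptance tests.
.bench_cache <- new.env(parent = emptyenv())

bench_cached <- function(task) {
  key <- paste0("bm_", task)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- run_benchmark(
      task, n = 100L, noise_levels = c(0.01, 0.05, 0.1),
      methods = c("inverse", "direct", "indirect_sg", "indirect_zerophase"),
      seed = 101L)
  }
  .bench_cache[[key]]
}

bench_fold <- function(bm, method) {
  s <- bm$summary
  s$mean_mse[s$method == method] / s$mean_mse[s$method == "inverse"]
}
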