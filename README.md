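# kinverse

Reconstruction of time-varying microbial **growth rates** μ(t) and
fluorescent-reporter **gene expression rates** φ(t) from noisy kinetic
plate-reader data (optical density + fluorescence), for systems and
synthetic biologists characterizing transcription units and growth
phenotypes.

## The problem and the method

A bulk culture with a constitutive reporter follows

    dB/dt = mu(t) B,        dy/dt = B(t) phi(t) - gamma y,

where B is biomass (OD), y reporter fluorescence, and γ the reporter
degradation rate (0 for stable fluorescent proteins). Estimating μ(t)
and φ(t) from sampled, background-contaminated, noisy B and y is an
ill-posed inverse problem: at low biomass, smoothing-and-differentiating
or dividing by the measured signal amplifies noise catastrophically.

`kinverse` represents each rate on a **Gaussian basis**,

    f(t) ≈ Σ_k f̂_k exp(−(t − kΔ)² / (2Δ)),   k = 0 … ⌊T/Δ⌋,

(spacing and variance parameter Δ, default 1 h — the timescale of
protein synthesis) and solves the **Tikhonov-regularized nonlinear
least-squares** problems

    min_Θ ‖B̄ − F(Θ)‖² + λ‖Θ‖²,   Θ = [B₀, μ̂]
    min_Θ ‖ȳ − G(Θ, B̄)‖² + λ‖Θ‖²,   Θ = [y₀, φ̂]

with nonnegative weights (rates are strictly positive), analytic
Jacobians, and a bound-constrained solver (Levenberg–Marquardt plus an
exact nonnegative-least-squares polish). λ is chosen by an oracle grid
scan on simulations or by the L-curve on experimental data.

Also included, behind the same interface:

* **Baselines**: direct linear inversion (insignificant-value rule
  ε_L), indirect Savitzky–Golay smooth-and-differentiate, and a
  zero-phase Butterworth variant (order 2, cutoff 4/33).
* **Simulator**: Gompertz growth (μ\* ~ U[0.5,1]/h, lag ~ U[0,4] h,
  B₀ = 0.01, B\* = 1), smoothed lognormal random-walk expression
  profiles, multiplicative noise, backgrounds B′ = y′ = 0.1, and
  control wells.
* **Benchmark**: per-method MSE distributions, fold changes, Welch
  tests, hyperparameter/γ/Δ sensitivity sweeps.
* **Plate pipeline**: long-format CSV I/O, background correction from
  control wells, per-well fitting, growth-peak synchronization
  (τ = t − t₀), z-normalization, and ratiometric comparison to a
  reference transcription unit.

## Worked example

```r
library(kinverse)

set.seed(7)
gp <- sample_gompertz()                      # random ground truth
#> <gompertz_params> mu* = 0.994 /h, lag = 1.59 h, B0 = 0.01, B* = 1

wl <- simulate_well(gp, 0, noise = noise_spec(0.05))   # noisy plate well
biomass <- dplyr::mutate(wl$biomass, value = value - 0.1)  # background-correct

fit <- fit_growth(biomass, delta = 1, lambda_reg = 1e-3)
glance(fit)
#> # A tibble: 1 × 6
#>   method  lambda_reg delta init_value residual_norm converged
#>   <chr>        <dbl> <dbl>      <dbl>         <dbl> <lgl>
#> 1 inverse      0.001     1    0.00787         0.371 TRUE

profile_mse(fit, gp, biomass$time)   # MSE vs the known mu(t), (per hour)^2
#> [1] 0.00926
peak_time(fit)                       # reconstructed growth-rate peak (h)
#> [1] 3.92
```

The reconstruction recovers the initial biomass (0.0079 vs true 0.01),
tracks μ(t) with an MSE of ~0.009 (h⁻²) at 5% multiplicative noise, and
places the growth-rate peak at 3.9 h against the analytic
lag + A/(μ\*e) = 3.3 h. `tidy(fit)` returns the rate curve as a tibble;
`autoplot(fit)` draws it. `run_benchmark()`, `characterize_sample()` and
`compare_to_reference()` follow the same tidy conventions.

A thin CLI wraps the same functions:

```sh
exec/kinverse benchmark --task growth --n 100 --noise 0.01,0.05,0.1 --seed 1 --out results/
exec/kinverse characterize --data plate.csv --sample sampleA --channel RFP --out profile.csv
```

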