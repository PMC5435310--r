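# ctscr — continuous-time spatial capture-recapture

`ctscr` estimates the spatial distribution and abundance of individually
identifiable animals surveyed by *continuous-time* detectors — motion-activated
camera traps, acoustic recorders — using the exact detection timestamps rather
than detection histories discretized into occasions. Discretization is
subjective (the "midnight problem") and throws away information; here every
recorded time enters the likelihood.

The package is for ecologists and biostatisticians running camera-trap style
surveys who want density surfaces, abundance maps, and estimates of temporal
behavior (e.g. nocturnality) from one coherent model.

## The model

A population of `N` animals lives in a planar region `B`. Each animal `i` has a
latent **activity center** `s_i`, fixed for the survey (spatial closure). The
centers follow a spatial Poisson process with log-linear intensity

    log λ(s) = β′ v(s),        Λ(B) = ∫_B λ(s) ds,   N ~ Poisson(Λ(B))

where `v(s)` are density covariates. Detections of animal `i` at trap `k`
(location `x_k`, operating over `(0, T_k]`) form an inhomogeneous temporal
Poisson process with intensity

    φ(t, s_i, x_k) = ψ_k · γ(t) · exp(−‖s_i − x_k‖² / 2σ²)

with trap baseline `log ψ_k = α′ w_k`, temporal modulation
`log γ(t) = ξ′ z(t)` (for tigers: `z(t)` = daytime indicator), and Gaussian
movement scale `σ`. Animals never detected anywhere (`n₀ = N − n` of them) are
handled by data augmentation through `π₀`, the probability of total
non-detection, and the model is fitted by Metropolis-within-Gibbs MCMC: random
walks on `(β, α, ξ, log σ)` and on each activity center, and an exact Gibbs
draw `n₀ ~ Poisson(π₀ Λ(B))`. A **restricted** (time-homogeneous) variant uses
only the counts `y_ik ~ Poisson(T_k φ)`; in it `γ` is not identifiable and is
absorbed into `α₀`.

Spatial integrals (`Λ(B)`, `π₀`) use midpoint quadrature on a habitat-masked
grid; posterior prediction of the unobserved centers (cell weights
`∝ λ exp(−ΣΦ)`) yields per-cell abundance maps `N(B_m)`, densities per unit
area, and home-range areas `π σ² χ²₂(0.95)`.

## Worked example

Simulate a survey from the package's reference design — a 5.2 × 5.2 region
(Λ(B) ≈ 147 expected animals) with a centered 10 × 10 trap array running 30
days, half day / half night, a daytime effect ξ = −1 and σ = 0.4 — then refit
it:

```r
library(ctscr)
cfg   <- sim_config()                       # generating values: β=(1.4,0.8), α=(−0.7,1.0), ξ=−1, σ=0.4
sim   <- simulate_study(cfg, seed = 7)
print(sim$survey)
#> scr_survey: 174 individuals, 100 traps, 8024 detections

chain <- run_chain(sim$survey, sim$domain, sim$schedule,
                   config = scr_mcmc_config(iterations = 1200, burn_in = 200, seed = 7))
summarize_chain(chain)
#>   parameter       mean       q2.5      q97.5         mcse
#> 1     beta0  1.6092895  1.3903562  1.7996074 0.0113294769
#> 2     beta1  0.7478273  0.5806367  0.9522316 0.0090250763
#> 3    alpha0 -0.7133588 -0.7489209 -0.6844760 0.0021065706
#> 4    alpha1  0.9879601  0.9636417  1.0169152 0.0013726642
#> 5        xi -1.0124118 -1.0546796 -0.9664577 0.0017810779
#> 6     sigma  0.4048579  0.3997700  0.4099306 0.0002777786
#> 7        n0  0.0300000  0.0000000  1.0000000 0.0046922850
```

Reading the output: the posterior means sit close to the generating values —
the day/night effect `xi ≈ −1.01` says daytime detection rates are
`exp(−1.01) ≈ 36%` of nighttime rates, and `sigma ≈ 0.40` is the movement
scale in map units. `n0 ≈ 0` because this compact design leaves almost no
animal undetected. Downstream:

```r
density_estimate(chain, sim$domain)   # animals per unit area: 6.44 (95% CI 6.43–6.47)
home_range_area(0.405)                # 95% home range ≈ 3.09 units²
map <- abundance_map(chain, sim$domain, sim$traps, sim$schedule, seed = 1)
```

A shell interface wrapping the same functions lives at `inst/cli/ctscr.R`
(subcommands `simulate`, `fit`, `predict`, `summarize`, `recover`).

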