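---
title: "Methods: the continuous-time SCR model in ctscr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the continuous-time SCR model in ctscr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`ctscr` fits a hierarchical model with two coupled point processes.

**Spatial layer.** Activity centers of the `N` animals in a region `B` are a
Poisson process with intensity `log λ(s) = β′v(s)`, so `N ~ Poisson(Λ(B))`
with `Λ(B) = ∫_B λ`. The assumptions here are spatial closure (centers fixed
during the survey), independence between animals, and log-linearity of
density in the covariates. `v(s)` always contains an intercept, so a
covariate-free model is the constant-density special case.

**Temporal layer.** Conditional on its center `s_i`, the detections of animal
`i` at trap `k` are an inhomogeneous Poisson process on `(0, T_k]` with rate
`φ(t) = ψ_k γ(t) exp(−‖s_i − x_k‖²/2σ²)`. This asserts (a) a Gaussian
distance-decay of encounter rate, (b) multiplicative trap (`ψ_k = exp(α′w_k)`)
and time (`γ(t) = exp(ξ′z(t))`) effects, and (c) conditional independence of
detections across traps and over time — no trap-happiness or animal
interaction. Integrating the rate gives the expected count
`Φ(T_k, s_i, x_k)`; the likelihood of a (count, times) pair is
`(1/y!) exp(−Φ) Π_j φ(t_j)`.

**Augmentation.** Only `n` animals are ever detected. The probability that an
animal living in `B` escapes all traps is
`π₀ = Λ(B)⁻¹ ∫_B λ(s) exp(−Σ_k Φ(T_k, s, x_k)) ds`, and the number of
never-detected animals enters the posterior through the factor
`exp(−Λ)(π₀Λ)^{n₀}/n₀!` — a Poisson full conditional that we exploit as an
exact Gibbs step.

**Restricted model.** With `γ` constant, detection times are uniform on
`(0, T_k]` and carry no information; the model reduces to Poisson counts with
mean `T_k φ`. `γ` and the baseline intercept `α₀` are then jointly
unidentifiable, so the restricted parameterization drops `ξ` entirely and the
package refuses a restricted fit with `ξ` set. We use the count pmf
`(T_kφ)^y e^{−T_kφ}/y!` as the restricted likelihood, which makes the exact
identity *full = restricted − Σ_ik y_ik log T_k* hold at `ξ = 0`; the identity
is enforced in the test suite at 1e−10. When day/night rates truly differ but
the restricted model is fitted anyway with equal day/night durations, the
estimated baseline converges to the time-average of the rate, i.e. `α₀` is
biased by `log((1 + e^ξ)/2)` — about −0.38 at `ξ = −1`. The replicate
experiment reproduces this bias and its total loss of interval coverage.

## Parameters, units, defaults

| Parameter | Meaning | Units |
|---|---|---|
| `β` | log-density coefficients; `β₀` is log animals per unit area | log(1/area) |
| `α` | log baseline encounter-rate coefficients; `exp(α′w_k)` is detections per unit time at distance 0 | log(1/time) |
| `ξ` | temporal log-rate effects; `exp(ξ)` is the day:night rate ratio for a binary daytime indicator | — |
| `σ` | Gaussian movement scale | coordinate units |

Coordinates are planar/projected (e.g. km); the model is metric-Euclidean and
the package does no CRS handling — reproject before import. Times are
trap-relative on each trap's own clock, `(0, T_k]`; ISO timestamps are
converted at the I/O boundary using per-trap deployment starts, because the
likelihood is written per trap clock.

Priors default to independent Normal(0, 10²) on every `β, α, ξ` component —
weakly informative at the scale of log-rates — and Uniform(0, σ_max) on `σ`
with `σ_max` = half the domain diameter, a standard weak choice in SCR
practice. All are configurable via `scr_prior()`.

## MCMC design

Each iteration updates, in order: the blocks `β`, `α`, `ξ`, `log σ` by
random-walk Metropolis against log-likelihood + log-prior (the `log σ` walk
carries the Jacobian `σ` so the prior remains on the natural scale); the `n`
observed centers by per-animal Gaussian random walks, vectorized, with
proposals outside the habitat mask rejected (a zero-prior region); then the
exact `n₀` Gibbs draw. `n₀` comes last because its conditional depends only on
`θ`. Proposal scales adapt toward acceptance 0.44 (scalar) / 0.25 (vector,
centers) during burn-in only and are frozen afterwards, so the post-burn-in
kernel leaves the posterior invariant. Centers of never-detected animals are
*not* part of the chain state; they are predicted post hoc (below), which
keeps the state small and mixes better at no inferential cost.

Starting values are data-driven: detection-weighted trap centroids for
centers (snapped into habitat if needed), a moment-matched `σ` from
within-animal capture spread, `α₀` from the crude detection rate, `β₀` from
`log(n/|B|)`, zeros elsewhere. Reproducibility: each iteration reseeds from a
stream derived from (master seed, iteration), so the first `m` iterations of
a chain are identical whatever the total length — convenient for protocol
comparisons and enforced by a test.

The default protocol (1200 iterations, 200 burn-in) is deliberately short: the
posterior in detection-rich designs is sharp and the blocks mix within tens of
iterations. The batch-means MCSE reported by `summarize_chain()` makes the
residual Monte Carlo error visible; rerun longer if it matters.

## Numerical choices

- **Quadrature.** All spatial integrals are midpoint sums over the unmasked
  grid cells. The rule is exact for constant `λ` and, for the smooth surfaces
  used here, stable in the third digit under refinement;
  `check_quadrature()` warns when `Λ(B)` moves more than 0.5% under a 2×
  refinement. Masked cells are excluded from integrals, proposals and
  predictions.
- **Expected counts.** For piecewise-constant `z(t)` (the day/night case)
  `Φ = ψ_k e^{−d²/2σ²} Σ_seg e^{ξ′z} Δt` is exact; a panel-wise adaptive
  quadrature fallback (`zfun`) covers arbitrary temporal paths. The closed
  form is checked against segment-wise adaptive integration at 1e−8 on random
  configurations.
- **Mixed discretization.** Covariates of a *continuous* center are read from
  the grid cell containing it (the resolution of covariate knowledge), while
  distances use exact coordinates. `log(n₀!)` uses `lgamma`. Tied detection
  times — probability zero under the process, common in real data — are
  accepted with a warning.
- **Unobserved-center sampling** is cell-discrete with uniform within-cell
  jitter, using weights `λ_m exp(−Σ_k Φ_mk)`: exactly the discretization used
  for `π₀`, so prediction and augmentation agree at the quadrature
  resolution. One fresh draw of all `n₀` centers is made per retained
  iteration, averaging maps over the full posterior.

## The simulator and what it does (not) emulate

`sim_config()` encodes the reference experiment: a square region with a
centered 10 × 10 array of traps spaced 0.5 units, each operating 30 time
units split equally into day and night; generating values `β = (1.4, 0.8)`,
`α = (−0.7, 1.0)`, `ξ = −1`, `σ = 0.4`. Density and detection covariates are
smooth seeded cosine random fields standardized to mean 0, sd 1 across cells,
fixed across replicates (replicate seeds drive only population and detection
randomness). The region side, 5.2 units, was set so that the default density
surface yields an expected abundance `Λ(B) ≈ 147`, matching the scale of the
reference study (~150 animals).

The exact detection sampler draws the pair total `y_ik ~ Poisson(Φ_ik)`,
allocates detections to schedule segments with probabilities
`∝ e^{ξ′z} Δt`, and places times uniformly within segments — exact for
piecewise-constant `z`. A thinning sampler (dominating homogeneous process at
the maximum segment rate) is provided for general rate paths and is
cross-validated against the exact one in distribution.

What the synthetic design does *not* reproduce: real covariate rasters (the
stand-in fields are smoother and stronger than typical habitat covariates, so
`ψ_k` spans a wider range than a field survey's 0.4–0.6 per day); and a
habitat buffer beyond the trap array. The compact region plus strong
baseline rates make nearly every simulated animal detectable, so `n₀ ≈ 0`
here — parameter recovery and the restricted-model bias are unaffected, but
passing tests on these data do not demonstrate `n₀` estimation under sparse
detection. (The `n₀` machinery itself is verified separately by
goodness-of-fit of its exact conditional.) Real surveys with wide buffers,
like the 1130 km² tiger domain with `n₀ ≈ 41` of `N ≈ 127`, exercise that
pathway.

## Replicate experiment sizes

The packaged recovery experiment uses 20 replicates (10 in the test suite)
of the reference design with 1200-iteration chains — sizes chosen as the
smallest at which the cross-replicate Monte Carlo error (reported as `mcse`
in `recover_study()` tables) is an order of magnitude below the effects being
checked (a −0.38 bias; recovery of `σ` to two decimals). Coverage at 10–20
replicates is only interpretable within binomial error, which is how the
tests treat it.

## Known limitations

- Poisson detection process: no behavioral response (trap-happiness),
  no self-exciting clustering of detections, no animal interactions.
- Paired cameras at one station are treated as a single detector; detection
  streams must be deduplicated upstream if two devices photograph one event.
- No open-population dynamics; single-session surveys only.
- Marginal likelihoods / model-comparison criteria are out of scope; the
  sampler reports MCSE and exports chains for external diagnostics.
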