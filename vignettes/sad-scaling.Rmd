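---
title: "Species abundance scaling: models, fitting and extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species abundance scaling: models, fitting and extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadscaling)
```

## The problem

Amplicon surveys of microbial communities count reads per OTU. When the
species abundance distribution (SAD) is heavy-tailed — a power law
`P(x) ~ x^(-1-α)` in the number of reads `x` — most OTUs are rare, and the
observed richness depends on how many reads were sequenced. Rarefaction
curves then show an *apparent* asymptote that is an artifact of sampling
depth: the expected richness keeps growing as `S ~ N^γ` with
`γ = min(α, 1)`. This package implements the machinery to (i) fit candidate
SADs to OTU tables and select among them, (ii) compute the scaling theory's
predictions, (iii) construct rarefaction curves and fit `γ`, and (iv)
extrapolate fitted communities to larger sequencing depths to quantify the
undershoot of rarefaction-based richness estimates.

## The theory in brief

Write the number of OTUs at abundance `x` as `n_x = A x^(-1-α)` on
`[1, N_max]`. Summing over abundances, `S = A ζ(1+α)` for large `N_max`
(`ζ` the Riemann zeta function, evaluated through `pracma::zeta`). The total
reads are `N = Σ x n_x`, which gives two regimes:

* `α > 1`: `N/S = ζ(α)/ζ(1+α)` is finite (`reads_per_species()`), so
  richness grows linearly with effort, `γ = 1`.
* `α < 1`: the reads integral is dominated by the largest abundance,
  `N ≈ S N_max^(1-α) / ((1-α) ζ(1+α))` (`richness_given_effort()` inverts
  this), and since `S ∝ N_max^α` (exactly one OTU at or above `N_max`,
  `n_max_from_richness()`), richness grows sublinearly: `γ = α`.

At the boundary `α = 1` the scaling is linear with a logarithmic correction;
the package warns and uses the harmonic-sum form. The same `S ∝ N^(g/s)`
scaling arises dynamically in a Yule process where new OTUs appear at rate
`g` per OTU and reads replicate at rate `s` per read; `yule_community()`
simulates exactly that event chain and its fitted tail exponent recovers
`g/s`.

## Candidate models and their conventions

All densities are continuous and normalized on `[1, ∞)` (or `[1, x_max]`),
which is the convention in which every closed-form constant below is exact:

| family | density kernel | free parameters (V) |
|---|---|---|
| pure power law | `x^(-1-α)`, `x ≥ x_min` | α (1) |
| truncated power law | `x^(-1-β) e^(-λx)` | β, λ (2) |
| lognormal / Weibull | standard, renormalized to `[1, ∞)` | 2 each |
| double power law | `A x^(-1-δ)` below `x_c`, `B x^(-1-α)` above | δ, α, x_c (3) |
| shifted power law | `A (x + x_0)^(-1-α)` | α, x_0 (2; `x_max` post hoc) |

The double power law's constants are *derived* from its two defining
constraints — continuity at `x_c` and unit mass — giving
`A = αδ / (α + (δ-α) x_c^(-δ))`, `B = A x_c^(α-δ)`; `double_pl_constants()`
never hard-codes a printed constant, and the δ→0 limit is handled
analytically. The shifted law's constant is
`A = α((1+x_0)^(-α) − (x_max+x_0)^(-α))^(-1)`. The truncated power law's
normalizer is the upper incomplete gamma `λ^β Γ(-β, λ)`, computed by the
stable one-step recurrence from `Γ(1-β, λ)`.

Counts are integers, so sampling discretizes the continuous laws: draws are
made by inverse CDF (closed form per branch for the double law, closed form
for the shifted and pure laws, monotone grid inversion with Newton polishing
for the truncated law) and then **rounded to the nearest integer** (clamped
to the support). Rounding, rather than flooring, keeps the discretized
distribution centred on the continuous law: flooring shifts every draw by
−1/2 on average, which measurably biases head-sensitive estimators (on the
deep-ocean recovery below, flooring drags the fitted shift `x_0` about 11%
low, while rounding recovers it). `sad_sample(..., discretize = FALSE)`
exposes the continuous draws for estimator studies.

## Fitting procedures

**Pure power law.** Closed-form continuous MLE
`α̂ = n / Σ log(x_i/x_min)`, standard error `α̂/√n`. The package's tests
verify the closed form against an independent numerical maximizer.

**Truncated power law, lognormal, Weibull.** Numerical likelihood
maximization on transformed parameters (rates and scales on the log scale),
three starts each to dodge local optima; standard errors from the observed
information (numerical Hessian). The truncated law's `λ = 0` boundary is
checked explicitly so a pure power law is never beaten by a worse interior
point.

**Double power law (two-stage).** Stage 1 scans every unique abundance
value with at least 10 tail points as a candidate cutoff, fits the tail
exponent above it by the closed-form MLE, and keeps the cutoff minimizing
the Kolmogorov–Smirnov distance between fitted and empirical tail CDF
(ties go to the smallest cutoff, for reproducibility). Stage 2 fits the
head exponent by MLE restricted to `[1, x_c]`. The KS scan has a known
small-sample behaviour: it tends to place the cutoff slightly below the
true transition, pulling the tail exponent a few percent low; at the
upper-ocean study size (18,022 OTUs) the seed-averaged tail estimate sits
within ~0.05 of the generating 1.54.

**Shifted power law (fixed point).** Alternating iteration of the two
score equations of the `x_max = ∞` likelihood,

```
α   <- S / Σ log((x_i + x_0)/(1 + x_0))
x_0 <- α S / ((1 + α) Σ 1/(x_i + x_0)) − 1
```

stopping when both updates move less than `tol` (default `1e-6`, the
reported convention). The `− 1` in the second update matters: the update
must solve `∂logL/∂x_0 = 0`, which reads
`1 + x_0 = αS/((1+α) Σ 1/(x_i+x_0))`. Without it the iteration still
converges — but to a point that is *not* a stationary point of the
likelihood (about +0.2 on α and +11 on x₀ at the deep-ocean study size).
The tests verify the fixed point coincides with direct two-dimensional
likelihood maximization to high precision. The finite upper support is
recovered afterwards from the observed mean abundance by inverting the
closed-form mean equation (`estimate_x_max()`; the mean is monotone in
`x_max`, so bracketed root finding on the log scale is reliable, and an
unreachable mean is flagged `unbounded` rather than silently capped).

**Model choice.** `AIC = −2 logL + 2V`; ΔAIC relative to the best
converged fit; Akaike weights `exp(−Δ/2)` normalized to 1. Fits on
different data vectors refuse to be compared; non-converged fits keep their
row but carry weight 0 with a warning.

## Rarefaction and the γ fit

`accumulation_curve()` subsamples reads uniformly **without replacement**
from the observed pool (rarefaction proper). Each replicate permutes the
pool once and reads richness off nested prefixes, so a 20-point curve costs
one permutation. The replicate mean matches the closed-form hypergeometric
expectation `E[S(n)] = Σ_i (1 − C(N−x_i, n)/C(N, n))`
(`expected_richness_hypergeometric()`, cross-checked against
`vegan::rarefy` in the tests).

A second engine (`method = "multinomial"`) draws reads *with* replacement
from the relative abundances. This is the correct regime when the abundance
vector stands for a community vastly larger than any subsample — e.g. a
model community whose read pool cannot be materialized. The finite-pool
engine cannot reach the `γ = α` regime for very heavy tails (an `α = 0.3`
community with a few hundred OTUs already implies ~10^12 reads), which is
why the γ–α law is verified with the multinomial engine on communities of
10^6 OTUs (3×10^6 for `α > 1`), a window of 10^3–10^4.5 reads, 12 grid
points, 3 replicates and 10 seeds (4 where the seed-to-seed spread is
negligible). Those sizes keep each check to a couple of minutes while
holding the subsample far below the community size, so collisions do not
depress the slope.

`fit_gamma()` is ordinary least squares of `log10 S` on `log10 N` over a
window, with a t-based 95% half-width on `n_points − 2` degrees of freedom —
so for daily time series the interval is governed by the number of days
observed. `fit_gamma_piecewise()` searches every admissible breakpoint
(≥ 3 points per segment) for the two-regime curves that double power-law
communities produce. `chao1()` is included as the conventional
singleton/doubleton lower bound; on deep-tailed synthetic communities it
sits well below the true generating richness, which is the package's
motivating contrast.

## Extrapolation to larger surveys

Fitted SAD parameters drift with sequencing effort (deeper surveys see
further down the rare tail), so extrapolation works on **parameter
trajectories**: `parameter_series()` refits the model over random sample
subsets of increasing size, bins the fits by total reads, and
`fit_trajectories()` fits each parameter's trend with one of two forms —
power-plus-constant `c1·N^c2 + c3` (cutoff, shift, mean abundance) or
saturating exponential `c1(1 ± c2·e^(−N/c3))` (exponents), via
Levenberg–Marquardt least squares. `default_trajectories()` packages the
reference coefficient sets for the upper- and deep-ocean surveys.

`generate_at_scale()` evaluates the trajectories at a target depth, builds
the corresponding model (double power law for the upper region; shifted
power law with `x_max` recovered from the trajectory mean abundance for the
deep region — with a sub-unity exponent the mean would otherwise diverge),
and draws abundances until the cumulative reads reach the target, keeping
the final overshooting draw. The generated richness is the number of draws.
Because the generating tails have infinite variance, the richness at a
fixed target fluctuates more across seeds than a √n heuristic suggests
(coefficient of variation ~10% upper, ~15% deep at 10^8 reads);
`richness_ratio_at_scale()` therefore reports seed-averaged ratios with
their spread.

**A caveat on the upper-ocean reference trajectories.** Evaluated at 10^8
reads they give `δ = 0.32`, `α = 1.42`, `x_c ≈ 1.26×10^5`, a double power
law whose mean abundance is ≈ 3,700 reads per OTU — hence ≈ 27,000–31,000
generated OTUs, about 0.8× the 35,650-OTU upper-ocean reference count. A
substantially larger underestimation factor is sometimes quoted for this
regime; reaching it from these trajectory forms would require a cutoff
near 10^4 at 10^8 reads, i.e. a much shallower cutoff trajectory than the
packaged coefficients encode. The package reports what the coefficients
give and does not adjust them. The deep-ocean analogue is internally
consistent: ≈ 4,300 OTUs at 10^8 reads, ≈ 1.1–1.2× the 3,695-OTU reference.

## Synthetic data: what it does and does not emulate

`synth_survey()` draws one latent community from a chosen SAD (fixed OTU
count or accumulated to a target read total) and then samples each survey
column multinomially from its relative abundances. Samples are
conditionally independent given the community; there is no spatial or
temporal structure, no sequencing-error or chimera model, and the optional
Dirichlet `dispersion` knob (off by default) is the only compositional
heterogeneity. `synth_mesocosm()` holds the community fixed across 20 daily
samples with lognormally scattered depths (mean 10^4 reads/day, CV 0.5 —
matching the order of magnitude of daily amplicon runs; on defaults the
20-day cumulative curve fits `γ ≈ 0.47`). A static community is a modeling
choice: real mesocosm dynamics can promote rare taxa over time, which this
generator deliberately does not emulate. Passing tests on these synthetic
surveys therefore validates the estimators under the stated sampling model,
not under ecological dynamics or PCR/sequencing artifacts.

Ground truth (generating model, true richness, seed) is returned alongside
every table so tests never re-derive it.

## Numerical conventions and edge cases

* Abundance effort `N` is always **reads**, never sample counts.
* Rank-abundance ties break lexicographically by OTU id — curves are
  byte-reproducible across runs.
* Zero-total OTUs are dropped at aggregation, not at load, so subsetting a
  table is lossless.
* Every public sampler takes an explicit `seed` and restores the caller's
  RNG state; derived seeds stay below 2^31.
* `ζ` is evaluated by `pracma::zeta`; test oracles use brute-force series
  with an Euler–Maclaurin tail remainder (a plain truncated sum at 10^7
  terms is only ~10^-4 accurate near `α = 1.5`, not the 10^-6 the checks
  demand).
* Degenerate inputs are typed conditions (`sads_domain_error`,
  `sads_parse_error`, `sads_comparison_error`, diverging-mean and
  divergent-sum errors), so callers can branch on them.

## Test problem sizes

The suite exercises: recovery of every family's MLE on its own continuous
draws (10 seeds × 5,000 draws; continuous, because the integer rounding
that is right for read counts injects a known bias into head-heavy families
like the lognormal, which would otherwise be mistaken for estimator
failure); integer-data recovery at the two survey configurations (3,695
draws for the shifted law, 18,022 for the double law); model selection on
50 seeds × 10^4 truncated-power-law draws; the γ–α law at the sizes above;
the hypergeometric rarefaction oracle on a 500-OTU community; Yule
communities of 10^6 events; and generation at 10^8 reads over 10 seeds.

## Known limitations

* Continuous likelihoods on integer counts: for abundances concentrated
  near 1 the continuous MLE carries a small discretization bias; a discrete
  (interval) likelihood is the natural extension and is not implemented.
* The KS cutoff scan's mild downward pull on the tail exponent (a few
  percent at survey sizes) is inherited from the scan procedure itself.
* The upper-ocean trajectory caveat above.
* The Yule simulator's richness constant is set by early stochasticity, so
  the *richness* of two runs differs substantially even though the *tail
  exponent* concentrates on `g/s`.
* No coverage-based corrections, Hill numbers, taxonomy handling, or
  BIOM/HDF5 parsing.
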