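---
title: "Modelling over-dispersed council-level disease counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling over-dispersed council-level disease counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countdisp)
```

## The problem

Annual disease counts reported per administrative council are a
textbook case of over-dispersed count data: incidence clusters within
councils that share urbanisation, wealth, health-facility density and
other socio-environmental conditions, so the between-council variance
far exceeds the mean. A Poisson regression fitted to such data gives
consistent point estimates but *understates* standard errors, because
it forces `Var(Y) = μ`. `countdisp` implements the comparison a careful
analyst runs before interpreting such a model: fit Poisson, NB2 and
generalized Poisson (GP) regressions by maximum likelihood, compare
their adequacy, and report inference from the family whose variance
structure the data support.

## The three families

All three model the conditional mean through a log link,
`log μ_i = x_i'β`, so coefficients are log-rate differences and
`exp(β_j)` is a rate ratio.

**Poisson** — `P(Y=y) = e^{-μ} μ^y / y!`, `Var(Y) = μ`.

**NB2** — gamma-mixed Poisson with
`Var(Y) = μ + μ²/α`; `α → ∞` recovers Poisson. The dispersion is
quadratic in the mean, which is why this parametrization is called NB2.

**Generalized Poisson** (Consul–Jain) — in mean form

$$P(Y=y) = \mu\,[\mu+(\vartheta-1)y]^{y-1}\,
  \frac{\vartheta^{-y}}{y!}\,
  \exp\!\Big[-\frac{\mu+(\vartheta-1)y}{\vartheta}\Big],$$

with `Var(Y) = ϑ²μ`. The dispersion factor `ϑ` relates to the natural
parameters `(α, δ)` by `μ = α/(1−δ)`, `ϑ = 1/(1−δ)`
(`gp_natural_to_mean()`). `ϑ = 1` is *exactly* Poisson (a pointwise
identity the test suite checks); `ϑ > 1` is over-dispersion; `ϑ < 1`
is under-dispersion, in which case the pmf is zero beyond the largest
integer `m` with `μ + m(ϑ−1) > 0` (`gp_support_bound()`). Feasibility
requires `ϑ ≥ max(1/2, 1 − μ/4)`; we enforce this bound as stated for
mean-parametrized inputs and do not extrapolate beyond it.

Two deliberate numerical positions on the truncated (under-dispersed)
case:

* the pmf is **not renormalized**: the truncated total can differ from
  one by a small amount (either side of it, in practice well inside
  ±1%), and `gp_mass_deficit()` exposes the signed shortfall instead of
  hiding it;
* the support bound is computed with a `1e-9` tolerance so that exact
  boundary ratios (where `μ/(1−ϑ)` is an integer up to floating-point
  noise) are excluded, as the strict inequality requires.

## Estimation

`fit_count_model()` maximizes the exact log-likelihood. The dispersion
is estimated on the log scale (`log ϑ`, `log α`) as one extra free
parameter — reported in the coefficient table as a dispersion-equation
intercept — so positivity never needs constrained optimization. Counting
it, `k = 13` parameters for Poisson and `14` for NB/GP under the full
council design (intercept, five continuous covariates, the Urban
indicator, six zone indicators).

Numerical choices, all visible in the code:

* **Gradients are analytic** for all three families (the GP score in
  `(β, log ϑ)` is a short closed form), which makes the convergence
  criterion — gradient max-norm below `1e-6` — meaningful rather than
  noise-limited.
* **Starting values**: Poisson starts at `β₀ = log ȳ` with zero slopes;
  NB and GP start from the fitted Poisson coefficients with the
  dispersion at its Pearson moment estimate, floored just above the
  equi-dispersed value. (The equi-dispersed NB `α` is infinite, so a
  literal equi-dispersed start is impossible for that family; the
  moment start is also more robust for GP when over-dispersion is
  strong.)
* **Optimization**: BFGS followed by Newton polishing with a
  central-difference Hessian of the analytic gradient, with
  backtracking line search. The observed-information inverse at the
  optimum supplies `vcov` and standard errors; z = estimate/SE with
  two-sided standard-normal p-values, no small-sample correction.
* **Feasibility**: parameter points with a non-finite linear predictor,
  or a GP dispersion violating `ϑ ≥ max(1/2, 1−μ_i/4)` for any
  observation, evaluate to `+∞` (the optimizer wrapper maps this to a
  large finite penalty only so BFGS line searches can reject the step);
  the likelihood surface itself is never smoothed or projected.
* **Degenerate inputs**: rank-deficient designs and negative or
  non-integer responses are refused up front; a fit that fails the
  gradient criterion is returned with `converged = FALSE`, never
  silently.

## Adequacy comparison

`information_criteria()` uses the standard definitions
`AIC = −2ℓ + 2k`, `AICc = AIC + 2k(k+1)/(n−k−1)`,
`BIC = −2ℓ + k log n`, with `n` passed explicitly so published tables
with a stated effective sample size can be reproduced exactly. Note a
reading the package commits to prominently: in the published adequacy
table this package reproduces, the column labelled `−2logL`
numerically holds `−logL` — the AIC minus twice the printed value
equals `2k` exactly for all three models — and the arithmetic here
follows that identification. Degrees of freedom are `n_used − k` with
the dispersion parameter counted in `k`, which reproduces the published
Poisson ratio (`9574.291/164 = 58.380` at `n = 177`). The published GP
and NB Pearson ratios are mutually inconsistent with `df = n − k` under
any single `n`; the package implements the definition and does not
chase those two cells.

`pearson_chi2()` computes `Σ (y_i − μ̂_i)²/V̂(y_i)` with the fitted
family's own variance function. `comparison_table()` ranks ascending by
AIC, breaking ties by BIC and then model name, and is invariant to the
input order of the fits.

## Descriptive stage

Counts are banded into `[0,50]`, `[51,200]`, `[201,∞)`. The published
band labels (`<50`, `51–200`) leave the value 50 unassigned; assigning
50 to the first band keeps the bands a partition, and the published
cells cannot disambiguate the choice. Percentages are taken out of the
grand total (a cell of 112 councils out of 184 prints 60.87), matching
the published layout. `chi2_independence()` is the Pearson test without
Yates correction and without an exact-test fallback even when expected
counts fall below 5 — that combination reproduces the published zone
p-values (0.01106 and 0.00474), and a flag marks tables where the
asymptotic approximation is doubtful. The published residence p-values
appear only as the bound "< 0.001"; the package reports exact
p-values, which the tests compare against that bound.

## What the synthetic generator does and does not emulate

`synth_config()` defaults encode the study conditions the analysis
assumes: 184 councils; zone frequencies matching the published zone
margins (Northern 31/184, …); an urban share of 45/184; a missingness
rate of 7/184 so complete-case fitting lands near n = 177; counts drawn
from a GP law with log-link mean `exp(x'β_true)` where `β_true` is the
published GP coefficient vector; and a dispersion factor
`ϑ = exp(1.4443) ≈ 4.24`, the exponential of the published
dispersion-equation intercept, giving strong over-dispersion.

No covariate summary statistics were published, so the continuous
covariate laws are plausible placeholders, chosen once and documented,
not reproductions: HIV prevalence gamma(2, 1.25) (% units, mean 2.5),
log-population N(12, 0.7) (median ≈ 160k people), log-GDP N(13, 0.8),
facility counts NB(size 5, mean 30), male share 100·Beta(8, 8).
Covariates are generated directly on the design (log) scale with raw
columns emitted too, so the transform pipeline is exercised; the two
age-band counts come from a binomial split (p = 0.5) of the council
total, so the *total* follows the GP law exactly. Zone effects enter
only through fixed-effect dummies — no spatial autocorrelation, no
covariate correlation, no exposure offsets. Passing recovery tests on
these data therefore demonstrates the estimator and pipeline are
correct *under the assumed model*; they say nothing about model
adequacy for any real council dataset.

The generator is fully determined by one integer seed (R's
Mersenne-Twister, inversion normals), drawn under a private RNG state
that leaves the caller's random stream untouched. GP sampling inverts
the cumulative pmf capped at `μ + 50ϑ√μ + 100` (a draw beyond the cap —
never observed at these settings — would be truncated with a warning).

## Open design choices

* **Which response the published coefficient table models** (ages 5–59,
  60+, or their sum) is not stated; the pipeline makes it a
  `model_spec()` choice and defaults to the sum.
* **Covariate units/scaling** in the published table are not stated;
  the default pipeline log-transforms population and GDP and records
  the transforms in the report, so coefficients are always
  interpretable against a declared scale.
* **The dispersion link used by the original software** is unknown; the
  package's `log` link is a choice made for unconstrained positivity,
  and the two published dispersion-intercept values are not targeted.

## Problem sizes

The test suite and acceptance script use sizes chosen to make
Monte-Carlo error small relative to the tolerances they assert:
`n = 10^5` draws for sampler moment checks, `n = 2000` for single-run
parameter recovery (every parameter within 3 SEs), 200 replicates at
`n = 500` for Wald coverage (nominal 95%, accepted range 90–99%), and
100 replicates at `n = 1000` for the model-selection and
SE-understatement rates. The whole suite runs in well under a minute on
one CPU.

## Limitations

The fitter targets the cross-sectional fixed-effects setting described
above: no offsets/exposure terms, no zero-inflation or hurdle
components, no random effects or spatial correlation. Under-dispersed
GP likelihoods near the feasibility boundary can be awkward for any
optimizer; the package keeps the surface honest (`+∞` outside the
feasible set) rather than projecting, and flags non-convergence. AICc
assumes `n > k + 1` and errors otherwise.
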