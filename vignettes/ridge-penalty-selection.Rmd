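---
title: "Ridge penalty selection: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge penalty selection: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgepen)
```

## Model and canonical form

The package works with the Gaussian linear model `Y = β₀ + Xβ + μ`,
`μ ~ N(0, σ²I)`, `n` observations on `p` predictors, `n > p`. As is
conventional for penalized estimation, the intercept is never penalized:
predictors and response are centered, the slopes are estimated on the
centered scale, and `β̂₀ = ȳ − Σⱼ β̂ⱼ x̄ⱼ` is reconstructed afterwards.

`standardize()` centers each predictor column and scales it to **unit
Euclidean norm**, so the cross-product of the standardized design `X*` is
exactly the sample correlation matrix `R` of the predictors.
`canonical_transform()` then rotates by the eigenvectors of
`X*'X* = EΛE'`: with `Z = X*E`, ordinary least squares decouples into
`α̂ᵢ = (Z'y)ᵢ/λᵢ`, and every ridge fit is the contraction
`α̂ᵢ(k) = λᵢ/(λᵢ+k)·α̂ᵢ`.

Why unit norm rather than unit standard deviation? Three reasons:

* the eigenvalues then satisfy `Σλᵢ = p` and are exactly the spectrum of
  `R`, so the condition number and VIFs used by the diagnostics and by the
  adaptive penalties refer to the same matrix the penalty formulas see;
* the back-transformation is the exact inverse of the standardization
  (division by the centered column norm, `= sd·√(n−1)`), which the test
  suite verifies to 1e−8 against a direct normal-equations solve;
* it is the scale on which the classical penalty-selection literature
  states its formulas.

This choice is consequential — several rules in the catalog (`LW`, `KAG`,
`SCI`, `NEW1`, `NEW2`) are *not* equivariant to rescaling the design, so
their effective shrinkage depends on the eigenvalue scale. See
*Limitations* below.

The residual variance used inside every penalty formula is the OLS value
`σ̂² = RSS/(n − p)` computed on the centered response. The response is
centered but not scaled; all reported coefficients are either on the
standardized scale (`beta_scaled`) or in original units
(`beta_original`), and every function states which.

## The penalty catalog

All fourteen rules are scalar functions of `(σ̂², α̂, λ, n, p)`; see
`?ridge_k` for the formulas. Two structural families are worth noting:

* **Inverse-coefficient rules** (`HK`, `KAM`, `KGM`, `KMED`, `KMS`)
  divide by canonical coefficients and are undefined when some `α̂ᵢ = 0`;
  the package raises an error rather than returning `Inf` (with
  continuous responses this is a measure-zero event).
* **Condition-number-adaptive rules**: `NEW1` and `NEW2` multiply the
  Karaibrahimoglu–Asar–Genc constant by the sample size and by a power of
  the eigenvalue ratio `r`. The package defaults to `r = λmax/λmin`, so
  that shrinkage *grows* with the severity of multicollinearity — the
  stated motivation of these rules, and the orientation consistent with
  `NEW2` shrinking more than `NEW1` (exponent 1/2 versus 1/(2p)). The
  opposite orientation (`r = λmin/λmax`), which makes both rules shrink
  less as collinearity worsens, is available behind
  `literal_ratio = TRUE` purely for auditability.

Numerical details: the geometric-mean rule is computed on the log scale to
avoid under/overflow of `Π α̂ᵢ²`; the median with an even number of
predictors is the midpoint of the central order statistics; eigenvalues
are stored in descending order and eigenvector signs are fixed by making
the largest-magnitude entry of each column positive, so canonical
coefficients are reproducible across platforms; designs with
`λmin/λmax < 1e−12` are rejected as singular rather than pseudo-inverted.

## Collinearity diagnostics

`collin_diagnostics()` reports, from the predictor correlation matrix:

* **VIF** — diagonal of `R⁻¹`; equals `1/(1−Rⱼ²)` for predictor `j`
  regressed on the others. The trace identity `ΣVIFⱼ = Σ1/λᵢ` is used as
  an internal consistency check in the tests.
* **Condition number** — `√(λmax/λmin)`, i.e. the ratio of extreme
  singular values of the standardized design. Values above ~10 are
  conventionally read as serious collinearity.
* **Farrar–Glauber statistic** — `−(n − 1 − (2p+5)/6)·ln det R`,
  asymptotically chi-square with `p(p−1)/2` degrees of freedom under
  mutually uncorrelated predictors. The log-determinant is accumulated
  from the eigenvalues for stability.

Two published correlation matrices ship as plain-CSV fixtures
(`bodyfat_cor()`, 13 predictors, n = 50; `livestock_cor()`, 5 predictors,
n = 18), transcribed at 4 decimal places. A note on rounding: entries
rounded to 4 decimals perturb eigenvalues by at most ~`p·5e−5`. For the
body-fat matrix (`λmin ≈ 0.0086`) the VIFs and Farrar–Glauber statistic
are therefore pinned to a fraction of a percent, and the published VIF
and FG values are reproduced to within 0.25%. The published condition
number for that matrix (18.33), however, is not consistent with the
matrix itself — the printed entries give 33.2, and the published VIF sum
(≈229 = Σ1/λᵢ) itself rules out any spectrum with condition number 18.33
— so the package reports the value the matrix actually implies. For the
livestock matrix `λmin ≈ 1.3e−5`, and its condition number is an
order-of-magnitude statement only; its FG statistic is still reproduced
within ~8%.

## The Monte Carlo study

`run_scenario()` emulates the standard simulation design of the
penalty-selection literature:

* predictors drawn once from `N(0, Σ(ρ))` with `Σ(ρ)` equicorrelated —
  every pair of predictors shares the same correlation `ρ`;
* true slope vector of unit squared norm, intercept 0; the default
  direction is equal weights `1/√p` (on an equicorrelated design with
  `ρ > 0` this is exactly the leading eigenvector of `Σ`, the direction
  along which collinearity carries the signal); `eigvec_max` is exposed
  as the explicit alternative;
* per replication, fresh `N(0, σ²)` errors, a full
  standardize–canonicalize–fit pass for all estimators, and the squared
  slope-estimation error in original units accumulated into
  `EMSE = (1/N)Σ‖β̂ₘ − β‖²`.

Study-condition defaults mirror the grid this design is normally run on:
`ρ ∈ {0.85, 0.90, 0.95, 0.99}`, `p ∈ {4, 6, 8}`, `σ ∈ {2, 3}`,
`n ∈ {30, …, 300}`, `N = 10000` replications.

Design choices made where the design was genuinely open:

* **Fixed design by default.** The generation scheme draws `X` before the
  replication loop; `redraw_X = TRUE` gives the random-design reading.
  Consequence: the absolute EMSE scale of any single scenario depends on
  the realized `X` (the tests therefore compare the Monte Carlo EMSE of
  OLS to its exact fixed-design expectation `σ²·tr((Xc'Xc)⁻¹)` rather
  than to any external number).
* **EMSE over the `p` slopes only**; the unpenalized intercept is
  excluded.
* **RNG contract**: one seed per scenario; each replication consumes
  draws in a fixed order that does not depend on the method list, so any
  method subset reproduces the same per-replication errors. Grid runs
  derive per-scenario seeds deterministically from a master seed.
* **Singular replications** (possible under `redraw_X`) are skipped and
  counted; more than 1% skips aborts the scenario rather than silently
  regularizing.
* Inside the replication loop the design-dependent pieces (scales,
  eigenstructure, rotated design) are hoisted out when `X` is fixed;
  the tests assert this fast path is numerically identical to the public
  `standardize() → canonical_transform() → fit_ridge()` pipeline.

What the generator does *not* emulate: non-Gaussian or heteroscedastic
errors, non-equicorrelated dependence (autoregressive or block
structures), measurement error in `X`, and model misspecification. A rule
that wins under this generator is not thereby guaranteed to win on real
data — which is why the real-data evaluation module exists.

## Real-data evaluation

`evaluate_dataset()` reports, per rule: the plug-in MSE (`σ̂²` and `α̂`
from the OLS fit evaluated at the rule's `k`), absolute and relative
shrinkage `AS = ‖β̂_OLS‖² − ‖β̂_Ridge‖²`, `RS = AS/‖β̂_OLS‖²` computed on
the standardized-coefficient scale (orthogonally equivalent to the
canonical scale, which guarantees `AS ≥ 0` and monotone growth in `k`),
and the prediction-interval coverage CPPI.

CPPI choices: in-sample coverage over the `n` fitting observations;
`t(α/2, n−p)` quantile with `α = 0.05` by default; the leverage term uses
the *unpenalized* `(X*'X*)⁻¹` for every method; the interval width uses
each method's own residual variance by default (`pi_sigma = "method"`),
with the OLS variance available via `pi_sigma = "ols"` since either
convention is defensible. Coverage is invariant to affine rescaling of
the response; note that in-sample coverage is also invariant to the noise
scale, so a near-noiseless fit covers at roughly the nominal rate, not at
100%.

## Problem sizes used by the test suite

The shipped tests run the simulation at reduced size, chosen to keep the
whole suite in the tens of seconds while leaving Monte Carlo standard
errors an order of magnitude below the effects being asserted: the
qualitative-ordering grid uses `N = 2000` over
`ρ ∈ {0.85, 0.99} × p ∈ {4, 8} × n ∈ {30, 100}` at `σ = 2`; the
fixed-design EMSE oracle uses `N = 5000` at `(ρ=0.9, p=4, σ=2, n=100)`;
the coverage simulation averages 50–60 datasets of `n = 200`. All seeds
are fixed in the test files.

## Limitations

* The non-equivariant penalties (`LW`, `KAG`, `SCI`, `NEW1`, `NEW2`)
  change their effective shrinkage if the design is standardized to a
  different eigenvalue scale (e.g. unit standard deviation, where
  `X*'X* = (n−1)R`). The package commits to the correlation scale
  everywhere and documents it; users comparing against results computed
  on another scale should expect **qualitative rank changes among these
  rules** — in particular, on the correlation scale the `n`-multiplied
  adaptive rules shrink aggressively at moderate `n`, and `NEW1` rather
  than `NEW2` can attain the best EMSE in low-`ρ` cells.
* `KMS` and `SCI` are not invariant to rescaling the response
  (`SCI ∝ σ̂²` has the dimension of `y²`); rankings involving them depend
  on the response units.
* No inference machinery (standard errors, tests) is provided for ridge
  coefficients, and no generalized (per-coordinate) ridge.
* Weighted least squares and non-Gaussian likelihoods are out of scope.
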