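# kfident

Joint state/parameter estimation for non-linear kinetic ODE models with
a **constrained square-root unscented Kalman filter (CSUKF)**, coupled
to a data-driven **identifiability analysis** that classifies every
parameter, explains *why* the non-identifiable ones are
non-identifiable, and constructs **informed priors** so that a unique
parameter set can be produced even when the likelihood alone cannot
provide one.

It is written for systems biologists fitting kinetic models (enzyme
kinetics, gene regulatory networks) to noisy concentration time series,
where most rate parameters cannot be measured directly and many are not
identifiable from the available data.

## The model and the method

A kinetic model is the state-space system

```
ẋ = F(x, θ, t) + w,    y(k) = H(x(t_k), θ) + v(k),
w ~ N(0, Q),           v ~ N(0, R)
```

with concentrations `x` (mM), rate parameters `θ`, and noisy
observations `y`. Estimation augments the state with the parameters
(`θ̇ = 0`) and filters the augmented system: sigma points are propagated
through the numerically integrated dynamics, the covariance is carried
as a Cholesky factor `S` (P = S·Sᵀ, guaranteeing positive definiteness),
and box constraints `L ≤ x ≤ U` are enforced by ray-scaling infeasible
sigma points back to the boundary with matching weight renormalization.
The filter's merit is the chi-square sum of R-weighted squared
innovations, `χ² = Σₖ (yₖ − ŷ⁻ₖ) Rₖ⁻¹ (yₖ − ŷ⁻ₖ)ᵀ`.

The identifiability module provides:

* **Orthogonal sensitivity ranking** of the scaled sensitivity matrix
  `z_ij = (∂x_i/∂θ_j)(θ̂_j/x̂_i)` with a residual-norm stop threshold
  (default 0.004); leftover parameters are ranking-non-identifiable.
* **Profile likelihood**: each parameter is stepped away from its
  estimate with the nuisance parameters re-optimized by the CSUKF;
  crossings of the 95% threshold `Δ(α,1) = 3.84` on both / one / no
  side classify the parameter as identifiable / practically /
  structurally non-identifiable, with likelihood-ratio confidence
  intervals `[σ⁻, σ⁺]`.
* **Relation detection**: linear correlations from the filter's
  square-root covariance, and non-linear functional relations by
  alternating conditional expectations with bootstrap (MOTA-style).
* **Informed priors**: rank-based uncertainty schedules (rank 1 gets
  the smallest prior std) and phase-to-phase carry-over, which make the
  Bayesian filter return a unique estimate despite non-identifiability.

## A worked example

The structurally non-identifiable fixture `ẋ = −θ₁θ₂x` (only the
product θ₁θ₂ = 0.3 is identifiable):

```r
library(kfident)

fx  <- make_fixture(fixture_spec("product_ni", seed = 1))
fit <- csukf(fx$model, fx$noisy, seed = 1)
fit
#> CSUKF fit: product_ni
#>   estimated parameters:
#>    th1    th2
#> 0.5280 0.5944
#>   chi-square merit:16.4444 (20 points, 20 passes, max passes)

prod(coef(fit))        # the identifiable combination, truth 0.3
#> [1] 0.3138441

tr <- profile_parameter(fit, "th1")
tr
#> Profile likelihood: th1 -> structural
#>   psi range [0.002821, 85.08], chi2 min 15.84, pointwise thr 3.84
#>   95% CI: [-Inf, Inf]

rel <- mota_detect(do.call(rbind, tr$eta), seed = 1)
rel[1, c("response", "predictors", "r2_mean", "significant")]
#>   response predictors   r2_mean significant
#> 1      th1        th2 0.9986631        TRUE
```

The flat profile over four decades marks both parameters as
structurally non-identifiable; the relation detector identifies the
θ₁–θ₂ coupling. The full pipeline (`run_framework()`) then builds a
rank-based informed prior and re-estimates, collapsing the across-run
spread of both parameters by two orders of magnitude while the fitted
trajectories still match the data.

Bring your own model either programmatically (`kinetic_model()`) or
from an SBML file (`load_sbml()`); measurement data are CSV tables with
a `time` column (`read_series()`). A command-line wrapper for the
common steps lives at `inst/cli/kfident.R`
(`Rscript kfident.R run --model path/to/model.sbml --data data.csv`).

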