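# fractumor

Fractional-order tumor growth modelling in R.

## The problem

Classical tumor growth laws — exponential, logistic, Gompertz, and the
Bertalanffy–Pütter power law in its general and particular forms — are
memoryless: the growth rate at time *t* depends only on the current
volume. Replacing the ordinary derivative with a **Caputo fractional
derivative** of order α ∈ (0, 1],

D^α v(t) = 1/Γ(1−α) ∫₀ᵗ v′(τ) (t−τ)^{−α} dτ,

adds one degree of freedom encoding long-range memory. At α = 1 the
classical model is recovered exactly, so the fractional family strictly
contains the classical one, and the question "does memory improve the
fit?" becomes a one-dimensional comparison.

`fractumor` is for modellers working with tumor-volume time series (or any
scalar growth curve) who want to fit and compare the classical and
fractional variants of these laws. It provides:

* **Fractional numerics** — Mittag-Leffler function `mittag_leffler()`,
  Riemann-Liouville integral `rl_integral()`, Caputo derivative (L1
  scheme) `caputo_derivative()`, and a fractional
  Adams-Bashforth-Moulton initial-value-problem solver
  `solve_caputo_ivp()` validated against the closed form
  v₀ E_α(a t^α).
* **The five growth laws** — `growth_model()` / `growth_rate()`, with both
  published Gompertz variants.
* **The two-stage fit** — `fracfit()`: cubic-spline resampling of sparse
  measurements, Nelder-Mead estimation of the kinetic parameters at
  α = 1 minimizing MSE = (1/n) Σ (yᵢ − ŷᵢ)², then a one-dimensional
  sweep over α with the parameters frozen. Standard methods
  (`print`, `summary`, `coef`, `predict`, `plot`, `residuals`,
  `simulate`) on the returned object.
* **Well-posedness diagnostics** — existence ((φ+ψc)θ < 1), uniqueness
  (1 − (φ+ψt)θ > 0) and Mittag-Leffler stability classification.
* **A synthetic experiment generator** — `simulate_experiment()`:
  treated/untreated xenograft arms with threshold-triggered dosing
  (200 mm³, ≥ 10 days apart), log-kill treatment effect, lognormal
  measurement noise, 2000 mm³ censoring, fully seeded.
* **A pipeline** — `run_pipeline()` fits every law to every dataset and
  writes a versioned JSON/CSV comparison report.

## Worked example

Simulate a treated arm (dose when a measurement reaches 200 mm³, 40%
log-kill) from a fractional exponential truth, then fit:

```r
library(fractumor)

m  <- growth_model("exponential", a = 0.109)
ex <- simulate_experiment(m, alpha = 0.9, v0_mm3 = 80,
                          protocol = treatment_protocol(),
                          kill_fraction = 0.4, sigma = 0.02, seed = 1)
ex
#> Synthetic tumor experiment [exponential, alpha = 0.9, treated]
#>   8 measurements over 17 days; noise sigma = 0.02
#>   doses at days: 10
#>   time_days volume_mm3
#> 1         0   79.00393
#> 2         2   99.42991
#> ...
#> 6        12  149.47647   <- post-dose drop
#> 8        17  244.27468

fit <- fracfit(as_model_units(ex), kind = "exponential")
fit
#> Two-stage fractional growth-model fit [exponential]
#>   integer order (alpha = 1):    MSE = 0.0904952
#>   fractional order alpha = 0.99 :  MSE = 0.0901809
#>   retained MSE: 99.65% of the integer-order error
#>   kinetic parameters (Nelder-Mead, 72 evaluations):
#> Growth law [exponential]: dv/dt = 0.0674118 v

coef(fit)
#>          a      alpha
#> 0.06741185 0.99000000
```

Reading the output: the integer stage estimated the growth rate
a = 0.0674 day⁻¹ (below the generating 0.109 because the post-dose dip
and the memory of the α = 0.9 truth both slow the apparent growth); the
fractional sweep then found that α = 0.99 retains 99.65% of the
integer-order error — a strict improvement, as the dip gives the memory
term something the one-parameter exponential cannot express. MSE is in
squared model volume units (1 unit = 100 mm³). `plot(fit)` shows the data
with both fitted curves and the MSE–α sweep;
`summary(fit)` appends the well-posedness report:

```r
wellposedness_report(fit$integer$model, alpha = fit$fractional$alpha)
#> Well-posedness [exponential, alpha = 0.99]:
#>   phi = 0.019802, psi = 1.9604, theta = 0.0674118 on [0, 20]
#>   existence  (phi + psi c) theta = 0.13349  -> holds (c = 1)
#>   uniqueness 1 - (phi + psi t) theta = -1.3801 -> fails (t = 18)
#>   Mittag-Leffler stability class: unbounded_growth
```

(The uniqueness bound grows linearly in the horizon, so it typically
fails at 18 days even for slow kinetics — a property of the bound, not of
the trajectories; see the vignette.)

For a full comparison across all five laws and both arms:

```r
res <- run_pipeline(list(synthetic = list(seed = 1), models = c(
  "exponential", "logistic", "gompertz", "bp_general", "bp_particular"),
  outdir = "out"))
res$comparison
```

## Documentation

The methods vignette (`vignettes/fractional-tumor-growth.Rmd`) documents
the model family and its assumptions, the numerical schemes and their
validation, the unit convention, what the synthetic generator does and
does not emulate, and the package's design decisions and limitations.
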