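---
title: "Fractional-order tumor growth models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order tumor growth models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractumor)
```

## The modelling problem

Tumor volume curves from xenograft experiments are classically described by
a handful of one-dimensional growth laws: exponential, logistic, Gompertz,
and the two-term Bertalanffy-Pütter power law in its general
($\dot v = p v^a - q v^b$, $a \ne b$) and particular ($a = b$,
$\dot v = p v^a - q v^a \ln v$) forms. These deterministic, memoryless
models often misfit empirical curves in a structured way. Replacing the
ordinary time derivative by a Caputo fractional derivative of order
$\alpha \in (0, 1]$,

$$ D^\alpha v(t) = \frac{1}{\Gamma(1-\alpha)} \int_0^t
   \frac{v'(\tau)}{(t-\tau)^{\alpha}}\, d\tau, $$

adds a single extra degree of freedom that encodes long-range memory: the
growth rate at time $t$ depends on the whole history of the trajectory, a
property often argued to suit biological processes. At $\alpha = 1$ the
classical model is recovered exactly, so the fractional family strictly
contains the classical one. The Caputo form (rather than
Riemann–Liouville) is used because it annihilates constants and admits
ordinary initial conditions $v(0) = v_0$.

`fractumor` implements this family end to end: the fractional numerics, the
five growth laws, a two-stage fitting procedure, well-posedness
diagnostics, and a synthetic data generator emulating a treated/untreated
mouse experiment.

## Units and conventions

Volumes are handled in *model volume units*, defined as 100 mm³ per unit.
This convention makes the published kinetic parameter scales (for example
logistic carrying capacities of 2.81 or 35.2) correspond to plausible
tumor volumes of a few hundred to a few thousand mm³, and places the
2000 mm³ censoring threshold at 20 units. The synthetic generator operates
in mm³ and `as_model_units()` performs the explicit conversion (the factor
is configurable everywhere it appears). Rates carry implied units
day$^{-\alpha}$ when used fractionally; their numeric values are kept as
printed in the literature.

For the Gompertz law two printed variants circulate, with and without the
leading $v$ factor ($a v \ln(b/(v+c))$ vs $a \ln(b/(v+c))$). Both appear
in published fitted-model tables, sometimes inconsistently. The package
exposes both through `gompertz_form = c("with_v", "without_v")` with the
$v$-factor form as the default, and asserts neither as "the" Gompertz
model.

## Numerics

**Mittag-Leffler function.** $E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k+1)$
solves the linear fractional equation: $D^\alpha v = a v$ gives
$v(t) = v_0 E_\alpha(a t^\alpha)$. The series is summed directly with a
term-ratio stopping rule inside the envelope $|z| \le 30$,
$\alpha \ge 0.3$, where double-precision summation is sound; larger
positive arguments raise an error rather than return an unvalidated
number. For $z < -5$ the alternating series loses digits to cancellation,
so the algebraic expansion
$E_\alpha(z) \sim -\sum_{k\ge1} z^{-k}/\Gamma(1-\alpha k)$ (optimally
truncated, with Gamma-pole terms skipped) is used instead; it is validated
in the test suite against the identity $E_{1/2}(-x) = \mathrm{erfcx}(x)$
to better than $10^{-6}$ over the crossover.

One published presentation of the linear solution writes the envelope as
$A\,E_\alpha((a t)^x)$ with an exponent $x$ distinct from $\alpha$; the
standard form $v_0 E_\alpha(a t^\alpha)$ is adopted here, which the
$\alpha = 1$ limit and the numerical solver both confirm.

**Fractional IVP solver.** `solve_caputo_ivp()` is the Diethelm-style
fractional Adams-Bashforth-Moulton predictor-corrector: a fractional Euler
predictor with weights $(n-j+1)^\alpha - (n-j)^\alpha$, then a
product-trapezoid corrector, both carrying the full $O(N^2)$ Caputo memory
term. At $\alpha = 1$ the weights collapse to the classical second-order
Adams pair, so integer-order trajectories use the same code path. The
default step is $h = 0.01$ day over the 18-day horizon (1801 points,
about 0.1 s per solve); fitting uses the resampled grid step instead
(0.1 day, 181 points), which keeps the $O(N^2)$ cost negligible inside
optimization loops. One corrector pass is the default; more are available
via `corrector_iters`. Against the Mittag-Leffler closed form at the
published rates and orders, the solver is accurate to about $10^{-6}$
relative at $h = 0.01$ — three orders better than the $10^{-3}$ the
package's acceptance checks require. Trajectory blow-up raises a classed
error carrying the last valid time; an optional non-negativity guard
(`nonneg = TRUE`, used for all tumor simulations) aborts if the state
crosses zero.

**Quadratures.** `rl_integral()` (Riemann-Liouville integral) uses
product-trapezoid weights, exact for piecewise-linear integrands;
`caputo_derivative()` is the L1 scheme, which inherits the defining
property that constants differentiate to exactly zero. Both converge as
the grid refines and are tested against closed forms
($I^\alpha 1 = t^\alpha/\Gamma(\alpha+1)$,
$D^\alpha t = t^{1-\alpha}/\Gamma(2-\alpha)$).

## The two-stage fit

`fracfit()` follows the identification recipe of the study the package
models:

1. **Resampling.** Sparse measurements (every 2–3 days) are interpolated
   by a cubic spline and evaluated on a uniform 0.1-day grid. The spline
   passes through every measurement; no extrapolation occurs.
2. **Integer stage.** The kinetic parameters are estimated at
   $\alpha = 1$ by Nelder-Mead (the `fminsearch` algorithm) minimizing the
   mean squared error, Eq. MSE $= \frac1n\sum_i (y_i - \hat y_i)^2$, on
   the resampled grid. Positivity is enforced by optimizing
   log-parameters. Defaults: objective tolerance $10^{-10}$, 2000
   iterations, one restart from the incumbent optimum; solver failures on
   a parameter trial score $+\infty$ rather than aborting.
3. **Fractional stage.** The kinetic parameters are frozen and only
   $\alpha$ is varied over a grid (default $[0.70, 1.00]$, step 0.01,
   chosen to bracket the orders reported for this kind of data, roughly
   0.86–0.98). Because the grid contains $\alpha = 1$, the fractional MSE
   can never exceed the integer-stage MSE; exact ties resolve to the
   smallest $\alpha$ so reports are deterministic.

The initial volume is fixed to the first resampled observation rather than
fitted or set near zero: freeing $v_0$ would confound it with the kinetic
parameters, and the near-zero simulation convention is a separate concern
from identification. This is a deliberate, documented divergence from the
looser "near zero initial conditions" convention sometimes used for
simulation.

Joint optimization of $\alpha$ together with the kinetic parameters is
intentionally out of scope: the two-stage structure isolates what the
fractional order alone contributes on top of the best classical fit.

## What the synthetic generator emulates — and what it does not

No public dataset accompanies the experimental protocol the package
targets, so `simulate_experiment()` stands in for it: an 18-day horizon,
measurements alternating 2 and 3 days apart, an untreated arm, and a
treated arm dosed (8 mg/kg, recorded but not mechanistically modelled)
when a *measured* volume reaches 200 mm³ with at least 10 days between
doses, censored at the first measurement of 2000 mm³. Choices the
protocol leaves open were fixed once:

* **Treatment effect.** The growth laws contain no drug term, so each dose
  applies an instantaneous log-kill: the volume drops to $(1-\kappa)$
  times its pre-dose value, default $\kappa = 0.4$, and the fractional
  solver restarts from the post-kill state (the Caputo memory is reset at
  dose times — the piecewise-defined trajectory is the model). A
  $\kappa = 0$ dose changes nothing and does not restart the solver, so a
  zero-effect treated arm coincides exactly with the untreated arm under
  the same seed.
* **Noise.** Multiplicative lognormal with median 1,
  $v_{\text{meas}} = v \exp(\sigma Z)$, default $\sigma = 0.05$. At this
  scale the mean of the ratio is $e^{\sigma^2/2} \approx 1.0013$,
  indistinguishable from 1 at the suite's sampling depth.
* **Dosing decisions** are taken at sample times from the noisy
  measurements (observation-driven protocol), not from the latent state.
* **Defaults.** $v_0 = 50$ mm³ and exponential dynamics at the published
  untreated rate $a = 0.109$; every default is an argument.

What the generator does *not* emulate: pharmacokinetics, inter-animal
variability, treatment resistance, measurement heteroscedasticity beyond
the lognormal form. Tests passing on these fixtures therefore demonstrate
the correctness and internal consistency of the pipeline, not the
biological adequacy of any growth law for real tumors.

## Behavior of the fractional stage on synthetic data

Two empirical properties of the two-stage procedure, established while
validating the package and worth knowing before use:

* On noiseless or mildly noisy *untreated* (monotone) fixtures generated
  at $\alpha < 1$, the integer refit absorbs the fractional shape almost
  completely — the refit kinetic parameters compensate — and the
  $\alpha$-sweep then sits on the boundary optimum $\alpha^* = 1$. The
  fractional stage detects memory that the classical parameter refit
  *cannot* mimic, not any departure of the generating order from 1.
* On *treated* fixtures, the log-kill dip produces curvature the monotone
  integer family cannot track, and the fractional stage strictly improves
  the fit in essentially every seeded replicate (40/40 in the package's
  replicate study: treated exponential arm, $a = 0.109$,
  $v_0 = 80$ mm³ so the dosing threshold is crossed mid-experiment,
  $\alpha = 0.9$, $\sigma = 0.02$).

When the fractional stage is run with the *generating* kinetic parameters
held fixed (order-recovery setting), it recovers the generating order to
one grid step with the characteristic unimodal MSE–$\alpha$ dip.

## Well-posedness diagnostics

The fixed-point existence/uniqueness theory for these models, built on the
Caputo-Fabrizio integral form, reduces to arithmetic on
$\phi(\alpha) = \frac{2-2\alpha}{M(\alpha)(2-\alpha)}$ and
$\psi(\alpha) = \frac{2\alpha}{(2-\alpha)M(\alpha)}$ together with a
Lipschitz constant $\theta$ of the growth law: a solution exists when
$(\phi + \psi c)\,\theta < 1$ and is unique when
$1 - (\phi + \psi t)\,\theta > 0$. The package takes $M(\alpha) \equiv 1$
(the common normalization; the theory leaves it unspecified), $c = 1$ and
$t =$ the 18-day horizon by default — both surfaced as arguments, since
the theory ties neither to a particular horizon. $\theta$ is exact
($= a$) for the linear law and otherwise a sup of the numerical
$|\partial f/\partial v|$ over a dense grid on the data's volume range;
for the particular Bertalanffy-Pütter law the range floor defaults to
$10^{-3}$ model units because $|\partial f/\partial v|$ is unbounded as
$v \to 0^+$ when the exponent is below one. Note that with the 18-day
horizon the uniqueness condition typically *fails* even for the slowest
published rates — a property of the bound, which grows linearly in $t$,
not of the trajectories. `ml_stability_report()` classifies the linear
model's long-time behavior (decay / bounded / unbounded) by evaluating
the Mittag-Leffler envelope at $t \in \{10, 100, 1000\}$ rather than
trusting sign reasoning alone.

## Numerical choices and degenerate inputs

* $\alpha$-grid ties resolve to the smallest $\alpha$; failed solves
  score $+\infty$ and are flagged in the sweep, never silently dropped.
* `bp_general` with $|a - b| < 10^{-6}$ is rejected, not auto-switched to
  the particular form: the two branches are distinct fitted models.
* The spline resampler requires at least 4 points (a cubic needs them)
  and strictly increasing times; the CSV reader reports the offending
  line for non-monotone times, negative volumes or malformed fields.
* Problem sizes: solver validation runs at $h = 0.01$ over 18 days
  (1801-point memory sums); fitting and the replicate study at the
  0.1-day resampled grid; recovery fixtures are dense solver trajectories
  on that same grid, so that "MSE at the truth" is meaningfully near
  zero. The 40-replicate study and all defaults execute in well under a
  minute each on a single core.

## Known limitations

* The fractional solver restarts with reset memory at dose times; a
  formulation retaining pre-dose memory across doses is a different
  model, not supported.
* The Mittag-Leffler evaluator is real-valued with a guarded envelope; no
  complex arguments, no $\alpha > 1$ solver support (the function itself
  accepts $\alpha = 2$ for identity checks only).
* MSE is the only comparison statistic, by design parity with the
  procedure the package implements; no information criteria or
  uncertainty quantification are provided.
* Variable-order and distributed-order operators, adaptive fractional
  steppers, and drug-term models are out of scope.
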