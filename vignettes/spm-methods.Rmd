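---
title: "Stochastic process models of aging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic process models of aging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmaging)
```

## The model

`spmaging` implements the stochastic process model (quadratic hazard
model) of aging: a joint model in which a vector of physiological
biomarkers $Y_t$ (age $t$, in years) follows a mean-reverting diffusion

$$dY_t = a(t, X)\,\bigl(Y_t - f_1(t, X)\bigr)\,dt + B\,dW_t,$$

and death (or disease onset) occurs with the hazard

$$\mu(t, Y_t, X) = \mu_0(t, X) +
  \bigl(Y_t - f_0(t, X)\bigr)^{\!\top} Q(t)\,\bigl(Y_t - f_0(t, X)\bigr).$$

Each component carries a biological reading:

* $a(t,X)$ — **adaptive capacity**: the strength of the negative
  feedback pulling the biomarker back toward its target after a
  disturbance.  Stable (homeostatic) dynamics need all eigenvalues of
  $a$ to have negative real part; `validate_model()` warns otherwise.
* $f_1(t,X)$ — the **allostatic trajectory** the process is pulled
  toward.
* $f_0(t,X)$ — the age-dependent **physiological norm**: the biomarker
  path that minimizes the hazard at each age.  The gap $f_1 - f_0$
  measures allostatic load.
* $Q(t)$ — the curvature of the U-shaped risk in the biomarker
  deviation, read as (inverse) **stress resistance**; its growth with
  age models declining resistance.
* $\mu_0(t,X)$ — the baseline (Gompertz) hazard remaining for an
  individual tracking the norm exactly.
* $B$ — diffusion intensity of the unexplained physiological noise.

### Parametric forms

The model family never pins down functional forms, so the package
commits to minimal identifiable defaults, all linear in age:
$a(t) = a_0 + a_1 t$; $f_1(t) = f_{1,0} + f_{1,1}t$ and likewise
$f_0$; constant diagonal $B$; $Q(t) = Q_0\max(1 + q_1 t,\, 0)$ with
$Q_0$ symmetric non-negative-definite; Gompertz
$\mu_0(t) = e^{c_0 + \theta t}$ with $\theta$ unconstrained in sign.
Baseline covariates act as additive shifts on the $f_1$/$f_0$
intercepts and log-linearly on $\mu_0$; the feedback, diffusion and
curvature are covariate-free by default because the latent-class and
genetic extensions already provide regime-specific versions of those
components.  Time-varying covariates are out of scope.

## The likelihood

Conditionally on survival and the accumulated observation history, the
law of $Y_t$ remains Gaussian under this model, so the likelihood is
assembled exactly from the conditional mean $m(t)$ and covariance
$\gamma(t)$, which obey

$$\dot m = a\,(m - f_1) - 2\gamma Q (m - f_0), \qquad
  \dot\gamma = a\gamma + \gamma a^{\top} + BB^{\top} - 2\gamma Q \gamma,$$

with the averaged hazard
$\bar\mu(t) = \mu_0 + (m - f_0)^\top Q (m - f_0) + \mathrm{tr}(Q\gamma)$.
Survival conditioning visibly pulls $m$ toward the norm and shrinks
$\gamma$; with $Q = 0$ the equations reduce to the unconditional
Ornstein–Uhlenbeck moments.  An individual contributes

$$\sum_{j \ge 1} \log N\!\bigl(y_{j};\, m(t_j^-), \gamma(t_j^-)\bigr)
  \;-\; \int_{t_0}^{\tau} \bar\mu(s)\,ds \;+\; \delta \log\bar\mu(\tau^-),$$

where the first examination initialises the state and is not scored,
examinations reset the state exactly ($m \leftarrow y$,
$\gamma \leftarrow 0$) when the process is observed without error, and a
linear-Gaussian filter update replaces the reset when a measurement-error
standard deviation is declared.  Left truncation is handled by starting
the integration at the individual's entry age from the initial law; when
censoring coincides with the last examination the survival integral
simply ends there, with no additional density factor.  A discrete-time
variant of the likelihood (Euler transition densities on a fixed step
grid, per-step survival factors) is provided as
`discrete_time_loglik()` and converges to the continuous version as the
step shrinks.

### Numerical choices

* The moment equations (with the survival integral appended as an extra
  coordinate, so it shares the integration error) are integrated with a
  fixed-step classical Runge–Kutta scheme, step `h_max` (default 0.1 y,
  one or more steps per inter-examination interval).  The components are
  smooth, low-curvature functions of age, so this already reproduces the
  closed forms to ~1e-9 relative error (the test suite checks against
  exact Ornstein–Uhlenbeck/Gompertz limits and an independent adaptive
  solver); a fixed step is deterministic, smooth in the parameters —
  which quasi-Newton optimization appreciates — and cheap inside the
  optimizer loop.  Fits on sparse examination schedules can safely use
  `h_max = 0.5`.
* $\gamma$ is monitored along every integration; eigenvalues below
  $-10^{-10}$ are counted and reported (then clipped at zero), values in
  $(-10^{-10}, 0)$ are clipped silently.
* Log-density and log-hazard arguments are floored at `1e-300`.
* Free parameters are optimized on an unconstrained scale: positive
  diagonals through `log`, non-negative-definite matrices through their
  Cholesky factor with `log`-transformed diagonal, everything else
  untransformed (`spm_pack()` / `spm_unpack()`).

## Estimation

`spm_fit()` maximizes the likelihood with multi-start quasi-Newton
(BFGS with numerical gradients; Nelder–Mead fallback per start).  The
default 5 starts are the template values plus four random log-scale
perturbations (factors in [0.5, 2]), guarding against the local maxima
that mixture-type likelihoods are known for; ties within `1e-6` are
broken by fewer function evaluations.  Standard errors come from the
inverse central-difference Hessian (step `1e-4`) on the unconstrained
scale and are mapped to the natural scale by the delta method.  Nested
models are compared with `lr_test()`, non-nested ones with AIC
(`spm_aic()`, `compare_aic()`).  The norm-versus-baseline trade-off
($f_0$ against $\mu_0$) is weakly identified in small samples; the
reported parameter covariance surfaces this as large correlated
uncertainties rather than attempting to resolve it.

## Latent-class and genetic extensions

`latent_class_model()` holds $K$ regime-specific parameter sets plus a
multinomial-logistic membership model on baseline covariates with class
$K$ as the reference (linear predictor pinned at 0).  The observed-data
mixture likelihood is maximized directly (`fit_latent()`); an EM loop
offers no closed-form M-step here because each class likelihood is
ODE-based, so direct maximization is the default and only route.
Label switching is resolved by canonically ordering classes by ascending
allostatic-target intercept.  `select_K()` reports log-likelihood, AIC
and BIC across a range of $K$ and flags the lowest-BIC row without
auto-selecting; likelihood-ratio tests across different $K$ are refused
because the null sits on the boundary of the parameter space.  The
initial law may be class-specific (the simulator's two-class defaults
use class-specific means so that entry cross-sections already reflect
the regimes), although regimes can share it.

`genetic_model()` has the same structure, but individuals with a
recorded genotype contribute $\log p_{k_i} + \ell_i^{(k_i)}$ while
non-genotyped individuals contribute the mixture term — with the *same*
parameters in both parts, which is where the power gain over a
genotyped-only analysis comes from.  Genetic effects on a declared
component act additively on its unconstrained scale (hence
multiplicatively on positive quantities such as the hazard curvature),
keeping constrained optimization smooth, with dominant / recessive /
additive / free modes of action of the minor allele; the additive mode
sets the heterozygote effect to the mean of the homozygote effects on
that scale.  Genotype missingness is assumed independent of the outcome
given the baseline covariates (missing at random); this is an assumption,
not something the data can test here.

## Prediction and forecasting

`predict_individual()` assimilates an individual's measurements up to a
conditioning age $s$ and integrates the moment equations forward:
$S(u\,|\,s) = \exp(-\int_s^u \bar\mu)$, with the conditional-Gaussian
band $m \pm z\sqrt{\gamma}$ reported as an approximation.  Updating a
prediction after a new measurement is simply re-predicting from the
extended history.  `predict_latent()` mixes regime-specific predictions
with posterior membership weights (degenerate at an observed genotype).

`forecast_population()` aggregates simulated life histories
(microsimulation) and contrasts a baseline arm with a "what-if"
scenario (`scenario_spec()`: scaling $Q$, $\mu_0$, $B$ or $a$, shifting
$f_0$/$f_1$, optionally from a later start age).  Both arms reuse the
same random-number stream, so contrasts are paired and a null scenario
reproduces the baseline exactly.  Population heterogeneity enters only
through the declared covariate values and the initial law; demographic
flows (fertility, migration) are out of scope.

## The simulator and what the tests show

`simulate_cohort()` is a first-class module, not a fixture: it draws
class labels from the membership model, integrates the SDE by
Euler–Maruyama (default step 0.05 y), fires events with per-step
probability $1 - e^{-\mu\,dt}$ (event age at the step midpoint — an
$O(dt)$ placement choice; an exponential within-step refinement was
considered and not needed at these step sizes), records examinations on
the scheme grid with optional per-visit missingness, jitter and Gaussian
measurement noise (off by default, matching a model whose process is
observed directly), and thins genotype labels by the genotyped
fraction.  All randomness flows through R's RNG, so a seed makes every
cohort byte-reproducible.

The default synthetic conditions emulate a blood-pressure-like marker
followed from age 40: target 100 + 0.5·age-above-40 units, norm 10
units below target, feedback −0.2/y (stationary SD ≈ 6.3 units),
curvature 5e-5 /unit²/y rising ~2%/y, Gompertz baseline with ~8.5%/y
slope.  These produce realistic event fractions (events mostly between
ages 65 and 95).  Validation experiments run at desk scale: recovery
uses one seeded cohort of n = 2000 with quarterly examinations over 30
years; test calibration uses 200 cohorts of n = 300 with quadrennial
examinations; the latent-class study uses n = 1000 with two classes
separated by four stationary SDs; the genetic study uses n = 2000 with
a 3:1 curvature ratio and 30% genotyping.  Synthetic cohorts share the
model's own functional forms, so passing these experiments demonstrates
internal consistency and correct implementation — not that the
parametric forms fit any particular real data set, where sensitivity
analyses over alternative forms remain essential.

## Known limitations

* Exact conditional-Gaussian propagation relies on linear drift in $y$
  and a quadratic hazard; other forms would need approximate filtering.
* No competing risks, recurrent events, informative visit processes, or
  time-varying covariates.
* Wald intervals and the conditional-Gaussian prediction bands are
  asymptotic approximations; profile or bootstrap intervals are left as
  extension hooks.
* Scanning many genetic markers is computationally prohibitive; the
  genetic module targets small, pre-selected sets of variants.
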