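# spmaging

Joint modelling of biomarker dynamics and mortality with the
**stochastic process model (SPM) of aging**, also known as the quadratic
hazard model — for biostatisticians and biodemographers analysing
longitudinal studies in which physiological variables are measured
intermittently and followed up to death, disease onset or censoring.

The model couples a mean-reverting diffusion for a vector of biomarkers
*Y<sub>t</sub>* (age *t* in years) with a hazard that is quadratic in the
deviation from an age-dependent physiological norm:

    dY_t = a(t, X) (Y_t − f1(t, X)) dt + B dW_t
    μ(t, Y_t, X) = μ0(t, X) + (Y_t − f0(t, X))ᵀ Q(t) (Y_t − f0(t, X))

Each component has a biological reading: `a` is adaptive capacity
(negative-feedback strength of homeostatic regulation), `f1` the
allostatic trajectory the process is pulled toward, `f0` the
hazard-minimizing physiological norm (the `f1 − f0` gap measures
allostatic load), `Q` the curvature of the U-shaped risk (declining
stress resistance as it grows with age), and `μ0` the Gompertz baseline
hazard.  Because the conditional law of the process given survival and
the observation history stays Gaussian, the likelihood is assembled
exactly from a pair of moment ODEs — no numerical integration over
random effects.

The package provides:

* **model_core** — `spm_params()`, `evaluate_components()`,
  `validate_model()`, and the `spm_pack()`/`spm_unpack()` codec between
  parameters and the unconstrained optimization scale;
* **simulator** — `simulate_cohort()` / `simulate_path()`:
  Euler–Maruyama trajectories, hazard-driven event times, sparse
  examination schedules, latent classes, partial genotyping; doubles as
  the Monte-Carlo oracle for the likelihood (`mc_survival()`);
* **likelihood** — continuous-time moment-equation likelihood
  (`cohort_loglik()`, `marginal_survival()`) and the discrete-time
  variant (`discrete_time_loglik()`);
* **estimation** — multi-start maximum likelihood (`spm_fit()`), Wald
  standard errors, `lr_test()` for nested models, AIC for non-nested;
* **latent_class** — `latent_class_model()`, `fit_latent()`,
  `posterior_class()`, `select_K()`;
* **genetic_spm** — `genetic_model()`, `fit_genetic()`,
  `test_genetic_effect()` with dominant/recessive/additive/free modes of
  genetic action, for cohorts where only a sub-sample is genotyped;
* **prediction_forecast** — dynamic individual prediction
  (`predict_individual()`, `predict_latent()`) and microsimulation
  what-if forecasting (`forecast_population()`, `scenario_spec()`);
* a thin command-line wrapper (`inst/cli/spm.R`) with subcommands
  `simulate`, `fit`, `fit-latent`, `fit-genetic`, `predict`, `forecast`
  and `validate`.

## Worked example

Simulate a blood-pressure-like cohort, refit it, predict one
individual, and forecast an intervention:

```r
library(spmaging)

truth <- spm_params(dim = 1, a0 = -0.2, f1_0 = 100, f1_1 = 0.5,
                    f0_0 = 90, f0_1 = 0.5, B = 4, Q0 = 5e-5, q1 = 0.02,
                    c0 = -10.3, theta = 0.085, m0 = 120, gamma0 = 25,
                    age_range = c(40, 110))
scheme <- observation_scheme(seq(40, 88, by = 2), censor_age = 90)
cohort <- simulate_cohort(truth, n = 1000, scheme, seed = 42)
cohort
#> <spm_cohort> 1000 individuals, 17453 examinations, J = 1
#>   events: 753 (75.3%); entry 40-40, follow-up to 90

fit <- spm_fit(cohort, truth, free = c("a0", "Q0", "c0", "theta"),
               options = fit_options(starts = 3, seed = 1))
print(fit$coef, digits = 3)
#>    coef  estimate       se   lower95   upper95
#> 1    a0 -2.00e-01 3.40e-03 -2.07e-01 -0.193394
#> 2    Q0  5.11e-05 4.03e-06  4.32e-05  0.000059
#> 3    c0 -1.08e+01 5.85e-01 -1.19e+01 -9.615935
#> 4 theta  9.12e-02 7.21e-03  7.71e-02  0.105325
```

The feedback strength (−0.20/y), hazard curvature (5.1e-5, truth 5e-5)
and Gompertz coefficients are recovered with their Wald intervals
covering the generating values.  Conditional survival for individual 7
given its measurements up to age 60:

```r
pred <- predict_individual(fit$params, cohort_individual(cohort, 7),
                           at_age = 60, horizon = 90, grid_n = 7)
round(pred, 3)
#>   age survival      m1     v1
#> 1  60    1.000 112.860  0.000
#> 2  65    0.951 124.618 34.178
#> 3  70    0.875 130.398 38.463
#> 4  75    0.771 134.037 38.960
#> 5  80    0.643 136.928 38.989
#> 6  85    0.497 139.555 38.960
#> 7  90    0.342 142.091 38.924
```

`survival` is S(u | history to 60); `m1`/`v1` are the conditional mean
and variance of the biomarker (the mean relaxes from the observed 112.9
toward the fitted allostatic trajectory).  A stress-resistance
intervention that halves the hazard curvature from entry:

```r
fc <- forecast_population(fit$params, 40, seq(50, 90, by = 10),
                          n_sim = 5000,
                          scenario = scenario_spec(Q_scale = 0.5),
                          seed = 2)
round(as.data.frame(fc)[, c("age", "survival", "survival_scen")], 3)
#>   age survival survival_scen
#> 1  50    0.885         0.933
#> 2  60    0.768         0.854
#> 3  70    0.638         0.744
#> 4  80    0.472         0.564
#> 5  90    0.245         0.308
```

Both arms share random numbers, so the +6 to +11 percentage-point
survival gains are paired contrasts, not two noisy simulations.

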