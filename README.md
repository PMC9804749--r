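# smcjm — substantive-model-compatible multilevel multiple imputation

`smcjm` imputes missing covariates in two-level data (individuals nested in
clusters) by joint modelling, for analysts whose final model is a
mixed-effects ("substantive") model. It implements three strategies:

* **JM-Hom** — one homoscedastic multilevel latent-normal joint model for
  outcome, covariates and auxiliaries, fitted by data-augmentation MCMC.
  Compatible with a random-intercept analysis model.
* **JM-Het** — cluster-specific level-1 covariances drawn around an
  inverse-Wishart hierarchy `IW(a, A)`.
* **SMC-JM** — the joint distribution is factorised as
  `f(y, x) = f(y | x) f(x)`: covariates follow the latent-normal joint
  model and `f(y | x)` *is* the analyst's substantive model

  ```
  y_ij = beta0 + beta1 PAR_ij + beta2 age_ij + u_j0 + u_j1 PAR_ij + e_ij,
  (u_j0, u_j1) ~ N(0, Omega_u),  e_ij ~ N(0, sigma_e^2),
  ```

  with binary/ordinal outcomes handled by logit / cumulative-logit
  families. Proposed imputations are drawn from the covariate-model
  conditional and accepted with probability `min(1, exp(Delta))`, where
  `Delta` is the substantive log-likelihood ratio — one row's contribution
  for level-1 cells, the cluster's summed contributions for level-2 cells.
  This keeps imputation compatible with random slopes, powers and
  interactions, where standard joint-model imputation is biased.

Completed datasets are analysed with `fit_mixed()` (lme4 / mgcv under the
hood) and pooled with `pool_rubin()` (Rubin's rules:
`T = W + (1 + 1/M) B`, small-sample degrees of freedom). An ADEMP-style
harness (`scenario_config()`, `run_study()`) generates the study scenarios
— random intercept, random slope, polynomials, interactions, level-2
covariates, auxiliaries, binary/ordinal outcomes, alternative covariate
mechanisms, systematically missing clusters — and reports bias, empirical
and model-based SEs and coverage with Monte-Carlo errors.

## Worked example

Generate one replicate of the random-slope scenario (50 clinicians × 40
admissions; binary PAR use, prevalence ≈ 0.7; standardised age), make ~30%
of cases incomplete under a MAR mechanism conditional on the outcome, and
impute compatibly with the random-slope model:

```r
library(smcjm)
cfg <- scenario_config("random_slope", seed = 7)
gen <- generate_scenario(cfg, rep = 1)
set.seed(8)
ds  <- apply_mar(gen$dataset, target = 0.30, gamma1 = 1)
missingness_summary(ds)$incomplete_rows
#> [1] 0.2955

spec <- gen$spec
spec
#> substantive model [gaussian_identity]: y ~ PAR + age + (1 + PAR | cluster)

imp  <- impute_smc_jm(ds, spec,
                      mcmc_config(n_burn = 500, n_between = 250,
                                  n_imputations = 5, seed = 9))
fits <- lapply(imp$imputations, fit_mixed, spec = spec)
pool_rubin(fits)
#> Rubin-pooled estimates (M = 5 ):
#>             estimate     se         df  ci_low ci_high
#> (Intercept)   0.3123 0.0159 36389.2229  0.2812  0.3435
#> PAR           0.4922 0.0220 78611.0430  0.4491  0.5353
#> age           0.0044 0.0037   470.4609 -0.0027  0.0116
#> variance components (means):
#> sigma_u00 sigma_u01 sigma_u11  sigma_e2
#>    0.0103   -0.0070    0.0210    0.0196
```

The generating values for this scenario are beta = (0.297, 0.511, −0.004)
with random-effect covariance (0.015, −0.011, 0.021) and residual variance
0.02. On this single replicate the PAR effect (0.492, CI 0.449–0.535) and
the random-slope variance (0.0210 vs 0.021) are recovered even though the
slope covariate is ~15% missing — the property that motivates SMC-JM —
while the near-zero age coefficient lands a couple of standard errors from
its tiny true value, a reminder that one replicate carries Monte-Carlo
noise; `run_study()` averages these quantities over replicates.

Chains are inspected with `get_chain()` / `mcmc_diagnostics()`, or from the
shell via the thin CLI in `inst/cli/smcjm.R` (`impute`, `simulate`,
`diagnose` subcommands).

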