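---
title: "Substantive-model-compatible multilevel imputation: models, samplers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substantive-model-compatible multilevel imputation: models, samplers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcjm)
```

## The problem

Two-level data — individuals (level 1) nested in clusters such as
clinicians or centres (level 2) — routinely arrive with missing covariate
values at both levels. Multiple imputation is the standard remedy, but it is
only valid when the imputation model is *compatible* with the analysis
("substantive") model: both must be derivable from a single joint model by
conditioning. A multivariate latent-normal joint model with cluster random
effects is compatible with a random-intercept linear mixed model, but it
cannot encode a random slope on a partially observed covariate, nor
polynomial or interaction terms: conditioning a homoscedastic joint normal
on the covariates yields outcome-given-covariates coefficients that are
functions of the (common) covariance elements alone, so they cannot vary by
cluster. `implied_conditional_coefficients()` implements exactly this
algebra and is used as the package's compatibility oracle in the tests.

The package provides three imputation strategies for this setting:

* **JM-Hom** (`impute_jm_hom`): all variables — outcome, covariates,
  auxiliaries — follow one homoscedastic multilevel latent-normal joint
  model, fitted by data-augmentation MCMC.
* **JM-Het** (`impute_jm_het`): the level-1 covariance is cluster-specific,
  with the per-cluster matrices drawn around an inverse-Wishart hierarchy
  `IW(a, A)`. This permits cluster-varying associations but is still not
  fully compatible with a random-slope analysis model.
* **SMC-JM** (`impute_smc_jm`): the joint distribution is factorised as
  f(y, x) = f(y | x) f(x). The covariates (and auxiliaries) follow the
  latent-normal joint model; f(y | x) *is* the user's substantive model.
  Proposed covariate imputations are drawn from the covariate-model
  conditional and accepted by a Metropolis-Hastings step against the
  substantive likelihood, which makes the imputation compatible with random
  slopes, powers and interactions by construction.

## Model and samplers

### The latent-normal joint model

Each level-1 variable k satisfies z\_{k,ij} = alpha\_k + u\_{k,j} +
e\_{k,ij} with level-1 residual covariance Omega\_1 and level-2
random-effect covariance Omega\_2; level-2 variables have no level-1
residual and live entirely in Omega\_2, whose cross-block links them to the
level-1 variables' random effects. A binary variable is represented by a
latent normal whose sign encodes the value (probit device); its level-1
residual variance is constrained to one for identifiability.

One Gibbs sweep updates, in fixed order: (1) latent normals for observed
binary cells (truncated conditional normals); (2) all missing cells from
their conditional multivariate normal given the row's observed components
and current parameters; (3) cluster random effects (conjugate normal);
(4) Omega\_1 — conjugate inverse-Wishart when unconstrained, otherwise a
Metropolis-Hastings step (below); (5) Omega\_2 likewise; (6) intercepts
(flat prior, conjugate). The sweep order is fixed purely for
reproducibility. Imputations are registered at iterations `n_burn`,
`n_burn + n_between`, ... to give M approximately independent draws.

### Constrained covariance updates

With latent-binary rows, the conditional distribution of a covariance
matrix is non-standard. The package parametrises the constrained space by
the Cholesky factor: strictly-lower-triangular entries plus log-diagonals
of unconstrained rows are free, while each constrained row's diagonal is
determined by its unit-variance requirement. A random-walk proposal in this
parametrisation is corrected by the exact Jacobian of the map to the
covariance scale, so the chain targets the correct posterior. The proposal
standard deviation is `mh_step_scale * 10 / sqrt(n_eff * d)` where `n_eff`
is the number of rows informing the update and `d` the number of free
parameters — the random-walk optimal-scaling rule — with five inner
proposals per sweep and no adaptive tuning; runs are therefore fully
reproducible from the seed. With the default `mh_step_scale = 0.1` this
gives acceptance rates around 15-40% across the study sizes used here.

### Heteroscedastic hierarchy

Under JM-Het each cluster's Omega\_{1,j} has prior `IW(a, A)` with `a`
fixed at p + 3 (p level-1 variables). Under this likelihood the conjugate
hyperprior for the scale matrix A is Wishart, and the package updates A
conjugately each sweep. With very small clusters the per-cluster matrices
shrink toward A; a cluster of size one triggers a warning rather than an
error.

### The SMC-JM kernel

Each sweep first refreshes latent normals (including those of imputed
cells, truncated to their current value — a valid extra Gibbs step that
helps mixing), then proposes every missing cell, one at a time, from the
covariate-model conditional given the row's other current values. Because
the proposal is exactly the covariate factor's conditional, the acceptance
ratio reduces to the substantive-likelihood ratio: a single row's
contribution for a level-1 cell, and the sum of the cluster's contributions
for a level-2 cell (which makes level-2 decisions invariant to
within-cluster row order). Derived terms (powers, products) are always
recomputed from the proposed base values — they are never imputed as free
columns, which is precisely what preserves compatibility. After the
covariate sweep, the substantive parameters are updated by one Bayesian
sweep on the current completed data: conjugate draws for the gaussian
family; random-walk Metropolis for the binomial-logit and
cumulative-logit families, with order-preserving cutpoint proposals.

A frozen-parameter mode (`control = list(freeze_covariate_params = TRUE,
freeze_substantive_params = TRUE, ...)`) runs the bare imputation kernel at
fixed parameters; the tests use it to verify that the kernel's stationary
law matches the posterior computed by exact enumeration on a binary toy.

### Priors and initialisation

Intercepts have flat priors. Omega\_1 and Omega\_2 have inverse-Wishart
(p + 1, I) priors; the substantive random-effect covariance has
inverse-Wishart(r + 2, 0.01 I) — scaled to the magnitude of plausible
random-effect variances so that a weak prior does not inflate small
variance components — and the residual variance an inverse-gamma(0.001,
0.001). Missing continuous cells start at the observed mean, binary cells
at a Bernoulli draw with observed prevalence; random effects start at zero;
Omega\_1 starts at the empirical covariance of the initialised working
values with latent-binary diagonals renormalised to one. Because the start
is near the posterior mode, short burn-ins suffice at the study sizes used
here; traces of the intercepts and substantive coefficients are stationary
well before iteration 100 (`mcmc_diagnostics()` reports means, lag-1
autocorrelation and split-chain ratios).

## Analysis and pooling

`fit_mixed()` fits the substantive model to each completed dataset: REML
(switchable to ML) via lme4 for gaussian outcomes, Laplace ML via
`lme4::glmer` for binomial ones, and a cumulative-logit (ocat) model with a
cluster random-effect smooth via mgcv for ordinal ones — the package does
not re-implement mixed-model optimisers. `pool_rubin()` combines the M
fits: qbar, between-variance B, within-variance W, total T = W +
(1 + 1/M) B, degrees of freedom (M−1)(1 + W/((1+1/M)B))²; when B = 0 the
degrees of freedom are taken as infinite by convention. Variance components
are pooled as simple means and reported as point summaries only.
Non-converged fits are excluded from pooling with a warning and the
replicate flagged, mirroring standard simulation-study practice.

## The simulation harness and its generator

`run_study()` follows the ADEMP pattern: generate, fit the full-data
reference, impose missingness, fit the complete records, impute with each
requested method, fit and pool, then report bias, relative bias, empirical
and model-based SEs and coverage, each with its Monte-Carlo error (the
Morris-White-Crowther formulas implemented in `performance_measures()`).
Every replicate derives a child seed from the master seed and the replicate
index, and each method arm re-seeds independently, so reports are
bit-reproducible and arms are comparable across method subsets.

The generator's defaults are the package's study conditions:

* **Dimensions**: 50 clusters of 40 rows. Under these dimensions the
  full-data model SE of the binary-covariate effect is of the order of the
  reference results the tests compare against.
* **Substantive truths** (random-intercept case): beta = (0.313, 0.497,
  −0.005) for intercept, binary level-1 covariate ("PAR") and standardised
  continuous covariate ("age"); random-intercept variance 0.010. The
  random-slope case uses beta = (0.297, 0.511, −0.004) with random-effect
  covariance (0.015, −0.011, 0.021). The residual variance, not tabulated
  in the reference, is set to 0.02, chosen once so that outcome noise,
  cluster heterogeneity and effect sizes sit in realistic proportion.
* **Covariates**: PAR has latent intercept qnorm(0.7) (prevalence ~0.70,
  echoing the motivating trial's observed PAR use), latent unit level-1
  variance and cluster variance 0.15; age is standardised with cluster
  variance 0.10; latent level-1 and level-2 correlations are 0.3. Two
  alternative mechanisms probe sensitivity to the covariate model: PAR
  drawn marginally Bernoulli with age shifted by PAR; and age drawn first
  with PAR logistic in a quadratic of age (deliberately outside the
  latent-normal family).
* **Missingness**: each target covariate is masked with probability
  logistic(gamma0 + 1.0 × standardised outcome), per row at level 1 and per
  cluster at level 2; gamma0 is calibrated by root-finding so the expected
  incomplete-case fraction is 0.30. A systematically-missing option masks
  whole clusters for a stated fraction of clusters.
* **Slope inflation** multiplies the random-slope variance by the factor
  and the intercept-slope covariance by its square root. Scaling the
  covariance by the full factor would make the random-effect covariance
  indefinite at factor 5 with the base truths above, so the
  correlation-preserving scaling is the one under which the inflated
  scenario exists at all.
* **Chain lengths**: desk-scale studies use n_burn = 150, n_between = 75,
  M = 5; smoke runs use shorter chains. These were fixed once from
  convergence traces under the near-mode initialisation.

### What the generator does and does not emulate

The generator reproduces the *structure* of the motivating setting —
clustered binary and continuous covariates at both levels, an outcome
driven by a mixed model, outcome-dependent missingness — with round
parameter values; it does not reproduce any real dataset, three-level
nesting, unequal hospital effects, or missingness mechanisms that depend on
unobserved values (MNAR). Passing tests therefore demonstrate the
statistical properties of the methods under a correctly structured
two-level world, not agreement with any particular trial. One consequence
of the chosen calibration is visible in the complete-records arm: because
the outcome's residual noise is small relative to the binary covariate's
effect, selection on the outcome is nearly selection on that covariate, and
complete-records estimates are more biased here than a milder missingness
dependence would produce. The imputation arms are unaffected — this is the
situation imputation exists for.

## Numerical choices and degenerate inputs

Covariance draws are guarded by symmetrisation and, where needed, a ridge
of relative size 1e-10; a proposal that would violate a unit-diagonal
constraint is rejected outright. Zero random-effect variances are
legitimate generator inputs (handled by an eigenvalue square root);
all-missing variables and observed-constant binary variables are rejected
with explicit errors, since they carry no information for the latent scale.
Cluster labels are arbitrary and mapped to contiguous indices internally.
The ordinal family requires integer codes 1..K with K ≥ 3 and at least one
observation per extreme category in the initialiser's cumulative-frequency
cutpoint start.

## Known limitations

* Three-level structures are out of scope; a third level can only be
  absorbed as fixed effects.
* Categorical variables with more than two levels are not supported as
  covariates; ordinal outcomes are supported in the substantive family
  only.
* Survival (Cox/frailty) substantive models and MNAR sensitivity analyses
  are not implemented.
* Level-2 summaries of level-1 variables (for example cluster means) cannot
  be used as imputation-model predictors; omitting them can bias analyses
  that rely on such constructs.
* The mixed ordinal fit delegates to a penalised-likelihood (ocat) fitter,
  whose variance-component point estimates are not pooled beyond simple
  means.
* Relative bias is reported but flagged for parameters whose true value is
  near zero; absolute bias is the meaningful measure there.
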