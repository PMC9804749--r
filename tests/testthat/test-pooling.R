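mk_fit <- function(est, se, vc = c(sigma_u00 = 0.1, sigma_e2 = 1),
                   converged = TRUE) {
  structure(list(estimates = est, se = se, vc = vc, converged = converged,
                 singular = FALSE), class = "model_fit")
}

test_that("Rubin's rules reproduce the hand-computed worked example", {
  fits <- lapply(c(1, 2, 3), function(q)
    mk_fit(c(theta = q), c(theta = 1)))
  pl <- pool_rubin(fits)
  expect_equal(unname(pl$qbar), 2)
  expect_equal(unname(pl$between), 1)
  expect_equal(unname(pl$within), 1)
  expect_equal(unname(pl$total_var), 1 + (1 + 1 / 3) * 1)
  expect_equal(unname(pl$total_var), 2.3333, tolerance = 1e-4)
  expect_equal(unname(pl$df), 2 * (1 + 1 / ((4 / 3)))^2)
})

test_that("zero between-imputation variance falls back to normal quantiles", {
  fits <- lapply(1:4, function(i) mk_fit(c(theta = 1), c(theta = 0.2)))
  pl <- pool_rubin(fits)
  expect_equal(unname(pl$qbar), 1)
  expect_equal(unname(pl$between), 0)
  expect_equal(unname(pl$total_var), 0.04)
  expect_equal(unname(pl$df), Inf)
  expect_equal(unname(pl$ci[, 2] - pl$ci[, 1]),
               2 * qnorm(0.975) * 0.2)
})

test_that("adding between-imputation spread never shrinks the total variance", {
  base <- lapply(c(1, 1.1, 0.9), function(q) mk_fit(c(b = q), c(b = 0.5)))
  t0 <- pool_rubin(base)$total_var
  for (bump in c(0.2, 0.5, 1)) {
    pert <- base
    pert[[1]]$estimates <- pert[[1]]$estimates + bump
    expect_gte(pool_rubin(pert)$total_var, t0)
  }
})

test_that("pooling rejects inconsistent input and flags exclusions", {
  f1 <- mk_fit(c(a = 1), c(a = 1))
  f2 <- mk_fit(c(b = 1), c(b = 1))
  expect_error(pool_rubin(list(f1, f2)), "names differ")
  f3 <- mk_fit(c(a = 2), c(a = 1), converged = FALSE)
  expect_warning(p <- pool_rubin(list(f1, f1, f3)), "non-converged")
  expect_equal(p$m, 2)
  expect_error(suppressWarnings(pool_rubin(list(f1, f3))), "at least 2")
})

test_that("implied conditional coefficients follow the normal algebra", {
  # diagonal covariance: no cross-covariance, all coefficients zero
  r0 <- implied_conditional_coefficients(c(0, 0, 0), diag(c(2, 1, 3)))
  expect_equal(unname(r0$beta), c(0, 0))
  # worked 3x3 example (outcome, PAR, age ordering)
  om <- matrix(c(2, 1, 0,
                 1, 1, 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  r1 <- implied_conditional_coefficients(c(0.5, 0.2, 0), om)
  expect_equal(unname(r1$beta), c(1, 0))
  expect_equal(r1$intercept, 0.5 - 0.2)
  expect_equal(r1$residual_var, 1)
  # joint scaling of the covariance leaves the coefficients unchanged
  r2 <- implied_conditional_coefficients(c(0.5, 0.2, 0), 3.7 * om)
  expect_equal(r2$beta, r1$beta)
  expect_error(
    implied_conditional_coefficients(c(0, 0, 0),
                                     matrix(c(1, 0, 0, 0, 1, 1, 0, 1, 1), 3)),
    "singular")
})

test_that("the mixed-model fitter recovers generating fixed effects", {
  cfg <- scenario_config("random_intercept", n_clusters = 50,
                         cluster_size = 40, seed = 63)
  gen <- generate_scenario(cfg, 1)
  fit <- fit_mixed(gen$dataset, gen$spec)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates["PAR"] - 0.497), 4 * fit$se["PAR"])
  expect_lt(abs(fit$estimates["(Intercept)"] - 0.313),
            4 * fit$se["(Intercept)"])
  expect_gt(fit$vc["sigma_u00"], 0)
})

test_that("zero cluster variance drives the fit to the OLS solution", {
  cfg <- scenario_config("random_intercept", n_clusters = 40,
                         cluster_size = 40, seed = 65,
                         truth = list(sigma_u00 = 0))
  gen <- generate_scenario(cfg, 1)
  fit <- fit_mixed(gen$dataset, gen$spec)
  df <- as.data.frame(gen$dataset)
  ols <- stats::lm(y ~ PAR + age, data = df)
  expect_lt(fit$vc["sigma_u00"], 5e-4)
  expect_equal(unname(fit$estimates), unname(stats::coef(ols)),
               tolerance = 0.01)
  # a random-slope spec on random-intercept data finds ~ zero slope variance
  cfg2 <- scenario_config("random_intercept", n_clusters = 40,
                          cluster_size = 40, seed = 66)
  gen2 <- generate_scenario(cfg2, 1)
  spec_rs <- substantive_model_spec(
    "y", c("PAR", "age"), random = list(intercept = TRUE, slopes = "PAR"))
  fit2 <- fit_mixed(gen2$dataset, spec_rs)
  expect_lt(fit2$vc["sigma_u11"], 0.005)
})

test_that("pooled intervals attain nominal coverage in a gaussian toy", {
  # analytic MI toy: n observations of N(0,1), half missing, proper
  # imputation from the posterior predictive; 2000 replicates
  set.seed(67)
  n <- 40; nobs <- 20; M <- 5
  hits <- logical(2000)
  for (r in seq_len(2000)) {
    x <- rnorm(nobs)
    fits <- lapply(seq_len(M), function(m) {
      s2 <- 1 / rgamma(1, (nobs - 1) / 2, sum((x - mean(x))^2) / 2)
      mu <- rnorm(1, mean(x), sqrt(s2 / nobs))
      xm <- rnorm(n - nobs, mu, sqrt(s2))
      xc <- c(x, xm)
      mk_fit(c(mu = mean(xc)), c(mu = sd(xc) / sqrt(n)))
    })
    ci <- pool_rubin(fits)$ci
    hits[r] <- ci[1, 1] <= 0 && 0 <= ci[1, 2]
  }
  cov <- 100 * mean(hits)
  mce <- sqrt(cov * (100 - cov) / 2000)
  expect_lt(abs(cov - 95), 3 * mce + 1)
})

test_that("joint-model compatibility: implied coefficients match large-sample fits", {
  # all-continuous joint model, where the conditional algebra is exact
  sim <- make_jm_sim(J = 60, nj = 60, binary_par = FALSE, seed = 69)
  ds <- multilevel_dataset(sim$df, sim$meta)
  spec <- substantive_model_spec("y", c("PAR", "age"))
  fit <- fit_mixed(ds, spec)
  implied <- implied_conditional_coefficients(sim$alpha, sim$Om1, sim$Om2)
  expect_lt(abs(fit$estimates["PAR"] - implied$beta[1]),
            3 * fit$se["PAR"])
  expect_lt(abs(fit$estimates["age"] - implied$beta[2]),
            3 * fit$se["age"])
  expect_lt(abs(fit$estimates["(Intercept)"] -
                  (implied$intercept - 0)), 4 * fit$se["(Intercept)"])
})
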