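test_that("substantive log-likelihood matches hand evaluations", {
  spec <- substantive_model_spec("y", "x")
  prm <- list(beta = c(0, 1), sigma2_e = 1)
  # zero residual at unit variance
  expect_equal(loglik_substantive(spec, prm, y = 2, rows = c(1, 2)),
               -0.5 * log(2 * pi))
  # y = 1, predictor 0, sigma2 = 4
  prm4 <- list(beta = c(0, 0), sigma2_e = 4)
  expect_equal(loglik_substantive(spec, prm4, y = 1, rows = c(1, 1)),
               -0.5 * log(8 * pi) - 1 / 8)
  # binomial at a zero linear predictor
  specb <- substantive_model_spec("y", "x", family = "binomial_logit")
  expect_equal(loglik_substantive(specb, list(beta = c(0, 0)), y = 1,
                                  rows = c(1, 0)), log(0.5))
  # random-effect contribution enters through the random design
  prm_u <- list(beta = c(0, 1), sigma2_e = 1)
  ll <- loglik_substantive(spec, prm_u, y = 3, rows = c(1, 2),
                           u = c(1), rdesign = matrix(1, 1, 1))
  expect_equal(ll, -0.5 * log(2 * pi))   # eta = 2 + 1 = 3 = y
  expect_error(loglik_substantive(spec, list(beta = c(Inf, 1), sigma2_e = 1),
                                  y = 1, rows = c(1, 1)), "non-finite")
})

test_that("binary proposals follow the latent probit probability", {
  ds <- make_toy_ds(J = 4, nj = 6, miss = 0, seed = 41)
  df <- as.data.frame(ds)
  df$PAR[3] <- NA
  ds <- multilevel_dataset(df, rbind(variable_meta("cl", 2, "continuous",
                                                   "cluster_id"), ds$meta))
  spec <- substantive_model_spec("y", c("PAR", "age"))
  st <- smc_state_init(ds, spec, seed = 43)
  set.seed(44)
  draws <- replicate(2e4, propose_covariate(st, ds, "PAR", row = 3)$value)
  one <- propose_covariate(st, ds, "PAR", row = 3)
  p_exp <- pnorm(one$mean / one$sd)
  se <- sqrt(p_exp * (1 - p_exp) / 2e4)
  expect_lt(abs(mean(draws) - p_exp), 4 * se)
  expect_equal(one$log_ratio, 0)
  # with a diagonal level-1 covariance the conditional ignores the other
  # covariates: the proposal mean reduces to alpha + u
  st$covariate$omega1 <- diag(c(1, 0.9))
  prop <- propose_covariate(st, ds, "PAR", row = 3)
  j <- ds$cluster[3]
  expect_equal(prop$mean,
               st$covariate$alpha[1] + st$covariate$u[j, 1])
  expect_error(propose_covariate(st, ds, "PAR", row = 1), "observed")
})

test_that("MH acceptance follows the substantive likelihood ratio", {
  # two-row cluster with a level-2 covariate: delta sums both rows
  df <- data.frame(cl = c(1, 1, 2, 2), y = c(5, 5, 0, 0),
                   x2 = c(NA, NA, 0, 0), age = rnorm(4))
  meta <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
                variable_meta("y", 1, "continuous", "outcome"),
                variable_meta("x2", 2, "continuous", "covariate"),
                variable_meta("age", 1, "continuous", "covariate"))
  ds <- multilevel_dataset(df, meta)
  spec <- substantive_model_spec("y", "x2")
  st <- smc_state_init(ds, spec, seed = 45)
  st$substantive$beta <- c(0, 1)
  st$substantive$sigma2_e <- 1
  st$substantive$u_sub <- matrix(0, 2, 1)
  st$covariate$values[1:2, "x2"] <- 0
  prop <- list(variable = "x2", row = NULL, cluster = 1, value = 5, z = 5,
               u = 5, mean = 0, sd = 1, log_ratio = 0)
  out <- mh_accept_covariate(st, ds, spec, prop)
  # hand sum over the two rows: 2 * (dnorm(5;5) - dnorm(5;0)) = 25
  expect_equal(out$delta, 25)
  expect_equal(out$prob, 1)
  expect_true(out$accept)
  # a proposal identical to the current value has delta 0, accepted w.p. 1
  prop0 <- within_list(prop, value = 0, z = 0, u = 0)
  out0 <- mh_accept_covariate(st, ds, spec, prop0)
  expect_equal(out0$delta, 0)
  expect_equal(out0$prob, 1)
  # an overwhelmingly unlikely proposal is rejected
  propbad <- within_list(prop, value = -1e4, z = -1e4, u = -1e4)
  outbad <- mh_accept_covariate(st, ds, spec, propbad)
  expect_equal(outbad$prob, 0)
  expect_false(outbad$accept)
})

test_that("level-2 acceptance is invariant to within-cluster row order", {
  set.seed(47)
  df <- data.frame(cl = rep(1:4, each = 5), y = rnorm(20),
                   x2 = rep(c(NA, 0.4, -0.2, 0.1), each = 5),
                   age = rnorm(20))
  meta <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
                variable_meta("y", 1, "continuous", "outcome"),
                variable_meta("x2", 2, "continuous", "covariate"),
                variable_meta("age", 1, "continuous", "covariate"))
  ds <- multilevel_dataset(df, meta)
  spec <- substantive_model_spec("y", c("x2", "age"))
  st <- smc_state_init(ds, spec, seed = 48)
  prop <- list(variable = "x2", row = NULL, cluster = 1, value = 0.7, z = 0.7,
               u = 0.7, mean = 0, sd = 1, log_ratio = 0)
  d1 <- mh_accept_covariate(st, ds, spec, prop)$delta
  perm <- c(5:1, 6:20)
  ds2 <- multilevel_dataset(df[perm, ], meta)
  st2 <- st
  st2$covariate$values <- st$covariate$values[perm, ]
  st2$covariate$z <- st$covariate$z[perm, ]
  d2 <- mh_accept_covariate(st2, ds2, spec, prop)$delta
  expect_equal(d1, d2)
})

test_that("frozen-kernel imputation matches exact enumeration", {
  # parameters frozen; the stationary law of the imputed binary covariate
  # must match the posterior computed by enumeration over {0, 1}
  df <- data.frame(cl = c(1, 1, 2, 2), y = c(0.4, 0.9, 0.3, 0.5),
                   PAR = c(1, NA, 0, 1))
  meta <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
                variable_meta("y", 1, "continuous", "outcome"),
                variable_meta("PAR", 1, "binary", "covariate"))
  ds <- multilevel_dataset(df, meta)
  spec <- substantive_model_spec("y", "PAR")
  alpha <- 0.3; b0 <- 0.2; b1 <- 0.6; s2 <- 0.09
  init_cov <- list(alpha = alpha, u = matrix(0, 2, 1),
                   omega1 = matrix(1, 1, 1), omega2 = matrix(0.001, 1, 1),
                   z = matrix(c(0.5, 0.5, -0.5, 0.5), 4),
                   values = matrix(c(1, 1, 0, 1), 4,
                                   dimnames = list(NULL, "PAR")),
                   variables = "PAR")
  init_sub <- list(beta = c(b0, b1), u_sub = matrix(0, 2, 1),
                   omega_u = matrix(1e-6, 1, 1), sigma2_e = s2,
                   cutpoints = NULL)
  res <- impute_smc_jm(
    ds, spec, mcmc_config(n_burn = 3e4, n_between = 1, n_imputations = 2,
                          seed = 49),
    control = list(freeze_covariate_params = TRUE,
                   freeze_substantive_params = TRUE,
                   init_covariate = init_cov, init_substantive = init_sub,
                   record_cells = TRUE))
  tr <- res$cell_trace[seq_len(3e4), 1]
  lik1 <- pnorm(alpha) * dnorm(0.9, b0 + b1, sqrt(s2))
  lik0 <- (1 - pnorm(alpha)) * dnorm(0.9, b0, sqrt(s2))
  p_exact <- lik1 / (lik1 + lik0)
  bm <- tapply(tr, rep(seq_len(100), each = 300), mean)
  se <- stats::sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(tr) - p_exact), 3 * se + 0.002)
})

test_that("gaussian substantive updates concentrate on the GLS estimate", {
  set.seed(51)
  J <- 15; nj <- 10; n <- J * nj
  cl <- rep(seq_len(J), each = nj)
  x <- rnorm(n)
  sig_u <- 0.3; sig_e <- 0.5
  u <- rnorm(J, 0, sig_u)
  y <- 1 + 0.8 * x + u[cl] + rnorm(n, 0, sig_e)
  df <- data.frame(cl = cl, y = y, PAR = rbinom(n, 1, 0.5), age = x)
  ds <- multilevel_dataset(df, toy_meta())
  spec <- substantive_model_spec("y", "age")
  st <- smc_state_init(ds, spec, seed = 52)
  # GLS at the true variance components
  X <- cbind(1, x)
  Vb <- lapply(seq_len(J), function(j)
    sig_u^2 + diag(sig_e^2, nj))
  V <- matrix(0, n, n)
  for (j in seq_len(J)) {
    ix <- which(cl == j)
    V[ix, ix] <- Vb[[j]]
  }
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  set.seed(53)
  draws <- matrix(NA_real_, 600, 2)
  for (it in seq_len(600)) {
    st <- update_substantive_params(st, ds, spec)
    draws[it, ] <- st$substantive$beta
  }
  keep <- draws[101:600, ]
  bm <- apply(keep, 2, function(v)
    tapply(v, rep(1:50, each = 10), mean))
  mcse <- apply(bm, 2, stats::sd) / sqrt(50)
  expect_true(all(abs(colMeans(keep) - drop(b_gls)) <
                    3 * mcse + 3 * apply(keep, 2, stats::sd) / sqrt(500) + 0.05))
})

test_that("non-gaussian update sweeps keep their structural constraints", {
  set.seed(55)
  J <- 8; nj <- 10; n <- J * nj
  cl <- rep(seq_len(J), each = nj)
  age <- rnorm(n)
  eta <- 0.8 * age + rnorm(J, 0, 0.4)[cl]
  yord <- 1L + rowSums(stats::runif(n) >
                         cbind(plogis(-0.5 - eta), plogis(0.5 - eta),
                               plogis(1.5 - eta)))
  df <- data.frame(cl = cl, compl4 = yord, PAR = rbinom(n, 1, 0.5), age = age)
  meta <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
                variable_meta("compl4", 1, "continuous", "outcome"),
                variable_meta("PAR", 1, "binary", "covariate"),
                variable_meta("age", 1, "continuous", "covariate"))
  ds <- multilevel_dataset(df, meta)
  spec <- substantive_model_spec("compl4", "age",
                                 family = "ordinal_cumulative_logit")
  st <- smc_state_init(ds, spec, seed = 56)
  for (it in 1:40) {
    st <- update_substantive_params(st, ds, spec)
    expect_true(!is.unsorted(st$substantive$cutpoints, strictly = TRUE))
    expect_true(is_pd(st$substantive$omega_u))
  }
})

test_that("SMC-JM with no missing cells returns the input, with chains", {
  ds <- make_toy_ds(miss = 0, seed = 57)
  spec <- substantive_model_spec("y", c("PAR", "age"))
  res <- impute_smc_jm(ds, spec, mcmc_config(n_burn = 30, n_between = 10,
                                             n_imputations = 2, seed = 58))
  for (cd in res$imputations) expect_identical(cd$data, ds$data)
  expect_true(all(c("beta[(Intercept)]", "beta[PAR]", "sigma2_e") %in%
                    colnames(res$chains)))
  expect_gt(stats::sd(get_chain(res, "beta[PAR]")), 0)
})

test_that("with a flat substantive model SMC-JM reduces to joint-model Gibbs", {
  # slopes frozen at zero: every proposal is accepted and the covariate
  # imputation law coincides with the covariates-only homoscedastic model
  sim <- make_jm_sim(J = 20, nj = 20, seed = 59)
  dfm <- mcar_mask(sim$df, c("PAR", "age"), 0.25, seed = 60)
  ds <- multilevel_dataset(dfm, sim$meta)
  spec <- substantive_model_spec("y", c("PAR", "age"))
  flat_sub <- list(beta = c(mean(sim$df$y), 0, 0), u_sub = matrix(0, 20, 1),
                   omega_u = matrix(1e-6, 1, 1), sigma2_e = 1,
                   cutpoints = NULL)
  cfg <- mcmc_config(n_burn = 300, n_between = 100, n_imputations = 4,
                     seed = 61)
  smc <- impute_smc_jm(ds, spec, cfg,
                       control = list(freeze_substantive_params = TRUE,
                                      init_substantive = flat_sub))
  expect_equal(smc$accept_cell, 1)
  hom <- impute_jm_hom(ds, cfg, variables = c("PAR", "age"))
  miss_age <- !ds$mask[, "age"]
  m_smc <- sapply(smc$imputations, function(cd) mean(cd$data[miss_age, "age"]))
  m_hom <- sapply(hom$imputations, function(cd) mean(cd$data[miss_age, "age"]))
  pool_sd <- sqrt(stats::var(m_smc) / 4 + stats::var(m_hom) / 4) + 0.02
  expect_lt(abs(mean(m_smc) - mean(m_hom)), 4 * pool_sd)
  p_smc <- sapply(smc$imputations, function(cd)
    mean(cd$data[!ds$mask[, "PAR"], "PAR"]))
  p_hom <- sapply(hom$imputations, function(cd)
    mean(cd$data[!ds$mask[, "PAR"], "PAR"]))
  pool_sd_p <- sqrt(stats::var(p_smc) / 4 + stats::var(p_hom) / 4) + 0.02
  expect_lt(abs(mean(p_smc) - mean(p_hom)), 4 * pool_sd_p)
})
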