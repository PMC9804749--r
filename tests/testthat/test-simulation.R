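test_that("null truth produces exchangeable noise with near-zero ICC", {
  cfg <- scenario_config("random_intercept", n_clusters = 30,
                         cluster_size = 30, seed = 71,
                         truth = list(beta = c("(Intercept)" = 0, PAR = 0,
                                               age = 0),
                                      sigma_u00 = 0, sigma_e2 = 0.02))
  gen <- generate_scenario(cfg, 1)
  y <- gen$dataset$data[, "y"]
  cl <- gen$dataset$cluster
  fit <- stats::aov(y ~ factor(cl))
  ms <- summary(fit)[[1]]$`Mean Sq`
  icc <- max(0, (ms[1] - ms[2]) / (ms[1] + (30 - 1) * ms[2]))
  expect_lt(icc, 0.02)
  expect_equal(stats::sd(y), sqrt(0.02), tolerance = 0.1)
})

test_that("slope inflation scales the random-effect covariance as documented", {
  base <- scenario_config("random_slope", seed = 1)
  inflated <- scenario_config("random_slope", slope_inflation = 5, seed = 1)
  expect_equal(inflated$truth$sigma_u11, 5 * base$truth$sigma_u11)
  expect_equal(inflated$truth$sigma_u01, sqrt(5) * base$truth$sigma_u01)
  ou <- matrix(c(inflated$truth$sigma_u00, inflated$truth$sigma_u01,
                 inflated$truth$sigma_u01, inflated$truth$sigma_u11), 2)
  expect_true(is_pd(ou))
})

test_that("the MAR mechanism calibrates to the target incomplete fraction", {
  cfg <- scenario_config("random_intercept", n_clusters = 50,
                         cluster_size = 40, seed = 73)
  gen <- generate_scenario(cfg, 1)
  # gamma1 = 0 is MCAR at the calibrated rate
  set.seed(74)
  mc <- apply_mar(gen$dataset, target = 0.30, gamma1 = 0)
  frac <- missingness_summary(mc)$incomplete_rows
  expect_lt(abs(frac - 0.30), 3 * sqrt(0.3 * 0.7 / 2000) + 0.005)
  # outcome-dependent missingness concentrates in high-outcome rows
  set.seed(75)
  mar <- apply_mar(gen$dataset, target = 0.30, gamma1 = 2)
  inc <- rowSums(!mar$mask[, c("PAR", "age")]) > 0
  y <- gen$dataset$data[, "y"]
  expect_gt(mean(y[inc]), mean(y[!inc]))
  # expected fraction still calibrated under strong dependence
  expect_lt(abs(mean(inc) - 0.30), 0.05)
})

test_that("systematic missingness masks whole clusters at the stated count", {
  cfg <- scenario_config("level2_variable", n_clusters = 20,
                         cluster_size = 10, seed = 77)
  gen <- generate_scenario(cfg, 1)
  set.seed(78)
  ds <- apply_mar(gen$dataset, target = 0, gamma1 = 1,
                  vars = c("PAR", "exper"), systematic_fraction = 0.2)
  masked_by_cluster <- tapply(!ds$mask[, "exper"], ds$cluster, all)
  expect_equal(sum(masked_by_cluster), 4)
  # masked clusters lose the level-1 target too
  par_masked <- tapply(!ds$mask[, "PAR"], ds$cluster, all)
  expect_equal(sum(par_masked), 4)
})

test_that("performance measures and their Monte-Carlo errors are exact", {
  pm0 <- performance_measures(rep(2, 10), rep(0.1, 10), rep(1.8, 10),
                              rep(2.2, 10), truth = 2)
  expect_equal(pm0$bias, 0)
  expect_equal(pm0$emp_se, 0)
  expect_equal(pm0$coverage_pct, 100)
  pm1 <- performance_measures(c(1, 3), truth = 2)
  expect_equal(pm1$bias, 0)
  expect_equal(pm1$emp_se, sqrt(2))
  # Morris coverage MC error: 95% at 1000 replicates ~ 0.689 pp
  est <- c(rep(0, 950), rep(10, 50))
  pmc <- performance_measures(est, ses = rep(1, 1000),
                              ci_low = est - 1.96, ci_high = est + 1.96,
                              truth = 0)
  expect_equal(pmc$coverage_pct, 95)
  expect_equal(pmc$coverage_mce, sqrt(95 * 5 / 1000), tolerance = 1e-8)
  # zero truth: relative bias flagged undefined, absolute bias reported
  pmz <- performance_measures(c(0.1, -0.1, 0.2), truth = 0)
  expect_true(is.na(pmz$rel_bias_pct))
  expect_false(is.na(pmz$bias))
})

test_that("zipper data ranks replicates and flags coverage stably", {
  cfg <- scenario_config("random_intercept", n_clusters = 15,
                         cluster_size = 10, n_reps = 6, seed = 79)
  rep1 <- run_study(cfg, methods = "full_data")
  zd <- zipper_data(rep1, "full_data", "PAR")
  expect_equal(nrow(zd), 6)
  expect_true(all(zd$covered == (zd$ci_low <= 0.497 & 0.497 <= zd$ci_high)))
  # most extreme replicate first
  z <- abs(zd$estimate - 0.497) / (zd$ci_high - zd$ci_low)
  expect_equal(order(z, decreasing = TRUE), seq_len(6))
  # flags do not depend on replicate order
  shuf <- rep1
  shuf$replicates <- shuf$replicates[sample(nrow(shuf$replicates)), ]
  zd2 <- zipper_data(shuf, "full_data", "PAR")
  expect_equal(zd2[order(zd2$rep), "covered"], zd[order(zd$rep), "covered"])
})

test_that("a study is bit-reproducible from its configuration and seed", {
  cfg <- scenario_config("random_intercept", n_clusters = 12,
                         cluster_size = 10, n_reps = 2, n_burn = 30,
                         n_between = 15, M = 2, seed = 81)
  r1 <- run_study(cfg, methods = c("full_data", "jm_hom", "smc_jm"))
  r2 <- run_study(cfg, methods = c("full_data", "jm_hom", "smc_jm"))
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$replicates, r2$replicates)
  expect_null(r1$failures)
})

test_that("alternative covariate mechanisms feed the same analysis pipeline", {
  for (s in c("alt_dgm_1", "alt_dgm_2")) {
    cfg <- scenario_config(s, n_clusters = 40, cluster_size = 30, seed = 83)
    gen <- generate_scenario(cfg, 1)
    expect_true(all(gen$dataset$data[, "PAR"] %in% c(0, 1)))
    fit <- fit_mixed(gen$dataset, gen$spec)
    expect_lt(abs(fit$estimates["PAR"] - 0.497), 5 * fit$se["PAR"])
  }
  # the auxiliary variable is carried in the data but stays out of the spec
  cfga <- scenario_config("auxiliary", n_clusters = 10, cluster_size = 8,
                          seed = 84)
  gena <- generate_scenario(cfga, 1)
  expect_true("aux" %in% gena$dataset$meta$name)
  expect_false("aux" %in% spec_covariates(gena$spec))
})
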