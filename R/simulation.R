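#' Configure a simulation scenario
#'
#' Each scenario bundles a data-generating mechanism (clustered covariates,
#' a mixed-model outcome at the scenario's true parameter values, and a
#' missing-at-random mechanism conditional on the fully observed outcome),
#' the substantive model to be fitted, and the study dimensions. Defaults
#' are the package's base-case study conditions; see the methods vignette
#' for how each value was chosen.
#'
#' @param scenario One of `"random_intercept"`, `"random_slope"`,
#'   `"polynomial"`, `"interaction"`, `"level2_variable"`,
#'   `"level2_interaction"`, `"auxiliary"`, `"binary_outcome"`,
#'   `"ordinal_outcome"`, `"alt_dgm_1"`, `"alt_dgm_2"`, `"sensitivity"`.
#' @param n_clusters,cluster_size Study dimensions (level-2 units and mean
#'   rows per unit).
#' @param cluster_size_dispersion Coefficient of variation of cluster
#'   sizes; 0 gives equal clusters.
#' @param slope_inflation Multiplies the random-slope variance by this
#'   factor and the intercept-slope covariance by its square root
#'   (correlation-preserving, keeping the covariance positive definite).
#' @param effect_inflation Multiplies the polynomial / interaction /
#'   level-2 effect in the scenarios that have one.
#' @param systematically_missing_fraction Fraction of clusters whose target
#'   covariates are masked entirely.
#' @param mar_target Incomplete-case fraction the MAR mechanism is
#'   calibrated to.
#' @param mar_gamma1 Slope of the missingness logit on the standardised
#'   outcome (0 gives MCAR).
#' @param auxiliary_mechanism For the auxiliary scenario: `"covariate"`
#'   generates the auxiliary from a general-location model given the binary
#'   covariate; `"outcome"` generates it as a noisy function of the
#'   outcome.
#' @param covariate_dgm Override of the covariate mechanism (set
#'   automatically for the `alt_dgm_*` scenarios).
#' @param truth Optional named overrides of the true parameter values.
#' @param n_reps,M Number of simulation replicates and imputations.
#' @param n_burn,n_between MCMC chain lengths used inside each replicate.
#' @param seed Master seed; replicate r uses a derived child seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario,
                            n_clusters = 50, cluster_size = 40,
                            cluster_size_dispersion = 0,
                            slope_inflation = 1, effect_inflation = 1,
                            systematically_missing_fraction = 0,
                            mar_target = 0.30, mar_gamma1 = 1.0,
                            auxiliary_mechanism = c("covariate", "outcome"),
                            covariate_dgm = NULL,
                            truth = NULL,
                            n_reps = 200, M = 5,
                            n_burn = 200, n_between = 100,
                            seed = 1) {
  scenario <- match.arg(scenario, c(
    "random_intercept", "random_slope", "polynomial", "interaction",
    "level2_variable", "level2_interaction", "auxiliary", "binary_outcome",
    "ordinal_outcome", "alt_dgm_1", "alt_dgm_2", "sensitivity"))
  auxiliary_mechanism <- match.arg(auxiliary_mechanism)
  stopifnot(n_clusters >= 2, cluster_size >= 2, n_reps >= 1, M >= 2,
            slope_inflation > 0, mar_target >= 0, mar_target < 1)
  def <- scenario_defaults(scenario, effect_inflation)
  if (!is.null(truth)) for (nm in names(truth)) def$truth[[nm]] <- truth[[nm]]
  if (is.null(covariate_dgm)) covariate_dgm <- def$covariate_dgm
  # correlation-preserving random-slope inflation
  if (!is.null(def$truth$sigma_u11) && slope_inflation != 1) {
    def$truth$sigma_u11 <- def$truth$sigma_u11 * slope_inflation
    def$truth$sigma_u01 <- def$truth$sigma_u01 * sqrt(slope_inflation)
    ou <- matrix(c(def$truth$sigma_u00, def$truth$sigma_u01,
                   def$truth$sigma_u01, def$truth$sigma_u11), 2)
    if (min(eigen(ou, only.values = TRUE)$values) <= 0)
      stop("inflated random-effect covariance is not positive definite",
           call. = FALSE)
  }
  structure(list(scenario = scenario, n_clusters = as.integer(n_clusters),
                 cluster_size = cluster_size,
                 cluster_size_dispersion = cluster_size_dispersion,
                 slope_inflation = slope_inflation,
                 effect_inflation = effect_inflation,
                 systematically_missing_fraction = systematically_missing_fraction,
                 mar_target = mar_target, mar_gamma1 = mar_gamma1,
                 auxiliary_mechanism = auxiliary_mechanism,
                 covariate_dgm = covariate_dgm,
                 spec = def$spec, truth = def$truth,
                 mar_vars = def$mar_vars,
                 n_reps = as.integer(n_reps), M = as.integer(M),
                 n_burn = as.integer(n_burn), n_between = as.integer(n_between),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# true parameter values of the two base-case scenarios, and the package's
# stand-ins for the scenarios whose generating values are not tabulated
scenario_defaults <- function(scenario, effect_inflation = 1) {
  ri_truth <- list(beta = c("(Intercept)" = 0.313, PAR = 0.497, age = -0.005),
                   sigma_u00 = 0.010, sigma_e2 = 0.02)
  rs_truth <- list(beta = c("(Intercept)" = 0.297, PAR = 0.511, age = -0.004),
                   sigma_u00 = 0.015, sigma_u01 = -0.011, sigma_u11 = 0.021,
                   sigma_e2 = 0.02)
  ri_spec <- substantive_model_spec("y", c("PAR", "age"))
  switch(scenario,
    random_intercept = list(spec = ri_spec, truth = ri_truth,
                            covariate_dgm = "joint", mar_vars = c("PAR", "age")),
    alt_dgm_1 = list(spec = ri_spec, truth = ri_truth,
                     covariate_dgm = "alt1", mar_vars = c("PAR", "age")),
    alt_dgm_2 = list(spec = ri_spec, truth = ri_truth,
                     covariate_dgm = "alt2", mar_vars = c("PAR", "age")),
    auxiliary = list(spec = ri_spec, truth = ri_truth,
                     covariate_dgm = "joint", mar_vars = c("PAR", "age")),
    random_slope = ,
    sensitivity = list(
      spec = substantive_model_spec("y", c("PAR", "age"),
                                    random = list(intercept = TRUE, slopes = "PAR")),
      truth = rs_truth, covariate_dgm = "joint", mar_vars = c("PAR", "age")),
    polynomial = list(
      spec = substantive_model_spec("y", c("PAR", "age", "age^2")),
      truth = within_list(ri_truth, beta = c(ri_truth$beta,
                                             "age^2" = 0.05 * effect_inflation)),
      covariate_dgm = "joint", mar_vars = c("PAR", "age")),
    interaction = list(
      spec = substantive_model_spec("y", c("PAR", "age", "PAR:age")),
      truth = within_list(ri_truth, beta = c(ri_truth$beta,
                                             "PAR:age" = 0.05 * effect_inflation)),
      covariate_dgm = "joint", mar_vars = c("PAR", "age")),
    level2_variable = list(
      spec = substantive_model_spec("y", c("PAR", "exper")),
      truth = list(beta = c("(Intercept)" = 0.313, PAR = 0.497,
                            exper = 0.02 * effect_inflation),
                   sigma_u00 = 0.010, sigma_e2 = 0.02),
      covariate_dgm = "joint", mar_vars = c("PAR", "exper")),
    level2_interaction = list(
      spec = substantive_model_spec("y", c("PAR", "CME", "PAR:CME")),
      truth = list(beta = c("(Intercept)" = 0.313, PAR = 0.45, CME = -0.05,
                            "PAR:CME" = 0.10 * effect_inflation),
                   sigma_u00 = 0.010, sigma_e2 = 0.02),
      covariate_dgm = "joint", mar_vars = c("PAR", "CME")),
    binary_outcome = list(
      spec = substantive_model_spec("PAR", c("gender", "age"),
                                    family = "binomial_logit"),
      truth = list(beta = c("(Intercept)" = 0.85, gender = 0.3, age = 0.3),
                   sigma_u00 = 0.15),
      covariate_dgm = "joint", mar_vars = c("gender", "age")),
    ordinal_outcome = list(
      spec = substantive_model_spec("compl4", c("PAR", "age"),
                                    family = "ordinal_cumulative_logit"),
      truth = list(beta = c(PAR = 1.0, age = -0.1), sigma_u00 = 0.3,
                   cutpoints = c(-0.5, 0.5, 1.5)),
      covariate_dgm = "joint", mar_vars = c("PAR", "age")))
}

within_list <- function(x, ...) {
  mods <- list(...)
  for (nm in names(mods)) x[[nm]] <- mods[[nm]]
  x
}

# matrix square root tolerating positive semi-definite inputs (zero
# random-effect variances are legitimate degenerate study conditions)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 30269) %% 2147483399) + 1L
}

# clustered covariate draws: multilevel latent-normal joint mechanism, or
# the two alternative mechanisms used for sensitivity to the covariate model
gen_covariates <- function(cfg, sizes) {
  J <- length(sizes)
  n <- sum(sizes)
  clus <- rep(seq_len(J), sizes)
  dgm <- cfg$covariate_dgm
  out <- list(clus = clus)
  rho <- 0.3
  if (dgm == "alt1") {
    PAR <- stats::rbinom(n, 1, 0.7)
    uj <- stats::rnorm(J, 0, sqrt(0.10))
    age <- 0.3 * (PAR - 0.7) + uj[clus] + stats::rnorm(n, 0, sqrt(0.90))
    out$PAR <- PAR; out$age <- age
    return(out)
  }
  if (dgm == "alt2") {
    uj <- stats::rnorm(J, 0, sqrt(0.10))
    age <- uj[clus] + stats::rnorm(n, 0, sqrt(0.90))
    eta <- 0.85 + 0.3 * age - 0.2 * age^2
    out$PAR <- stats::rbinom(n, 1, stats::plogis(eta))
    out$age <- age
    return(out)
  }
  # joint latent-normal mechanism
  covs <- switch(cfg$scenario,
                 level2_variable = c("PAR", "exper"),
                 level2_interaction = c("PAR", "CME"),
                 binary_outcome = c("gender", "age"),
                 c("PAR", "age"))
  desc <- list(
    PAR = list(level = 1, bin = TRUE, alpha = stats::qnorm(0.7),
               u_var = 0.15, e_var = 1.0),
    gender = list(level = 1, bin = TRUE, alpha = 0, u_var = 0.15, e_var = 1.0),
    age = list(level = 1, bin = FALSE, alpha = 0, u_var = 0.10, e_var = 0.90),
    exper = list(level = 2, bin = FALSE, alpha = 0, u_var = 0.50, e_var = 0),
    CME = list(level = 2, bin = TRUE, alpha = stats::qnorm(0.4),
               u_var = 1.0, e_var = 0))[covs]
  pc <- length(desc)
  uv <- vapply(desc, function(d) d$u_var, numeric(1))
  Om2 <- diag(uv)
  for (i in seq_len(pc)) for (j in seq_len(pc))
    if (i != j) Om2[i, j] <- rho * sqrt(uv[i] * uv[j])
  U <- matrix(stats::rnorm(J * pc), J) %*% chol(Om2)
  lev1 <- which(vapply(desc, function(d) d$level == 1, logical(1)))
  ev <- vapply(desc[lev1], function(d) d$e_var, numeric(1))
  Om1 <- diag(ev, length(lev1))
  if (length(lev1) > 1)
    for (i in seq_along(lev1)) for (j in seq_along(lev1))
      if (i != j) Om1[i, j] <- rho * sqrt(ev[i] * ev[j])
  E <- matrix(stats::rnorm(n * length(lev1)), n) %*% chol(Om1)
  for (idx in seq_len(pc)) {
    d <- desc[[idx]]
    nm <- names(desc)[idx]
    if (d$level == 1) {
      z <- d$alpha + U[clus, idx] + E[, match(idx, lev1)]
      out[[nm]] <- if (d$bin) as.numeric(z >= 0) else z
    } else {
      z <- d$alpha + U[, idx]
      val <- if (d$bin) as.numeric(z >= 0) else z
      out[[nm]] <- val[clus]
    }
  }
  out
}

#' Generate one fully observed scenario replicate
#'
#' Draws cluster sizes, clustered covariates from the configured mechanism,
#' and the outcome from the scenario's substantive model at the true
#' parameter values. The auxiliary scenario adds one auxiliary variable
#' under the configured mechanism.
#'
#' @param cfg A [scenario_config()].
#' @param rep Replicate index (drives the derived child seed).
#' @return List with `dataset` (fully observed [multilevel_dataset()]),
#'   `spec` and `truth` (named vector over fixed effects and variance
#'   components).
#' @export
generate_scenario <- function(cfg, rep = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(child_seed(cfg$seed, rep))
  J <- cfg$n_clusters
  sizes <- if (cfg$cluster_size_dispersion > 0) {
    pmax(2L, as.integer(round(stats::rnorm(
      J, cfg$cluster_size, cfg$cluster_size_dispersion * cfg$cluster_size))))
  } else rep(as.integer(cfg$cluster_size), J)
  cv <- gen_covariates(cfg, sizes)
  clus <- cv$clus
  n <- length(clus)
  spec <- cfg$spec
  truth <- cfg$truth
  covdf <- as.data.frame(cv[setdiff(names(cv), "clus")])

  # outcome from the substantive model at truth
  r <- 1L + length(spec$random$slopes)
  if (r == 1L) {
    omu <- matrix(truth$sigma_u00, 1, 1)
  } else {
    omu <- matrix(c(truth$sigma_u00, truth$sigma_u01,
                    truth$sigma_u01, truth$sigma_u11), 2)
  }
  Usub <- matrix(stats::rnorm(J * r), J) %*% psd_sqrt(omu)
  X <- design_matrix(spec, covdf)
  Zr <- rand_design(spec, covdf)
  eta <- drop(X %*% truth$beta) + rowSums(Zr * Usub[clus, , drop = FALSE])
  yname <- spec$outcome
  if (spec$family == "gaussian_identity") {
    covdf[[yname]] <- eta + stats::rnorm(n, 0, sqrt(truth$sigma_e2))
  } else if (spec$family == "binomial_logit") {
    covdf[[yname]] <- stats::rbinom(n, 1, stats::plogis(eta))
  } else {
    K <- length(truth$cutpoints) + 1L
    cum <- vapply(truth$cutpoints, function(ck) stats::plogis(ck - eta),
                  numeric(n))
    u <- stats::runif(n)
    covdf[[yname]] <- 1L + rowSums(u > cum)
  }

  meta <- variable_meta(".cluster", 2, "continuous", "cluster_id")
  yv <- if (spec$family == "binomial_logit") "binary" else "continuous"
  meta <- rbind(meta, variable_meta(yname, 1, yv, "outcome"))
  covmeta <- list(PAR = c(1, "binary"), gender = c(1, "binary"),
                  age = c(1, "continuous"), exper = c(2, "continuous"),
                  CME = c(2, "binary"))
  for (v in setdiff(names(covdf), yname))
    meta <- rbind(meta, variable_meta(v, as.integer(covmeta[[v]][1]),
                                      covmeta[[v]][2], "covariate"))
  if (cfg$scenario == "auxiliary") {
    covdf$aux <- if (cfg$auxiliary_mechanism == "covariate") {
      2 * covdf$PAR + stats::rnorm(n, 0, 0.5)   # general-location style
    } else {
      2 * covdf[[yname]] + stats::rnorm(n, 0, 0.2)
    }
    meta <- rbind(meta, variable_meta("aux", 1, "continuous", "auxiliary"))
  }
  covdf$.cluster <- clus
  ds <- multilevel_dataset(covdf, meta)

  tr <- truth$beta
  tr["sigma_u00"] <- truth$sigma_u00
  if (!is.null(truth$sigma_u11)) {
    tr["sigma_u01"] <- truth$sigma_u01
    tr["sigma_u11"] <- truth$sigma_u11
  }
  list(dataset = ds, spec = spec, truth = tr)
}

#' Impose a missing-at-random mechanism conditional on the outcome
#'
#' Each target covariate is masked with probability
#' `plogis(gamma0 + gamma1 * standardised outcome)` — per row for level-1
#' variables, per cluster (using the cluster-mean standardised outcome) for
#' level-2 variables. `gamma0` is calibrated by root-finding so the
#' expected incomplete-case fraction hits the target. With
#' `systematically_missing_fraction > 0`, a rounded fraction of clusters
#' additionally has the target covariates masked entirely.
#'
#' @param ds A fully observed [multilevel_dataset()] (outcome observed).
#' @param target Desired incomplete-case fraction.
#' @param gamma1 Dependence of missingness on the standardised outcome.
#' @param vars Target covariates (default: all covariate-role variables).
#' @param systematic_fraction Fraction of clusters masked entirely.
#' @param outcome Outcome variable name (default: the role-outcome column).
#' @return The dataset with an updated mask; attribute `"gamma0"` records
#'   the calibrated intercept.
#' @export
apply_mar <- function(ds, target = 0.30, gamma1 = 1.0, vars = NULL,
                      systematic_fraction = 0, outcome = NULL) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  meta <- ds$meta
  if (is.null(outcome)) outcome <- meta$name[meta$role == "outcome"]
  if (any(!ds$mask[, outcome]))
    stop("the MAR mechanism conditions on a fully observed outcome",
         call. = FALSE)
  if (is.null(vars)) vars <- meta$name[meta$role == "covariate"]
  y <- ds$data[, outcome]
  ystd <- (y - mean(y)) / stats::sd(y)
  clus <- ds$cluster
  J <- n_clusters(ds)
  ybar <- tapply(ystd, clus, mean)
  lev <- meta$level[match(vars, meta$name)]

  expected_incomplete <- function(g0) {
    p_keep <- rep(1, length(y))
    for (t in seq_along(vars)) {
      if (lev[t] == 1L) {
        p_keep <- p_keep * (1 - stats::plogis(g0 + gamma1 * ystd))
      } else {
        p_keep <- p_keep * (1 - stats::plogis(g0 + gamma1 * ybar))[clus]
      }
    }
    mean(1 - p_keep)
  }
  if (target > 0) {
    root <- try(stats::uniroot(function(g) expected_incomplete(g) - target,
                               c(-20, 10), tol = 1e-8), silent = TRUE)
    if (inherits(root, "try-error"))
      stop("MAR calibration failed: target incomplete fraction unreachable",
           call. = FALSE)
    g0 <- root$root
    mask <- ds$mask
    for (t in seq_along(vars)) {
      v <- vars[t]
      if (lev[t] == 1L) {
        hit <- stats::runif(length(y)) < stats::plogis(g0 + gamma1 * ystd)
        mask[hit, v] <- FALSE
      } else {
        hitj <- stats::runif(J) < stats::plogis(g0 + gamma1 * ybar)
        mask[hitj[clus], v] <- FALSE
      }
    }
  } else {
    g0 <- -Inf
    mask <- ds$mask
  }
  if (systematic_fraction > 0) {
    nsys <- round(systematic_fraction * J)
    sysj <- sample.int(J, nsys)
    mask[clus %in% sysj, vars] <- FALSE
  }
  out <- ds
  out$mask <- mask
  out$data[!mask] <- NA
  attr(out, "gamma0") <- g0
  validate_dataset(out)
  out
}

# subset rows of a dataset (used for complete-records analyses)
ds_subset_rows <- function(ds, rows) {
  df <- as.data.frame(ds)[rows, , drop = FALSE]
  meta <- rbind(variable_meta(ds$cluster_var, 2, "continuous", "cluster_id"),
                ds$meta)
  multilevel_dataset(df, meta)
}
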