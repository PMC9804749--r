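#' Substantive-model log-likelihood, conditional on the random effects
#'
#' Evaluates the outcome factor of the factorised joint model: the normal
#' log-density (gaussian family), Bernoulli-logit log-mass, or
#' cumulative-logit log-mass of the outcome given the expanded fixed-effect
#' design and the current cluster random effects. No integration over the
#' random effects is performed.
#'
#' @param spec A [substantive_model_spec()].
#' @param params List with `beta`, `omega_u`, `sigma2_e` (gaussian),
#'   `cutpoints` (ordinal) and optionally `u_sub`.
#' @param y Outcome value(s).
#' @param rows Design row (vector) or matrix from [design_row()].
#' @param u Random-effect value(s) for the rows' cluster: vector of length
#'   `r`, or matrix with one row per observation. `NULL` means zero.
#' @param rdesign Random-effect design (1 and the slope covariates); `NULL`
#'   means intercept-only.
#' @return Sum of per-row log-likelihood contributions.
#' @export
loglik_substantive <- function(spec, params, y, rows, u = NULL, rdesign = NULL) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  eta <- drop(rows %*% params$beta)
  if (!is.null(u)) {
    if (is.null(rdesign)) rdesign <- matrix(1, nrow(rows), 1)
    if (is.null(dim(u))) u <- matrix(u, nrow(rows), length(u), byrow = TRUE)
    eta <- eta + rowSums(rdesign * u)
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  switch(spec$family,
    gaussian_identity = sum(stats::dnorm(y, eta, sqrt(params$sigma2_e), log = TRUE)),
    binomial_logit = sum(y * eta - log1p(exp(eta))),
    ordinal_cumulative_logit = {
      K <- length(params$cutpoints) + 1L
      up <- ifelse(y < K, stats::plogis(params$cutpoints[pmin(y, K - 1)] - eta), 1)
      lo <- ifelse(y > 1, stats::plogis(params$cutpoints[pmax(y - 1, 1)] - eta), 0)
      sum(log(pmax(up - lo, 1e-300)))
    })
}

# initial substantive parameters from the initialised completed data
init_substantive <- function(spec, values, yout, J) {
  X <- design_matrix(spec, values)
  r <- 1L + length(spec$random$slopes)
  params <- list(u_sub = matrix(0, J, r), omega_u = diag(1e-2, r),
                 sigma2_e = 1, cutpoints = NULL)
  if (spec$family == "gaussian_identity") {
    XtX <- crossprod(X)
    beta <- drop(solve(XtX + diag(1e-8, ncol(X)), crossprod(X, yout)))
    res <- yout - drop(X %*% beta)
    params$beta <- beta
    params$sigma2_e <- max(stats::var(res), 1e-6)
    params$omega_u <- diag(max(0.2 * params$sigma2_e, 1e-4), r)
  } else if (spec$family == "binomial_logit") {
    beta <- rep(0, ncol(X))
    beta[1] <- stats::qlogis(min(max(mean(yout), 0.02), 0.98))
    params$beta <- beta
    params$omega_u <- diag(0.1, r)
  } else {
    params$beta <- rep(0, ncol(X))
    K <- max(yout)
    cum <- cumsum(tabulate(yout, K))[-K] / length(yout)
    params$cutpoints <- stats::qlogis(pmin(pmax(cum, 0.02), 0.98))
    params$omega_u <- diag(0.1, r)
  }
  params
}

family_code <- function(family) {
  match(family, c("gaussian_identity", "binomial_logit",
                  "ordinal_cumulative_logit")) - 1L
}

# encode fixed terms / random design against the covariate matrix columns
encode_terms <- function(spec, variables) {
  enc <- t(vapply(spec$terms, function(t) {
    v1 <- match(t$v1, variables) - 1L
    v2 <- if (is.na(t$v2)) -1L else match(t$v2, variables) - 1L
    c(v1, t$p1, v2, t$p2)
  }, integer(4)))
  if (spec$family != "ordinal_cumulative_logit")
    enc <- rbind(c(-1L, 0L, -1L, 0L), enc)
  storage.mode(enc) <- "integer"
  enc
}

encode_rcols <- function(spec, variables) {
  as.integer(c(-1L, match(spec$random$slopes, variables) - 1L))
}

#' Impute compatibly with the substantive model (SMC-JM)
#'
#' The joint model is factorised into a latent-normal joint model for the
#' covariates (and auxiliaries) times the substantive model for the outcome.
#' Each MCMC sweep runs the covariate-model Gibbs updates with every
#' missing-cell draw routed through a Metropolis-Hastings step: the proposal
#' is the covariate-model conditional, so the acceptance ratio reduces to
#' the substantive-likelihood ratio — a single row's contribution for
#' level-1 cells, the cluster's summed contributions for level-2 cells.
#' Substantive parameters are then updated by one Bayesian sweep on the
#' current completed data.
#'
#' @param ds A [multilevel_dataset()]; the outcome must be observed
#'   wherever it enters the substantive likelihood.
#' @param spec A [substantive_model_spec()]; auxiliary variables take part
#'   in the covariate joint model but never in the spec.
#' @param config An [mcmc_config()].
#' @param covariate_model `"homoscedastic"` (default) or
#'   `"heteroscedastic"` covariate joint model.
#' @param variables Covariate-model variables (default: all non-cluster,
#'   non-outcome columns).
#' @param control Diagnostic switches: `freeze_covariate_params` /
#'   `freeze_substantive_params` hold the respective parameter blocks at
#'   their initial values (used to study the imputation kernel at frozen
#'   parameters), `init_covariate` / `init_substantive` override the
#'   initial state, `record_cells` stores the imputed value of every
#'   missing cell at every iteration.
#' @return An `imputation_result` with the additional element
#'   `substantive` (final substantive-parameter state) and chains for both
#'   model blocks.
#' @export
impute_smc_jm <- function(ds, spec, config = mcmc_config(),
                          covariate_model = c("homoscedastic", "heteroscedastic"),
                          variables = NULL, control = list()) {
  stopifnot(inherits(ds, "multilevel_dataset"),
            inherits(spec, "substantive_model_spec"),
            inherits(config, "mcmc_config"))
  covariate_model <- match.arg(covariate_model)
  validate_spec(spec, ds)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(variables))
    variables <- setdiff(ds$meta$name, spec$outcome)
  if (spec$outcome %in% variables)
    stop("the outcome cannot be a covariate-model variable under SMC-JM",
         call. = FALSE)
  if (!all(spec_covariates(spec) %in% variables))
    stop("covariate-model variables must include every covariate in the spec",
         call. = FALSE)
  if (any(!ds$mask[, spec$outcome]))
    stop("SMC-JM requires the outcome observed wherever it is modelled",
         call. = FALSE)

  inp <- jm_inputs(ds, variables)
  state <- control$init_covariate
  if (is.null(state)) state <- jm_state_init_impl(inp, ds)
  yout <- ds$data[, spec$outcome]
  sub <- control$init_substantive
  if (is.null(sub)) sub <- init_substantive(spec, state$values, yout, inp$J)

  het <- covariate_model == "heteroscedastic"
  M <- config$n_imputations
  reg <- config$n_burn + (seq_len(M) - 1L) * config$n_between
  res <- cpp_smc_mcmc(state$values, matrix(as.integer(inp$obs), nrow(inp$obs)),
                      inp$isbin, inp$lev2, inp$clus0, inp$J,
                      yout = yout, family = family_code(spec$family),
                      terms = encode_terms(spec, variables),
                      rcols = encode_rcols(spec, variables),
                      n_cat = if (spec$family == "ordinal_cumulative_logit")
                        as.integer(max(yout)) else 2L,
                      n_iter = max(reg), register_iters = as.integer(reg),
                      mh_step = config$mh_step_scale, mh_inner = config$mh_inner,
                      het = het, iw_a = if (het) sum(inp$lev2 == 0L) + 3 else 0,
                      init_cov = state, init_sub = sub,
                      freeze_cov = isTRUE(control$freeze_covariate_params),
                      freeze_sub = isTRUE(control$freeze_substantive_params),
                      record_cells = isTRUE(control$record_cells))
  r <- 1L + length(spec$random$slopes)
  sub_names <- c(paste0("beta[", param_labels(spec), "]"),
                 tri_names("omega_u", c("(Intercept)", spec$random$slopes)))
  if (spec$family == "gaussian_identity") sub_names <- c(sub_names, "sigma2_e")
  if (spec$family == "ordinal_cumulative_logit")
    sub_names <- c(sub_names, paste0("cutpoint[", seq_len(max(yout) - 1), "]"))
  build_imputation_result(
    res, ds, inp, config, method = "smc_jm",
    chain_names = c(jm_chain_names(inp, het = FALSE), sub_names),
    extra = list(substantive = res$substantive, spec = spec,
                 accept_cell = res$accept_cell))
}

#' Initialise an SMC-JM state for step-wise inspection
#'
#' Exposes the two blocks of the factorised model — the covariate
#' joint-model state and the substantive parameters — for use with
#' [propose_covariate()], [mh_accept_covariate()] and
#' [update_substantive_params()].
#'
#' @inheritParams impute_smc_jm
#' @param seed Optional seed.
#' @return List with elements `covariate` and `substantive`.
#' @export
smc_state_init <- function(ds, spec, variables = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_spec(spec, ds)
  if (is.null(variables)) variables <- setdiff(ds$meta$name, spec$outcome)
  inp <- jm_inputs(ds, variables)
  cov <- jm_state_init_impl(inp, ds)
  sub <- init_substantive(spec, cov$values, ds$data[, spec$outcome], inp$J)
  list(covariate = cov, substantive = sub)
}

#' Propose an imputation from the covariate-model conditional
#'
#' Draws the target cell from the covariate joint model's conditional
#' distribution given the row's (or cluster's) other current values — the
#' latent-normal conditional for binary variables, the normal conditional
#' for continuous ones. Because the proposal is exactly the covariate-model
#' conditional, the proposal log-ratio required by the acceptance step is
#' the substantive-likelihood ratio alone; the returned `log_ratio` is the
#' residual correction, which is zero for this proposal.
#'
#' @param state An [smc_state_init()] state.
#' @param ds The dataset (the target cell must be masked).
#' @param variable Variable to propose for.
#' @param row Row index (level-1 variables).
#' @param cluster Cluster index (level-2 variables).
#' @return List with the proposed `value`, latent `z`, conditional `mean`
#'   and `sd`, and `log_ratio`.
#' @export
propose_covariate <- function(state, ds, variable, row = NULL, cluster = NULL) {
  cov <- state$covariate
  vars <- cov$variables
  k <- match(variable, vars)
  if (is.na(k)) stop("unknown variable '", variable, "'", call. = FALSE)
  meta <- ds$meta[match(vars, ds$meta$name), ]
  isbin <- meta$vtype[k] == "binary"
  if (meta$level[k] == 1L) {
    stopifnot(!is.null(row))
    if (ds$mask[row, variable]) stop("target cell is observed", call. = FALSE)
    i1 <- which(meta$level == 1L)
    a <- match(k, i1)
    j <- ds$cluster[row]
    e <- cov$z[row, i1] - cov$alpha[i1] - cov$u[j, i1]
    if (length(i1) > 1L) {
      Om <- cov$omega1
      b <- solve(Om[-a, -a, drop = FALSE], Om[-a, a])
      s2 <- Om[a, a] - sum(Om[-a, a] * b)
      mu <- cov$alpha[k] + cov$u[j, k] + sum(b * e[-a])
    } else {
      s2 <- cov$omega1[1, 1]
      mu <- cov$alpha[k] + cov$u[j, k]
    }
    z <- stats::rnorm(1, mu, sqrt(s2))
    list(variable = variable, row = row, cluster = NULL,
         value = if (isbin) as.numeric(z >= 0) else z, z = z,
         mean = mu, sd = sqrt(s2), log_ratio = 0)
  } else {
    stopifnot(!is.null(cluster))
    rows_j <- which(ds$cluster == cluster)
    if (any(ds$mask[rows_j, variable]))
      stop("target cells are observed", call. = FALSE)
    Om2 <- cov$omega2
    b <- solve(Om2[-k, -k, drop = FALSE], Om2[-k, k])
    s2 <- Om2[k, k] - sum(Om2[-k, k] * b)
    mu <- sum(b * cov$u[cluster, -k])
    u <- stats::rnorm(1, mu, sqrt(s2))
    z <- cov$alpha[k] + u
    list(variable = variable, row = NULL, cluster = cluster,
         value = if (isbin) as.numeric(z >= 0) else z, z = z, u = u,
         mean = mu, sd = sqrt(s2), log_ratio = 0)
  }
}

#' Metropolis-Hastings acceptance of a covariate imputation
#'
#' Accepts with probability `min(1, exp(delta))` where `delta` is the
#' substantive log-likelihood at the proposal minus at the current value,
#' plus the proposal log-ratio correction. For level-1 variables the single
#' row's contribution is used; for level-2 variables the contributions of
#' all rows of the cluster are summed, so the decision is invariant to
#' within-cluster row order. A proposal with `-Inf` substantive
#' log-likelihood is always rejected.
#'
#' @param state An [smc_state_init()] state.
#' @param ds The dataset.
#' @param spec The substantive model.
#' @param proposal A [propose_covariate()] result.
#' @return List with `accept`, `delta`, acceptance probability `prob` and
#'   the (possibly updated) `state`.
#' @export
mh_accept_covariate <- function(state, ds, spec, proposal) {
  cov <- state$covariate
  sub <- state$substantive
  vars <- cov$variables
  k <- match(proposal$variable, vars)
  yout <- ds$data[, spec$outcome]
  rows <- if (is.null(proposal$cluster)) proposal$row else
    which(ds$cluster == proposal$cluster)
  jj <- ds$cluster[rows]
  ll_at <- function(values) {
    X <- design_matrix(spec, values[rows, , drop = FALSE])
    Zr <- rand_design(spec, values[rows, , drop = FALSE])
    loglik_substantive(spec, sub, yout[rows], X,
                       u = sub$u_sub[jj, , drop = FALSE], rdesign = Zr)
  }
  vals_cur <- cov$values
  vals_prop <- vals_cur
  vals_prop[rows, k] <- proposal$value
  ll0 <- ll_at(vals_cur)
  ll1 <- ll_at(vals_prop)
  delta <- (ll1 - ll0) + proposal$log_ratio
  prob <- if (!is.finite(delta) && delta < 0) 0 else min(1, exp(delta))
  accept <- is.finite(ll1) && stats::runif(1) < prob
  if (accept) {
    cov$values[rows, k] <- proposal$value
    cov$z[rows, k] <- proposal$z
    if (!is.null(proposal$cluster)) cov$u[proposal$cluster, k] <- proposal$u
    state$covariate <- cov
  }
  list(accept = accept, delta = delta, prob = prob, state = state)
}

#' One Bayesian update sweep of the substantive parameters
#'
#' Gaussian family: conjugate draws for the fixed effects, per-cluster
#' random effects, random-effect covariance (inverse-Wishart) and residual
#' variance (inverse-gamma). Binomial and ordinal families: random-walk
#' Metropolis for the fixed effects and random effects, order-preserving
#' random-walk for the cutpoints, conjugate inverse-Wishart for the
#' random-effect covariance.
#'
#' @param state An [smc_state_init()] state whose covariate values are
#'   fully imputed.
#' @param ds The dataset.
#' @param spec The substantive model.
#' @return The state with updated `substantive` parameters.
#' @export
update_substantive_params <- function(state, ds, spec) {
  sub <- state$substantive
  values <- state$covariate$values
  yout <- ds$data[, spec$outcome]
  clus <- ds$cluster
  J <- n_clusters(ds)
  X <- design_matrix(spec, values)
  Zr <- rand_design(spec, values)
  r <- ncol(Zr)
  nu0 <- r + 2; S0 <- diag(0.01, r)
  if (spec$family == "gaussian_identity") {
    resid_u <- yout - rowSums(Zr * sub$u_sub[clus, , drop = FALSE])
    XtXi <- solve(crossprod(X))
    bhat <- drop(XtXi %*% crossprod(X, resid_u))
    sub$beta <- drop(rmvnorm_r(bhat, sub$sigma2_e * XtXi))
    fit <- drop(X %*% sub$beta)
    Omui <- solve(sub$omega_u)
    for (j in seq_len(J)) {
      idx <- which(clus == j)
      Zj <- Zr[idx, , drop = FALSE]
      prec <- crossprod(Zj) / sub$sigma2_e + Omui
      covm <- solve(prec)
      mean_j <- drop(covm %*% (crossprod(Zj, yout[idx] - fit[idx]) / sub$sigma2_e))
      sub$u_sub[j, ] <- rmvnorm_r(mean_j, covm)
    }
    sub$omega_u <- riwish_r(nu0 + J, S0 + crossprod(sub$u_sub))
    res <- yout - fit - rowSums(Zr * sub$u_sub[clus, , drop = FALSE])
    sub$sigma2_e <- 1 / stats::rgamma(1, 0.001 + length(yout) / 2,
                                      0.001 + sum(res^2) / 2)
  } else {
    ll_all <- function(s) {
      loglik_substantive(spec, s, yout, X, u = s$u_sub[clus, , drop = FALSE],
                         rdesign = Zr)
    }
    prop <- sub
    prop$beta <- sub$beta + 0.1 * stats::rnorm(length(sub$beta))
    if (log(stats::runif(1)) < ll_all(prop) - ll_all(sub)) sub <- prop
    Omui <- solve(sub$omega_u)
    for (j in seq_len(J)) {
      prop <- sub
      prop$u_sub[j, ] <- sub$u_sub[j, ] + 0.3 * stats::rnorm(r)
      d <- ll_all(prop) - ll_all(sub) -
        0.5 * (drop(prop$u_sub[j, ] %*% Omui %*% prop$u_sub[j, ]) -
               drop(sub$u_sub[j, ] %*% Omui %*% sub$u_sub[j, ]))
      if (log(stats::runif(1)) < d) sub <- prop
    }
    sub$omega_u <- riwish_r(nu0 + J, S0 + crossprod(sub$u_sub))
    if (spec$family == "ordinal_cumulative_logit") {
      K <- length(sub$cutpoints) + 1L
      for (k in seq_len(K - 1)) {
        cand <- sub$cutpoints
        cand[k] <- cand[k] + 0.1 * stats::rnorm(1)
        if (is.unsorted(cand, strictly = TRUE)) next
        prop <- sub; prop$cutpoints <- cand
        if (log(stats::runif(1)) < ll_all(prop) - ll_all(sub)) sub <- prop
      }
    }
  }
  state$substantive <- sub
  state
}

# small multivariate-normal and inverse-Wishart draws used by the R-level
# update sweep (the compiled samplers have their own)
rmvnorm_r <- function(mu, Sigma) {
  L <- chol((Sigma + t(Sigma)) / 2)
  mu + drop(t(L) %*% stats::rnorm(length(mu)))
}

riwish_r <- function(nu, S) {
  p <- nrow(S)
  Sinv <- solve((S + t(S)) / 2)
  L <- chol(Sinv)
  A <- matrix(0, p, p)
  diag(A) <- sqrt(stats::rchisq(p, nu - seq_len(p) + 1))
  A[upper.tri(A)] <- stats::rnorm(p * (p - 1) / 2)
  W <- crossprod(A %*% L)
  solve(W)
}
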