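#' MCMC configuration for the imputation samplers
#'
#' @param n_burn Iterations run before the first imputation is registered.
#' @param n_between Iterations between successive registered imputations,
#'   guaranteeing approximate stochastic independence of the M draws.
#' @param n_imputations Number of imputations M (at least 2).
#' @param seed Optional integer seed; all randomness in a run flows from it.
#' @param mh_step_scale Base scale of the random-walk Metropolis-Hastings
#'   proposals for constrained covariance matrices. The proposal standard
#'   deviation used is `mh_step_scale * 10 / sqrt(rows informing the update)`
#'   so the default behaves across sample sizes; there is no adaptive tuning.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 1000, n_between = 1000, n_imputations = 5,
                        seed = NULL, mh_step_scale = 0.1) {
  stopifnot(n_burn >= 1, n_between >= 1, n_imputations >= 2, mh_step_scale > 0)
  structure(list(n_burn = as.integer(n_burn), n_between = as.integer(n_between),
                 n_imputations = as.integer(n_imputations), seed = seed,
                 mh_step_scale = mh_step_scale, mh_inner = 5L),
            class = "mcmc_config")
}

#' Draw from a sign-constrained latent normal
#'
#' The latent-normal device for binary variables: a draw from
#' `N(mean, sd^2)` truncated to `(-Inf, 0)` when the observed value is 0 and
#' to `[0, Inf)` when it is 1.
#'
#' @param value 0/1 value(s) fixing the truncation side.
#' @param mean,sd Normal parameters (recycled); `sd` must be positive.
#' @return Numeric vector of truncated-normal draws.
#' @export
sample_latent <- function(value, mean = 0, sd = 1) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (!all(value %in% c(0, 1))) stop("value must be 0 or 1", call. = FALSE)
  n <- max(length(value), length(mean), length(sd))
  cpp_rtnorm(as.integer(rep_len(value, n)), rep_len(as.numeric(mean), n),
             rep_len(as.numeric(sd), n))
}

# assemble sampler inputs for a set of joint-model variables
jm_inputs <- function(ds, variables) {
  meta <- ds$meta
  if (is.null(variables)) variables <- meta$name
  miss <- setdiff(variables, meta$name)
  if (length(miss)) stop("unknown variables: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  m <- meta[match(variables, meta$name), , drop = FALSE]
  Y <- ds$data[, variables, drop = FALSE]
  obs <- ds$mask[, variables, drop = FALSE]
  for (v in variables) {
    x <- Y[, v][obs[, v]]
    if (length(x) == 0L)
      stop("variable '", v, "' is 100% missing: no information to impute from",
           call. = FALSE)
    if (m$vtype[m$name == v] == "binary" && length(unique(x)) < 2L)
      stop("binary variable '", v, "' is constant among observed values",
           call. = FALSE)
  }
  list(variables = variables, Y = Y, obs = obs,
       isbin = as.integer(m$vtype == "binary"),
       lev2 = as.integer(m$level == 2L),
       clus0 = ds$cluster - 1L, J = n_clusters(ds), meta = m)
}

#' Initialise the joint-model MCMC state
#'
#' Missing continuous cells start at the observed variable mean, missing
#' binary cells at a Bernoulli draw with the observed prevalence; random
#' effects start at zero; the level-1 covariance starts at the empirical
#' covariance of the initialised working values with latent-binary diagonals
#' renormalised to one.
#'
#' @param ds A [multilevel_dataset()].
#' @param variables Joint-model variables (default: all non-cluster columns).
#' @param seed Optional seed for the initial Bernoulli fills.
#' @return A state list (`alpha`, `u`, `omega1`, `omega2`, `z`, `values`,
#'   `variables`) accepted by [gibbs_sweep_hom()].
#' @export
jm_state_init <- function(ds, variables = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inp <- jm_inputs(ds, variables)
  jm_state_init_impl(inp, ds)
}

#' One Gibbs/MH sweep of the homoscedastic joint model
#'
#' Runs, in fixed order: latent refresh for observed binary cells; draws of
#' all missing cells from their conditional multivariate normal; cluster
#' random effects (conjugate normal); level-1 covariance (conjugate
#' inverse-Wishart, or Metropolis-Hastings when a latent-binary unit-diagonal
#' constraint is present); level-2 covariance; intercepts (flat prior,
#' conjugate normal).
#'
#' @param state State from [jm_state_init()] or a previous sweep.
#' @param ds The source dataset.
#' @param mh_step_scale See [mcmc_config()].
#' @return The updated state.
#' @export
gibbs_sweep_hom <- function(state, ds, mh_step_scale = 0.1) {
  inp <- jm_inputs(ds, state$variables)
  res <- cpp_jm_mcmc(state$values, matrix(as.integer(inp$obs), nrow(inp$obs)),
                     inp$isbin, inp$lev2, inp$clus0, inp$J,
                     n_iter = 1L, register_iters = integer(0),
                     mh_step = mh_step_scale, mh_inner = 5L,
                     het = FALSE, iw_a = 0, init = state, record_cells = FALSE)
  st <- res$state
  st$variables <- state$variables
  st
}

tri_names <- function(prefix, vars) {
  p <- length(vars)
  out <- character(0)
  for (i in seq_len(p)) for (j in seq_len(i))
    out <- c(out, paste0(prefix, "[", vars[i], ",", vars[j], "]"))
  out
}

jm_chain_names <- function(inp, het = FALSE) {
  vars <- inp$variables
  v1 <- vars[inp$lev2 == 0L]
  nm <- c(paste0("alpha[", vars, "]"), tri_names("omega1", v1),
          tri_names("omega2", vars))
  if (het) nm <- c(nm, tri_names("iw_scale", v1))
  nm
}

run_jm <- function(ds, config, variables, het, iw_df = NULL,
                   record_cells = FALSE) {
  stopifnot(inherits(ds, "multilevel_dataset"), inherits(config, "mcmc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  inp <- jm_inputs(ds, variables)
  state <- jm_state_init_impl(inp, ds)
  p1 <- sum(inp$lev2 == 0L)
  if (het) {
    if (inp$J < 5L)
      warning("fewer than 5 clusters: cluster-specific covariances are ",
              "poorly identified", call. = FALSE)
    if (any(tabulate(ds$cluster, inp$J) < 2L))
      warning("cluster of size < 2: its covariance shrinks to the ",
              "inverse-Wishart scale", call. = FALSE)
    if (is.null(iw_df)) iw_df <- p1 + 3
    if (iw_df <= p1 - 1) stop("iw_df must exceed p - 1", call. = FALSE)
  }
  M <- config$n_imputations
  reg <- config$n_burn + (seq_len(M) - 1L) * config$n_between
  res <- cpp_jm_mcmc(state$values, matrix(as.integer(inp$obs), nrow(inp$obs)),
                     inp$isbin, inp$lev2, inp$clus0, inp$J,
                     n_iter = max(reg), register_iters = as.integer(reg),
                     mh_step = config$mh_step_scale, mh_inner = config$mh_inner,
                     het = het, iw_a = if (het) iw_df else 0,
                     init = state, record_cells = record_cells)
  build_imputation_result(res, ds, inp, config,
                          method = if (het) "jm_het" else "jm_hom",
                          chain_names = jm_chain_names(inp, het))
}

jm_state_init_impl <- function(inp, ds) {
  Y <- inp$Y; obs <- inp$obs
  p <- ncol(Y)
  for (k in seq_len(p)) {
    xobs <- Y[, k][obs[, k]]
    if (inp$isbin[k] == 1L) {
      Y[, k][!obs[, k]] <- stats::rbinom(sum(!obs[, k]), 1, mean(xobs))
    } else {
      Y[, k][!obs[, k]] <- mean(xobs)
    }
  }
  Z <- Y
  alpha <- colMeans(Y)
  for (k in which(inp$isbin == 1L)) {
    alpha[k] <- stats::qnorm(min(max(mean(Y[, k]), 0.02), 0.98))
    Z[, k] <- ifelse(Y[, k] >= 0.5, 0.5, -0.5)
  }
  i1 <- which(inp$lev2 == 0L)
  p1 <- length(i1)
  Om1 <- stats::cov(Z[, i1, drop = FALSE])
  Om1 <- Om1 + diag(1e-4 + 1e-3 * mean(diag(Om1)), p1)
  for (a in seq_len(p1)) {
    if (inp$isbin[i1[a]] == 1L) {
      s <- sqrt(Om1[a, a])
      Om1[a, ] <- Om1[a, ] / s
      Om1[, a] <- Om1[, a] / s
      Om1[a, a] <- 1
    }
  }
  U <- matrix(0, inp$J, p)
  Om2 <- diag(p)
  for (k in seq_len(p)) {
    if (inp$lev2[k] == 1L) {
      cl_vals <- tapply(Z[, k], ds$cluster, function(x) x[1])
      U[, k] <- cl_vals - alpha[k]
      Om2[k, k] <- if (inp$isbin[k] == 1L) 1 else max(stats::var(cl_vals), 1e-3)
    } else {
      Om2[k, k] <- 0.1 * max(Om1[match(k, i1), match(k, i1)], 1e-3)
    }
  }
  list(alpha = alpha, u = U, omega1 = Om1, omega2 = Om2, z = Z, values = Y,
       variables = inp$variables)
}

build_imputation_result <- function(res, ds, inp, config, method, chain_names,
                                    extra = list()) {
  chains <- res$chains
  colnames(chains) <- chain_names
  source_data <- ds$data[, inp$variables, drop = FALSE]
  imps <- lapply(seq_along(res$imputations), function(m) {
    vals <- res$imputations[[m]]
    colnames(vals) <- inp$variables
    full <- ds$data
    full[, inp$variables] <- vals
    # never overwrite observed cells (bit-identical preservation)
    full[ds$mask] <- ds$data[ds$mask]
    as_completed(ds, full, m)
  })
  out <- c(list(imputations = imps, chains = chains, method = method,
                config = config, variables = inp$variables,
                state = res$state,
                accept_cov = res$accept_cov),
           extra)
  if (!is.null(res$cell_trace)) out$cell_trace <- res$cell_trace
  structure(out, class = "imputation_result")
}

#' Impute with the homoscedastic latent-normal joint model
#'
#' All joint-model variables (outcome, covariates and auxiliaries by
#' default) are modelled as a multivariate latent normal with a common
#' level-1 covariance and cluster random effects; missing cells are imputed
#' by data-augmentation MCMC. Imputations are registered at iterations
#' `n_burn, n_burn + n_between, ...`.
#'
#' @param ds A [multilevel_dataset()].
#' @param config An [mcmc_config()].
#' @param variables Variables to include in the joint model (default: all
#'   non-cluster columns).
#' @return An object of class `imputation_result`: `imputations` (list of M
#'   completed datasets), `chains` (one row per MCMC iteration), `method`,
#'   `config`.
#' @export
impute_jm_hom <- function(ds, config = mcmc_config(), variables = NULL) {
  run_jm(ds, config, variables, het = FALSE)
}

#' Impute with the heteroscedastic (cluster-specific covariance) joint model
#'
#' As [impute_jm_hom()], but each cluster has its own level-1 covariance
#' drawn around an inverse-Wishart hierarchy `IW(a, A)`; the scale `A` is
#' given a Wishart hyperprior and updated conjugately each sweep.
#'
#' @inheritParams impute_jm_hom
#' @param iw_df Inverse-Wishart degrees of freedom `a` (default `p + 3` for
#'   `p` level-1 variables; must exceed `p - 1`).
#' @return An `imputation_result`.
#' @export
impute_jm_het <- function(ds, config = mcmc_config(), variables = NULL,
                          iw_df = NULL) {
  run_jm(ds, config, variables, het = TRUE, iw_df = iw_df)
}

#' Extract a stored parameter chain
#'
#' @param result An `imputation_result`.
#' @param parameter Chain name, e.g. `"alpha[age]"` or `"omega1[PAR,PAR]"`;
#'   see `colnames(result$chains)`.
#' @return Numeric vector with one value per MCMC iteration.
#' @export
get_chain <- function(result, parameter) {
  stopifnot(inherits(result, "imputation_result"))
  if (!parameter %in% colnames(result$chains))
    stop("unknown parameter '", parameter, "'; available: ",
         paste(utils::head(colnames(result$chains), 20), collapse = ", "),
         call. = FALSE)
  result$chains[, parameter]
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("imputation_result (", x$method, "): ", length(x$imputations),
      " imputations, ", nrow(x$chains), " MCMC iterations\n", sep = "")
  invisible(x)
}

#' Write imputations as a stacked CSV
#'
#' Standard stacked multiple-imputation format: `imputation` column 0 holds
#' the original data with the missing token, 1..M the completed datasets.
#'
#' @param result An `imputation_result`.
#' @param ds The source dataset (for the original rows).
#' @param path Output CSV path.
#' @param missing_token Token for missing entries in the original rows.
#' @export
write_imputations <- function(result, ds, path, missing_token = "NA") {
  orig <- as.data.frame(ds)
  orig$imputation <- 0L
  stacks <- lapply(seq_along(result$imputations), function(m) {
    df <- as.data.frame(result$imputations[[m]])
    df$imputation <- m
    df
  })
  all <- do.call(rbind, c(list(orig), stacks))
  utils::write.csv(all, path, row.names = FALSE, na = missing_token)
  invisible(NULL)
}

#' Write parameter chains as CSV
#' @param result An `imputation_result`.
#' @param path Output CSV path.
#' @export
write_chains <- function(result, path) {
  df <- data.frame(iteration = seq_len(nrow(result$chains)), result$chains,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}
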