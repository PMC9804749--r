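#' Fit the substantive mixed model to a completed dataset
#'
#' Gaussian outcomes are fitted by REML (switchable to ML) with
#' \pkg{lme4}; binomial outcomes by Laplace-approximate ML with
#' `lme4::glmer`; ordinal outcomes by a cumulative-logit (ocat) model with a
#' cluster random-effect smooth in \pkg{mgcv}. Non-convergence and singular
#' random-effect covariances are flagged, not raised.
#'
#' @param ds A completed dataset (no missing cells among the model
#'   variables).
#' @param spec A [substantive_model_spec()].
#' @param reml Use REML for the gaussian family (default `TRUE`).
#' @return An object of class `model_fit` with `estimates`, `se`, `vc`
#'   (variance components `sigma_u00`, `sigma_u01`, `sigma_u11`,
#'   `sigma_e2`, as applicable), `converged` and `singular`.
#' @export
fit_mixed <- function(ds, spec, reml = TRUE) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  validate_spec(spec, ds)
  vars <- spec_covariates(spec)
  if (any(!ds$mask[, c(spec$outcome, vars)]))
    stop("fit_mixed requires complete data for the model variables",
         call. = FALSE)
  df <- as.data.frame(ds$data[, c(spec$outcome, vars), drop = FALSE])
  df$.cluster <- factor(ds$cluster)
  fixed_txt <- vapply(spec$terms, function(t) {
    f1 <- if (t$p1 > 1L) paste0("I(", t$v1, "^", t$p1, ")") else t$v1
    if (is.na(t$v2)) return(f1)
    f2 <- if (t$p2 > 1L) paste0("I(", t$v2, "^", t$p2, ")") else t$v2
    paste0(f1, ":", f2)
  }, character(1))
  labs <- param_labels(spec)
  r <- 1L + length(spec$random$slopes)

  if (spec$family == "ordinal_cumulative_logit") {
    fml <- stats::as.formula(paste(spec$outcome, "~",
                                   paste(fixed_txt, collapse = " + "),
                                   "+ s(.cluster, bs = 're')"))
    fit <- try(mgcv::gam(fml, data = df, family = mgcv::ocat(R = max(df[[spec$outcome]])),
                         method = "REML"), silent = TRUE)
    if (inherits(fit, "try-error"))
      return(failed_fit(labs, vc_labels(spec)))
    sm <- summary(fit)
    est <- sm$p.coeff[-1]           # drop the ocat intercept (cutpoint role)
    se <- sm$se[seq_along(sm$p.coeff)][-1]
    names(est) <- names(se) <- labs
    vcomp <- try({
      tmp <- NULL
      utils::capture.output(tmp <- mgcv::gam.vcomp(fit))
      tmp
    }, silent = TRUE)
    s_u <- if (inherits(vcomp, "try-error")) NA_real_ else vcomp[1, 1]^2
    vc <- c(sigma_u00 = s_u, sigma_e2 = NA_real_)
    return(structure(list(estimates = est, se = se, vc = vc,
                          converged = fit$converged %||% TRUE,
                          singular = FALSE, fit = NULL),
                     class = "model_fit"))
  }

  rnd <- if (r > 1L)
    paste0("(1 + ", paste(spec$random$slopes, collapse = " + "), " | .cluster)")
  else "(1 | .cluster)"
  fml <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(fixed_txt, collapse = " + "), "+", rnd))
  fit <- if (spec$family == "gaussian_identity") {
    try(suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = df, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)))),
      silent = TRUE)
  } else {
    try(suppressWarnings(suppressMessages(
      lme4::glmer(fml, data = df, family = stats::binomial(),
                  control = lme4::glmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE)))),
      silent = TRUE)
  }
  if (inherits(fit, "try-error")) return(failed_fit(labs, vc_labels(spec)))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(est) <- names(se) <- labs
  vcm <- lme4::VarCorr(fit)$.cluster
  vc <- numeric(0)
  for (i in seq_len(r)) for (j in seq_len(i))
    vc <- c(vc, vcm[i, j])
  vc <- c(vc, if (spec$family == "gaussian_identity")
    stats::sigma(fit)^2 else NA_real_)
  names(vc) <- vc_labels(spec)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(list(estimates = est, se = se, vc = vc,
                 converged = is.null(msgs) || length(msgs) == 0L,
                 singular = lme4::isSingular(fit), fit = NULL),
            class = "model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

failed_fit <- function(labs, vlabs) {
  structure(list(estimates = stats::setNames(rep(NA_real_, length(labs)), labs),
                 se = stats::setNames(rep(NA_real_, length(labs)), labs),
                 vc = stats::setNames(rep(NA_real_, length(vlabs)), vlabs),
                 converged = FALSE, singular = NA, fit = NULL),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit (converged:", x$converged, ")\n")
  print(round(rbind(estimate = x$estimates, se = x$se), 4))
  cat("variance components:\n")
  print(round(x$vc, 4))
  invisible(x)
}

#' Pool multiply-imputed fits with Rubin's rules
#'
#' `qbar` is the mean of the M point estimates, `B` their sample variance,
#' `W` the mean squared model SE, and the total variance
#' `T = W + (1 + 1/M) B`. Degrees of freedom follow the standard
#' small-sample formula `nu = (M - 1) (1 + W / ((1 + 1/M) B))^2`; when
#' `B = 0` the degrees of freedom are taken as infinite (normal quantile)
#' by convention. Variance components are pooled as simple means (point
#' summaries only).
#'
#' @param fits List of M [fit_mixed()] results over the M completed
#'   datasets (identical parameter names).
#' @param level Confidence level (default 0.95).
#' @return An object of class `pooled_estimates` with `qbar`, `within`,
#'   `between`, `total_var`, `df`, `ci` (matrix) and `vc_mean`.
#' @export
pool_rubin <- function(fits, level = 0.95) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) && !anyNA(f$estimates),
               logical(1))
  if (any(!ok))
    warning(sum(!ok), " non-converged fit(s) excluded from pooling",
            call. = FALSE)
  fits <- fits[ok]
  M <- length(fits)
  if (M < 2L) stop("at least 2 converged fits are required", call. = FALSE)
  nm <- names(fits[[1]]$estimates)
  if (!all(vapply(fits, function(f) identical(names(f$estimates), nm),
                  logical(1))))
    stop("parameter names differ across fits", call. = FALSE)
  Q <- do.call(rbind, lapply(fits, function(f) f$estimates))
  S <- do.call(rbind, lapply(fits, function(f) f$se))
  qbar <- colMeans(Q)
  B <- apply(Q, 2, stats::var)
  W <- colMeans(S^2)
  Tv <- W + (1 + 1 / M) * B
  df <- ifelse(B > 0, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, Inf)
  a <- 1 - (1 - level) / 2
  tq <- ifelse(is.finite(df), stats::qt(a, df), stats::qnorm(a))
  ci <- cbind(lower = qbar - tq * sqrt(Tv), upper = qbar + tq * sqrt(Tv))
  Vc <- do.call(rbind, lapply(fits, function(f) f$vc))
  structure(list(qbar = qbar, within = W, between = B, total_var = Tv,
                 df = df, ci = ci, level = level, m = M,
                 vc_mean = colMeans(Vc)),
            class = "pooled_estimates")
}

#' @export
print.pooled_estimates <- function(x, ...) {
  cat("Rubin-pooled estimates (M =", x$m, "):\n")
  print(round(data.frame(estimate = x$qbar, se = sqrt(x$total_var),
                         df = x$df, ci_low = x$ci[, 1], ci_high = x$ci[, 2]),
              4))
  cat("variance components (means):\n")
  print(round(x$vc_mean, 4))
  invisible(x)
}

#' @export
as.data.frame.pooled_estimates <- function(x, ...) {
  data.frame(parameter = names(x$qbar), estimate = unname(x$qbar),
             se = unname(sqrt(x$total_var)), df = unname(x$df),
             ci_low = unname(x$ci[, 1]), ci_high = unname(x$ci[, 2]),
             stringsAsFactors = FALSE)
}

#' Outcome-given-covariates coefficients implied by a latent-normal joint model
#'
#' Under the homoscedastic joint model, conditioning the outcome row on the
#' covariate rows gives a linear predictor whose coefficients depend on the
#' covariance elements only: the cross-covariance vector times the inverse
#' of the covariate block. This is the algebra behind the compatibility of
#' the homoscedastic joint model with a random-intercept analysis model —
#' and behind its incompatibility with a random slope, which would need
#' those (fixed) covariance elements to vary by cluster.
#'
#' @param alpha Joint-model intercepts (outcome first).
#' @param omega1 Level-1 covariance (outcome row/column first).
#' @param omega2 Optional level-2 (random-effect) covariance, same order;
#'   when supplied, the implied random-intercept variance of the
#'   conditional model is returned as well.
#' @return List with `beta` (covariate coefficients), `intercept`,
#'   `residual_var`, and `random_intercept_var` when `omega2` is given.
#' @export
implied_conditional_coefficients <- function(alpha, omega1, omega2 = NULL) {
  p <- nrow(omega1)
  stopifnot(p >= 2, length(alpha) == p)
  xs <- 2:p
  Oxx <- omega1[xs, xs, drop = FALSE]
  if (rcond(Oxx) < 1e-12) stop("covariate block is singular", call. = FALSE)
  oyx <- omega1[1, xs]
  beta <- drop(solve(Oxx, oyx))
  names(beta) <- colnames(omega1)[xs] %||% paste0("x", seq_along(beta))
  out <- list(beta = beta,
              intercept = alpha[1] - sum(beta * alpha[xs]),
              residual_var = omega1[1, 1] - sum(oyx * beta))
  if (!is.null(omega2)) {
    cvec <- c(1, -beta)
    out$random_intercept_var <- drop(cvec %*% omega2 %*% cvec)
  }
  out
}
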