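#' ADEMP performance measures with Monte-Carlo errors
#'
#' Bias, relative bias, empirical SE, model-based SE and confidence-interval
#' coverage over simulation replicates, each with its Monte-Carlo standard
#' error (Morris, White and Crowther's formulas). Relative bias is flagged
#' undefined when the true value is zero; absolute bias is always reported.
#'
#' @param estimates Replicate point estimates.
#' @param ses Replicate model-based standard errors (may be `NULL`).
#' @param ci_low,ci_high Replicate confidence-interval bounds (may be
#'   `NULL`).
#' @param truth True parameter value.
#' @return One-row data frame of metrics and Monte-Carlo errors.
#' @export
performance_measures <- function(estimates, ses = NULL, ci_low = NULL,
                                 ci_high = NULL, truth) {
  keep <- is.finite(estimates)
  estimates <- estimates[keep]
  n <- length(estimates)
  if (n < 2L) stop("at least 2 replicates are required", call. = FALSE)
  m <- mean(estimates)
  emp_se <- stats::sd(estimates)
  bias <- m - truth
  bias_mce <- emp_se / sqrt(n)
  rel <- if (truth != 0) 100 * bias / truth else NA_real_
  rel_mce <- if (truth != 0) 100 * bias_mce / abs(truth) else NA_real_
  mod_se <- mod_se_mce <- NA_real_
  if (!is.null(ses)) {
    s2 <- ses[keep]^2
    s2 <- s2[is.finite(s2)]
    if (length(s2) >= 2) {
      mod_se <- sqrt(mean(s2))
      mod_se_mce <- sqrt(stats::var(s2) / (4 * length(s2) * mod_se^2))
    }
  }
  cov_pct <- cov_mce <- NA_real_
  if (!is.null(ci_low) && !is.null(ci_high)) {
    cl <- ci_low[keep]; ch <- ci_high[keep]
    okci <- is.finite(cl) & is.finite(ch)
    if (any(okci)) {
      cov_pct <- 100 * mean(cl[okci] <= truth & truth <= ch[okci])
      cov_mce <- sqrt(cov_pct * (100 - cov_pct) / sum(okci))
    }
  }
  data.frame(n = n, truth = truth, mean = m, bias = bias, bias_mce = bias_mce,
             rel_bias_pct = rel, rel_bias_mce = rel_mce,
             emp_se = emp_se, emp_se_mce = emp_se / sqrt(2 * (n - 1)),
             model_se = mod_se, model_se_mce = mod_se_mce,
             coverage_pct = cov_pct, coverage_mce = cov_mce)
}

fit_to_rows <- function(fit, method, rep, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  fx <- data.frame(rep = rep, method = method, parameter = names(fit$estimates),
                   type = "fixed", estimate = unname(fit$estimates),
                   se = unname(fit$se),
                   ci_low = unname(fit$estimates - z * fit$se),
                   ci_high = unname(fit$estimates + z * fit$se),
                   converged = fit$converged, stringsAsFactors = FALSE)
  vc <- data.frame(rep = rep, method = method, parameter = names(fit$vc),
                   type = "vc", estimate = unname(fit$vc), se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   converged = fit$converged, stringsAsFactors = FALSE)
  rbind(fx, vc)
}

pooled_to_rows <- function(pl, method, rep) {
  df <- as.data.frame(pl)
  fx <- data.frame(rep = rep, method = method, parameter = df$parameter,
                   type = "fixed", estimate = df$estimate, se = df$se,
                   ci_low = df$ci_low, ci_high = df$ci_high, converged = TRUE,
                   stringsAsFactors = FALSE)
  vc <- data.frame(rep = rep, method = method, parameter = names(pl$vc_mean),
                   type = "vc", estimate = unname(pl$vc_mean), se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, converged = TRUE,
                   stringsAsFactors = FALSE)
  rbind(fx, vc)
}

na_rows <- function(method, rep, labs) {
  data.frame(rep = rep, method = method, parameter = labs, type = "fixed",
             estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, converged = FALSE, stringsAsFactors = FALSE)
}

#' Run a simulation study
#'
#' For each replicate: generate a fully observed dataset, fit the
#' substantive model (full-data reference), impose the MAR mechanism, fit
#' on the complete records, then run each requested imputation method, fit
#' the substantive model on every completed dataset and pool with Rubin's
#' rules. Performance measures with Monte-Carlo errors are computed per
#' method and parameter. The report is reproducible from `(config, seed)`
#' alone; per-replicate failures are logged and excluded, never raised.
#'
#' @param cfg A [scenario_config()].
#' @param methods Subset of `"full_data"`, `"complete_records"`,
#'   `"jm_hom"`, `"jm_het"`, `"smc_jm"`.
#' @param verbose Print per-replicate progress.
#' @return An object of class `simulation_report` with `metrics`
#'   (per method x parameter), `replicates` (rep-level estimates and CIs),
#'   `truth`, `failures` and the config.
#' @export
run_study <- function(cfg, methods = c("full_data", "complete_records",
                                       "jm_hom", "jm_het", "smc_jm"),
                      verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  methods <- match.arg(methods, c("full_data", "complete_records", "jm_hom",
                                  "jm_het", "smc_jm"), several.ok = TRUE)
  spec <- cfg$spec
  labs <- param_labels(spec)
  rows <- list()
  failures <- list()
  mcfg <- mcmc_config(n_burn = cfg$n_burn, n_between = cfg$n_between,
                      n_imputations = cfg$M)

  for (r in seq_len(cfg$n_reps)) {
    gen <- generate_scenario(cfg, r)
    ds_full <- gen$dataset
    ds_miss <- NULL
    needs_miss <- any(methods != "full_data")
    if (needs_miss) {
      set.seed(child_seed(child_seed(cfg$seed, r), 999))
      ds_miss <- apply_mar(ds_full, target = cfg$mar_target,
                           gamma1 = cfg$mar_gamma1, vars = cfg$mar_vars,
                           systematic_fraction = cfg$systematically_missing_fraction)
    }
    for (mi in seq_along(methods)) {
      method <- methods[mi]
      set.seed(child_seed(child_seed(cfg$seed, r), mi))
      res <- tryCatch({
        if (method == "full_data") {
          fit_to_rows(fit_mixed(ds_full, spec), method, r)
        } else if (method == "complete_records") {
          keep <- rowSums(!ds_miss$mask[, cfg$mar_vars, drop = FALSE]) == 0
          fit_to_rows(fit_mixed(ds_subset_rows(ds_miss, which(keep)), spec),
                      method, r)
        } else {
          imp <- switch(method,
            jm_hom = impute_jm_hom(ds_miss, mcfg),
            jm_het = impute_jm_het(ds_miss, mcfg),
            smc_jm = impute_smc_jm(ds_miss, spec, mcfg))
          fits <- lapply(imp$imputations, fit_mixed, spec = spec)
          pooled_to_rows(suppressWarnings(pool_rubin(fits)), method, r)
        }
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<-
          data.frame(rep = r, method = method, message = conditionMessage(e),
                     stringsAsFactors = FALSE)
        na_rows(method, r, labs)
      })
      rows[[length(rows) + 1L]] <- res
    }
    if (verbose) message("replicate ", r, "/", cfg$n_reps, " done")
  }

  replicates <- do.call(rbind, rows)
  truth <- gen_truth(cfg)
  metrics <- list()
  for (method in methods) {
    for (par in names(truth)) {
      sub <- replicates[replicates$method == method &
                        replicates$parameter == par, ]
      if (nrow(sub) == 0 || sum(is.finite(sub$estimate)) < 2) next
      pm <- performance_measures(sub$estimate, sub$se, sub$ci_low,
                                 sub$ci_high, truth[[par]])
      metrics[[length(metrics) + 1L]] <-
        cbind(data.frame(method = method, parameter = par,
                         type = sub$type[1], stringsAsFactors = FALSE), pm)
    }
  }
  structure(list(metrics = do.call(rbind, metrics), replicates = replicates,
                 truth = truth,
                 failures = if (length(failures)) do.call(rbind, failures)
                            else NULL,
                 config = cfg),
            class = "simulation_report")
}

gen_truth <- function(cfg) {
  tr <- cfg$truth$beta
  tr["sigma_u00"] <- cfg$truth$sigma_u00
  if (!is.null(cfg$truth$sigma_u11)) {
    tr["sigma_u01"] <- cfg$truth$sigma_u01
    tr["sigma_u11"] <- cfg$truth$sigma_u11
  }
  as.list(tr)
}

#' @export
print.simulation_report <- function(x, ...) {
  cat("simulation_report:", x$config$scenario, "scenario,",
      x$config$n_reps, "replicates\n")
  cols <- c("method", "parameter", "truth", "mean", "rel_bias_pct",
            "emp_se", "model_se", "coverage_pct")
  print(cbind(x$metrics[, c("method", "parameter")],
              round(x$metrics[, setdiff(cols, c("method", "parameter"))], 4)))
  if (!is.null(x$failures))
    cat(nrow(x$failures), "replicate-method failures logged\n")
  invisible(x)
}

#' Rep-level confidence intervals ranked for zipper plotting
#'
#' Orders the replicates by the centile of the standardised estimate (most
#' extreme first, the convention of zipper plots) and flags whether each
#' replicate's interval covered the truth. The flags are invariant to the
#' original replicate order.
#'
#' @param report A [run_study()] report.
#' @param method,parameter Which arm and parameter to extract.
#' @return Data frame with `rep`, `estimate`, `ci_low`, `ci_high`,
#'   `centile`, `covered`, sorted for plotting.
#' @export
zipper_data <- function(report, method, parameter) {
  stopifnot(inherits(report, "simulation_report"))
  sub <- report$replicates[report$replicates$method == method &
                           report$replicates$parameter == parameter &
                           report$replicates$type == "fixed", ]
  sub <- sub[is.finite(sub$estimate) & is.finite(sub$se) & sub$se > 0, ]
  truth <- report$truth[[parameter]]
  z <- abs(sub$estimate - truth) / sub$se
  ord <- order(z, decreasing = TRUE)
  out <- data.frame(rep = sub$rep, estimate = sub$estimate,
                    ci_low = sub$ci_low, ci_high = sub$ci_high,
                    centile = (rank(z, ties.method = "first") - 0.5) / nrow(sub),
                    covered = sub$ci_low <= truth & truth <= sub$ci_high)
  out[ord, ]
}

#' Write a simulation report to disk
#'
#' Writes the metrics table as CSV, a JSON summary, and the rep-level log.
#'
#' @param report A [run_study()] report.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = report$config$scenario,
         n_reps = report$config$n_reps, seed = report$config$seed,
         truth = report$truth, metrics = report$metrics,
         n_failures = if (is.null(report$failures)) 0L
                      else nrow(report$failures)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$failures))
    utils::write.csv(report$failures, file.path(dir, "failures.csv"),
                     row.names = FALSE)
  invisible(NULL)
}
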