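#' Declare the substantive (analysis) model
#'
#' The substantive model is the mixed-effects model the analyst would fit to
#' complete data; under SMC-JM it is also the outcome factor of the joint
#' imputation model, so it must be declared before imputation. Fixed-effect
#' terms are written as strings over base covariates: main effects
#' (`"PAR"`), integer powers (`"age^2"`) and two-way products
#' (`"PAR:age"`, including cross-level products). Derived terms are always
#' recomputed from the base covariates, never imputed as free columns.
#'
#' @param outcome Outcome variable name.
#' @param fixed Character vector of fixed-effect term strings (an intercept
#'   is implicit, except for the ordinal family where it is absorbed by the
#'   cutpoints).
#' @param random List with `intercept` (logical, default `TRUE`) and
#'   `slopes` (character vector of level-1 covariates with random slopes);
#'   the random-effect covariance is unstructured.
#' @param family `"gaussian_identity"`, `"binomial_logit"` or
#'   `"ordinal_cumulative_logit"`.
#' @return An object of class `substantive_model_spec`.
#' @export
substantive_model_spec <- function(outcome, fixed,
                                   random = list(intercept = TRUE,
                                                 slopes = character(0)),
                                   family = "gaussian_identity") {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  family <- match.arg(family, c("gaussian_identity", "binomial_logit",
                                "ordinal_cumulative_logit"))
  if (is.null(random$intercept)) random$intercept <- TRUE
  if (is.null(random$slopes)) random$slopes <- character(0)
  if (!isTRUE(random$intercept))
    stop("a random intercept is required", call. = FALSE)
  terms <- lapply(fixed, parse_term)
  spec <- structure(list(outcome = outcome, fixed = fixed, terms = terms,
                         random = random, family = family),
                    class = "substantive_model_spec")
  if (outcome %in% unlist(lapply(terms, term_vars)))
    stop("the outcome cannot appear among the fixed-effect terms",
         call. = FALSE)
  spec
}

parse_factor <- function(txt) {
  m <- regmatches(txt, regexec("^([A-Za-z._][A-Za-z0-9._]*)(\\^([0-9]+))?$", txt))[[1]]
  if (length(m) == 0)
    stop("cannot parse term factor '", txt, "'", call. = FALSE)
  pow <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (pow < 1L) stop("powers must be integers >= 1", call. = FALSE)
  list(var = m[2], power = pow)
}

parse_term <- function(txt) {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  if (length(parts) > 2L)
    stop("only two-way products are supported: '", txt, "'", call. = FALSE)
  f1 <- parse_factor(parts[1])
  f2 <- if (length(parts) == 2L) parse_factor(parts[2]) else NULL
  list(label = txt, v1 = f1$var, p1 = f1$power,
       v2 = if (is.null(f2)) NA_character_ else f2$var,
       p2 = if (is.null(f2)) 0L else f2$power)
}

term_vars <- function(term) {
  v <- term$v1
  if (!is.na(term$v2)) v <- c(v, term$v2)
  v
}

#' Base covariates referenced by a model spec
#' @param spec A [substantive_model_spec()].
#' @return Character vector of distinct covariate names.
#' @export
spec_covariates <- function(spec) {
  unique(c(unlist(lapply(spec$terms, term_vars)), spec$random$slopes))
}

param_labels <- function(spec) {
  labs <- vapply(spec$terms, function(t) t$label, character(1))
  if (spec$family == "ordinal_cumulative_logit") labs else c("(Intercept)", labs)
}

validate_spec <- function(spec, ds) {
  meta <- ds$meta
  vars <- spec_covariates(spec)
  miss <- setdiff(c(spec$outcome, vars), meta$name)
  if (length(miss))
    stop("model spec references unknown variables: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (v in spec$random$slopes) {
    if (meta$level[meta$name == v] != 1L)
      stop("random-slope variable '", v, "' must be a level-1 covariate",
           call. = FALSE)
  }
  if (spec$family == "ordinal_cumulative_logit") {
    y <- ds$data[, spec$outcome][ds$mask[, spec$outcome]]
    if (any(y != round(y)) || length(unique(y)) < 3L)
      stop("ordinal family requires an integer-coded outcome with >= 3 levels",
           call. = FALSE)
  }
  invisible(spec)
}

#' Expand one covariate vector into a fixed-effect design row
#'
#' Deterministic expansion in declared term order: intercept (unless
#' ordinal), main effects, powers and products.
#'
#' @param spec A [substantive_model_spec()].
#' @param covariate_values Named numeric vector with every referenced
#'   covariate.
#' @return Named numeric design row.
#' @export
design_row <- function(spec, covariate_values) {
  need <- spec_covariates(spec)
  miss <- setdiff(need, names(covariate_values))
  if (length(miss))
    stop("missing covariates for design row: ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- vapply(spec$terms, function(t) {
    v <- covariate_values[[t$v1]]^t$p1
    if (!is.na(t$v2)) v <- v * covariate_values[[t$v2]]^t$p2
    v
  }, numeric(1))
  if (spec$family == "ordinal_cumulative_logit") {
    stats::setNames(vals, param_labels(spec))
  } else {
    stats::setNames(c(1, vals), param_labels(spec))
  }
}

# design matrix for a named matrix / data frame of covariates
design_matrix <- function(spec, values) {
  values <- as.matrix(values)
  cols <- lapply(spec$terms, function(t) {
    v <- values[, t$v1]^t$p1
    if (!is.na(t$v2)) v <- v * values[, t$v2]^t$p2
    v
  })
  X <- do.call(cbind, cols)
  if (spec$family != "ordinal_cumulative_logit") X <- cbind(1, X)
  colnames(X) <- param_labels(spec)
  X
}

# random-effect design matrix (intercept + slopes)
rand_design <- function(spec, values) {
  values <- as.matrix(values)
  Zr <- matrix(1, nrow(values), 1)
  for (v in spec$random$slopes) Zr <- cbind(Zr, values[, v])
  colnames(Zr) <- c("(Intercept)", spec$random$slopes)
  Zr
}

vc_labels <- function(spec) {
  r <- 1L + length(spec$random$slopes)
  labs <- character(0)
  for (i in seq_len(r)) for (j in seq_len(i))
    labs <- c(labs, paste0("sigma_u", j - 1, i - 1))
  c(labs, "sigma_e2")
}

#' Serialise a model spec to YAML
#' @param spec A [substantive_model_spec()].
#' @param path Output path.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(list(outcome = spec$outcome, terms = as.list(spec$fixed),
                        random = list(intercept = spec$random$intercept,
                                      slopes = as.list(spec$random$slopes)),
                        family = spec$family), path)
  invisible(NULL)
}

#' Read a model spec from YAML
#' @param path YAML file written by [write_model_spec()].
#' @return A [substantive_model_spec()].
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  substantive_model_spec(
    outcome = y$outcome, fixed = unlist(y$terms),
    random = list(intercept = isTRUE(y$random$intercept),
                  slopes = as.character(unlist(y$random$slopes))),
    family = y$family)
}

#' @export
print.substantive_model_spec <- function(x, ...) {
  rnd <- if (length(x$random$slopes))
    paste0("(1 + ", paste(x$random$slopes, collapse = " + "), " | cluster)")
  else "(1 | cluster)"
  cat("substantive model [", x$family, "]: ", x$outcome, " ~ ",
      paste(x$fixed, collapse = " + "), " + ", rnd, "\n", sep = "")
  invisible(x)
}
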