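#' Describe one variable of a two-level dataset
#'
#' Builds the metadata record used throughout the package: which level a
#' variable lives at (1 = varies by row, 2 = constant within cluster), whether
#' it is continuous or binary, and its role in the analysis. Exactly one
#' variable must have role `"cluster_id"` and exactly one role `"outcome"`.
#'
#' @param name Variable name, matching the CSV header.
#' @param level 1 or 2. Ignored (fixed to 2) for the cluster id.
#' @param vtype `"continuous"` or `"binary"`. Binary variables must take
#'   values in \{0, 1\} where observed.
#' @param role One of `"outcome"`, `"covariate"`, `"auxiliary"`,
#'   `"cluster_id"`.
#' @return A one-row data frame; rows for several variables are combined with
#'   `rbind()` into the `meta` argument of [multilevel_dataset()].
#' @export
variable_meta <- function(name, level = 1, vtype = "continuous", role = "covariate") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  level <- as.integer(level)
  if (!level %in% c(1L, 2L)) stop("level must be 1 or 2", call. = FALSE)
  vtype <- match.arg(vtype, c("continuous", "binary"))
  role <- match.arg(role, c("outcome", "covariate", "auxiliary", "cluster_id"))
  data.frame(name = name, level = level, vtype = vtype, role = role,
             stringsAsFactors = FALSE)
}

validate_meta <- function(meta) {
  need <- c("name", "level", "vtype", "role")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("meta must be a data frame with columns name, level, vtype, role",
         call. = FALSE)
  if (anyDuplicated(meta$name)) stop("duplicate variable names in meta", call. = FALSE)
  if (sum(meta$role == "cluster_id") != 1L)
    stop("exactly one variable must have role 'cluster_id'", call. = FALSE)
  if (sum(meta$role == "outcome") != 1L)
    stop("exactly one variable must have role 'outcome'", call. = FALSE)
  if (!all(meta$level %in% c(1L, 2L))) stop("levels must be 1 or 2", call. = FALSE)
  if (!all(meta$vtype %in% c("continuous", "binary")))
    stop("vtype must be 'continuous' or 'binary'", call. = FALSE)
  meta
}

#' Construct a two-level dataset with explicit missingness
#'
#' The container shared by the imputation samplers and the simulation
#' harness. Values are stored as a numeric matrix with a parallel logical
#' mask (`TRUE` = observed); the mask, never a magic value, is the missing
#' sentinel. Cluster labels may be arbitrary; they are mapped to contiguous
#' integer indices internally and restored on write.
#'
#' @param df Data frame holding one column per `meta` row, missing entries as
#'   `NA`. The cluster-id column may be character, factor or numeric.
#' @param meta Data frame of [variable_meta()] rows covering every column.
#' @return An object of class `multilevel_dataset` with elements `data`
#'   (numeric matrix over the non-cluster variables), `mask` (logical
#'   matrix), `meta`, `cluster` (integer index 1..J) and `cluster_labels`.
#' @export
multilevel_dataset <- function(df, meta) {
  meta <- validate_meta(meta)
  if (!all(meta$name %in% names(df)))
    stop("data is missing columns declared in meta: ",
         paste(setdiff(meta$name, names(df)), collapse = ", "), call. = FALSE)
  cl_var <- meta$name[meta$role == "cluster_id"]
  cl_raw <- df[[cl_var]]
  if (anyNA(cl_raw)) stop("cluster id must be fully observed", call. = FALSE)
  cl_f <- factor(cl_raw, levels = unique(cl_raw))
  vmeta <- meta[meta$role != "cluster_id", , drop = FALSE]
  rownames(vmeta) <- NULL
  dat <- sapply(vmeta$name, function(v) as.numeric(df[[v]]))
  dat <- matrix(dat, nrow = nrow(df), dimnames = list(NULL, vmeta$name))
  mask <- !is.na(dat)
  ds <- structure(
    list(data = dat, mask = mask, meta = vmeta,
         cluster = as.integer(cl_f), cluster_labels = levels(cl_f),
         cluster_var = cl_var),
    class = "multilevel_dataset")
  validate_dataset(ds)
}

validate_dataset <- function(ds) {
  meta <- ds$meta
  if (length(ds$cluster_labels) < 2L)
    stop("at least 2 clusters are required", call. = FALSE)
  for (v in meta$name[meta$vtype == "binary"]) {
    x <- ds$data[, v][ds$mask[, v]]
    if (length(x) && !all(x %in% c(0, 1)))
      stop("binary variable '", v, "' takes values outside {0, 1}", call. = FALSE)
  }
  for (v in meta$name[meta$level == 2L]) {
    vals <- split(ds$data[, v], ds$cluster)
    ok_val <- vapply(vals, function(x) {
      x <- x[!is.na(x)]
      length(x) == 0L || all(x == x[1L])
    }, logical(1))
    if (!all(ok_val))
      stop("level-2 variable '", v, "' varies within a cluster", call. = FALSE)
    msk <- split(ds$mask[, v], ds$cluster)
    ok_msk <- vapply(msk, function(m) all(m) || all(!m), logical(1))
    if (!all(ok_msk))
      stop("level-2 variable '", v,
           "' is partially observed within a cluster", call. = FALSE)
  }
  ds
}

n_clusters <- function(ds) length(ds$cluster_labels)

#' @export
print.multilevel_dataset <- function(x, ...) {
  cat("multilevel_dataset:", nrow(x$data), "rows,",
      n_clusters(x), "clusters,", ncol(x$data), "variables\n")
  mfrac <- round(colMeans(!x$mask), 3)
  info <- paste0(x$meta$name, " (L", x$meta$level, " ", x$meta$vtype, " ",
                 x$meta$role, ", ", 100 * mfrac, "% missing)")
  cat(paste(" ", info, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.multilevel_dataset <- function(x, ...) {
  dat <- x$data
  dat[!x$mask] <- NA
  out <- as.data.frame(dat)
  out[[x$cluster_var]] <- x$cluster_labels[x$cluster]
  out[, c(x$cluster_var, x$meta$name), drop = FALSE]
}

#' Read a two-level dataset from CSV
#'
#' @param path CSV file with a header row containing every `meta` name.
#' @param meta Variable metadata (see [variable_meta()]).
#' @param missing_token Text encoding a missing entry (default `"NA"`).
#' @return A [multilevel_dataset()].
#' @export
read_dataset <- function(path, meta, missing_token = "NA") {
  meta <- validate_meta(meta)
  df <- utils::read.csv(path, na.strings = missing_token, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(meta$name %in% names(df)))
    stop("CSV header does not match meta: missing ",
         paste(setdiff(meta$name, names(df)), collapse = ", "), call. = FALSE)
  multilevel_dataset(df, meta)
}

#' Write a dataset (or completed dataset) to CSV
#'
#' Column order is the meta order, with the cluster id first; masked entries
#' are written as the missing token. A completed dataset can carry its
#' imputation index as an extra column.
#'
#' @param ds A `multilevel_dataset` or completed dataset.
#' @param path Output file path.
#' @param missing_token Token written at masked cells.
#' @param imputation_column If `TRUE` and `ds` carries an imputation index,
#'   write it as a column named `imputation`.
#' @export
write_dataset <- function(ds, path, missing_token = "NA",
                          imputation_column = FALSE) {
  df <- as.data.frame(ds)
  if (imputation_column && !is.null(attr(ds, "imputation")))
    df$imputation <- attr(ds, "imputation")
  utils::write.csv(df, path, row.names = FALSE, na = missing_token)
  invisible(NULL)
}

#' Per-variable and per-row missingness summary
#'
#' @param ds A `multilevel_dataset`.
#' @return A list with `variables` (data frame of per-variable missing
#'   fractions) and `incomplete_rows`, the share of rows with at least one
#'   masked covariate or auxiliary entry.
#' @export
missingness_summary <- function(ds) {
  stopifnot(inherits(ds, "multilevel_dataset"))
  frac <- colMeans(!ds$mask)
  vars <- data.frame(name = ds$meta$name, level = ds$meta$level,
                     role = ds$meta$role, missing_fraction = unname(frac),
                     stringsAsFactors = FALSE)
  target <- ds$meta$role %in% c("covariate", "auxiliary")
  inc <- if (any(target)) {
    mean(rowSums(!ds$mask[, target, drop = FALSE]) > 0)
  } else 0
  list(variables = vars, incomplete_rows = inc)
}

# mark a dataset as completed imputation m (mask all TRUE)
as_completed <- function(ds, values, m) {
  out <- ds
  out$data <- values
  colnames(out$data) <- ds$meta$name
  out$mask <- matrix(TRUE, nrow(values), ncol(values),
                     dimnames = dimnames(ds$mask))
  attr(out, "imputation") <- m
  class(out) <- c("completed_dataset", "multilevel_dataset")
  out
}

#' Write variable metadata as a YAML sidecar
#' @param meta Metadata data frame.
#' @param path Output path.
#' @export
write_meta <- function(meta, path) {
  meta <- validate_meta(meta)
  recs <- lapply(seq_len(nrow(meta)), function(i)
    list(name = meta$name[i], level = as.integer(meta$level[i]),
         vtype = meta$vtype[i], role = meta$role[i]))
  yaml::write_yaml(list(variables = recs), path)
  invisible(NULL)
}

#' Read variable metadata from a YAML sidecar
#' @param path YAML file written by [write_meta()] (or hand-authored in the
#'   same shape).
#' @return Metadata data frame.
#' @export
read_meta <- function(path) {
  y <- yaml::read_yaml(path)
  recs <- y$variables
  meta <- do.call(rbind, lapply(recs, function(r)
    variable_meta(r$name, r$level, r$vtype, r$role)))
  validate_meta(meta)
}

#' Check that imputations preserve observed cells
#'
#' Shared invariant: every completed dataset must agree with the source on
#' all observed cells.
#'
#' @param result An [imputation_result].
#' @param ds The source dataset.
#' @return `TRUE` if all observed cells are bit-identical in every completed
#'   dataset, else `FALSE`.
#' @export
imputation_preserves_observed <- function(result, ds) {
  all(vapply(result$imputations, function(cd)
    identical(cd$data[ds$mask], ds$data[ds$mask]), logical(1)))
}
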