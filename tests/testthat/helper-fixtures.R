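# fixtures built in code: a small two-level dataset with one binary and one
# continuous level-1 covariate, and simulators used across test files

toy_meta <- function(extra = NULL) {
  m <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
             variable_meta("y", 1, "continuous", "outcome"),
             variable_meta("PAR", 1, "binary", "covariate"),
             variable_meta("age", 1, "continuous", "covariate"))
  if (!is.null(extra)) m <- rbind(m, extra)
  m
}

make_toy_ds <- function(J = 8, nj = 12, miss = 0.2, seed = 42) {
  set.seed(seed)
  n <- J * nj
  cl <- rep(seq_len(J), each = nj)
  u <- rnorm(J, 0, 0.3)
  PAR <- rbinom(n, 1, 0.6)
  age <- rnorm(n)
  y <- 0.3 + 0.5 * PAR - 0.1 * age + u[cl] + rnorm(n, 0, 0.4)
  df <- data.frame(cl = cl, y = y, PAR = PAR, age = age)
  if (miss > 0) {
    df$PAR[runif(n) < miss] <- NA
    df$age[runif(n) < miss] <- NA
  }
  multilevel_dataset(df, toy_meta())
}

# data simulated exactly from the homoscedastic latent-normal joint model
make_jm_sim <- function(J = 30, nj = 15, alpha = c(0.2, 0.5, -0.1),
                        Om1 = matrix(c(0.05, 0.04, 0.02,
                                       0.04, 1.00, 0.30,
                                       0.02, 0.30, 0.90), 3, 3),
                        Om2 = diag(c(0.01, 0.15, 0.10)),
                        binary_par = TRUE, seed = 1) {
  set.seed(seed)
  n <- J * nj
  cl <- rep(seq_len(J), each = nj)
  U <- matrix(rnorm(J * 3), J) %*% chol(Om2)
  E <- matrix(rnorm(n * 3), n) %*% chol(Om1)
  Z <- sweep(U[cl, ] + E, 2, alpha, `+`)
  df <- data.frame(cl = cl, y = Z[, 1],
                   PAR = if (binary_par) as.numeric(Z[, 2] >= 0) else Z[, 2],
                   age = Z[, 3])
  meta <- rbind(variable_meta("cl", 2, "continuous", "cluster_id"),
                variable_meta("y", 1, "continuous", "outcome"),
                variable_meta("PAR", 1,
                              if (binary_par) "binary" else "continuous",
                              "covariate"),
                variable_meta("age", 1, "continuous", "covariate"))
  list(df = df, meta = meta, alpha = alpha, Om1 = Om1, Om2 = Om2)
}

mcar_mask <- function(df, vars, rate, seed = 2) {
  set.seed(seed)
  for (v in vars) df[[v]][runif(nrow(df)) < rate] <- NA
  df
}

# positive definiteness
is_pd <- function(S, tol = 1e-10) {
  all(eigen((S + t(S)) / 2, only.values = TRUE)$values > tol)
}

# extract a named covariance matrix from a chains row
tri_from_chain <- function(chains, iter, prefix, vars) {
  p <- length(vars)
  M <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(i)) {
    v <- chains[iter, paste0(prefix, "[", vars[i], ",", vars[j], "]")]
    M[i, j] <- M[j, i] <- v
  }
  M
}
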