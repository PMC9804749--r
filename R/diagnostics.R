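#' Summarise MCMC chains
#'
#' Per-parameter mean, standard deviation, lag-1 autocorrelation and the
#' split-chain ratio (potential scale reduction computed on the two halves
#' of each chain; values near 1 indicate stationarity). Constant chains are
#' flagged degenerate — expected for constrained parameters such as a
#' latent-binary diagonal, suspicious otherwise. Registering imputations
#' should wait until the sampler has converged; for SMC-JM the substantive
#' -model parameters are the ones to watch first.
#'
#' @param chains Matrix with one column per parameter (e.g.
#'   `result$chains`).
#' @return Data frame with one row per parameter.
#' @export
mcmc_diagnostics <- function(chains) {
  chains <- as.matrix(chains)
  if (nrow(chains) < 4L) stop("chains too short to summarise", call. = FALSE)
  nm <- colnames(chains)
  if (is.null(nm)) nm <- paste0("param", seq_len(ncol(chains)))
  out <- lapply(seq_len(ncol(chains)), function(k) {
    x <- chains[, k]
    s <- stats::sd(x)
    degenerate <- !is.finite(s) || s < 1e-12
    lag1 <- if (degenerate) NA_real_ else
      stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
    split <- if (degenerate) NA_real_ else split_chain_ratio(x)
    data.frame(parameter = nm[k], mean = mean(x), sd = s,
               lag1_autocorr = lag1, split_ratio = split,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# split-Rhat on two halves of a single chain
split_chain_ratio <- function(x) {
  n <- length(x)
  h <- floor(n / 2)
  a <- x[seq_len(h)]
  b <- x[(n - h + 1):n]
  W <- (stats::var(a) + stats::var(b)) / 2
  if (W < 1e-300) return(NA_real_)
  mu <- c(mean(a), mean(b))
  B <- h * stats::var(mu)
  sqrt(((h - 1) / h * W + B / h) / W)
}
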