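# Split-R-hat and effective sample size, computed from a draws-by-chain
# matrix. Classic formulas (split chains, Geyer initial-positive-sequence
# truncation for the autocorrelation sum).

split_chains <- function(x, chain_ids) {
  chains <- split(x, chain_ids)
  out <- list()
  for (ch in chains) {
    n <- length(ch)
    h <- n %/% 2L
    out[[length(out) + 1L]] <- ch[seq_len(h)]
    out[[length(out) + 1L]] <- ch[(n - h + 1L):n]
  }
  len <- min(lengths(out))
  lapply(out, function(v) v[seq_len(len)])
}

split_rhat <- function(x, chain_ids) {
  sc <- split_chains(x, chain_ids)
  n <- length(sc[[1L]])
  if (n < 4L) return(NA_real_)
  means <- vapply(sc, mean, numeric(1))
  vars <- vapply(sc, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_bulk <- function(x, chain_ids) {
  sc <- split_chains(x, chain_ids)
  n <- length(sc[[1L]])
  m <- length(sc)
  if (n < 8L) return(NA_real_)
  lag_max <- min(n - 2L, 200L)
  acov <- vapply(sc, function(ch)
    as.numeric(stats::acf(ch, lag.max = lag_max, type = "covariance",
                          plot = FALSE, demean = TRUE)$acf),
    numeric(lag_max + 1L))
  vars <- acov[1L, ] * n / (n - 1)
  W <- mean(vars)
  means <- vapply(sc, mean, numeric(1))
  var_plus <- (n - 1) / n * W + stats::var(means)
  if (var_plus <= 0) return(n * m)
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] == 1 (lag 0)
  # Geyer initial positive sequence on paired sums
  tau <- 0
  t <- 2L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)  # initial monotone adjustment
    tau <- tau + pair
    prev_pair <- pair
    t <- t + 2L
  }
  ess <- n * m / (1 + 2 * tau)
  min(ess, n * m * log10(n * m))
}

diagnose_draws <- function(mat, chain_ids) {
  data.frame(
    param = colnames(mat),
    rhat = apply(mat, 2L, split_rhat, chain_ids = chain_ids),
    ess = apply(mat, 2L, ess_bulk, chain_ids = chain_ids),
    row.names = NULL
  )
}
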