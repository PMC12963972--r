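# Shared fixtures, all generated in code.

tiny_schema <- function(k = 8L) {
  channel_schema("CUSTOM", labels = paste0("ch", seq_len(k)))
}

sbs96 <- channel_schema("SBS96")

# Independent R-side oracle for the truncated COM-Poisson log-pmf with the
# asymptotic rate mapping: plain log-sum-exp over 0..upper.
cmp_logpmf_oracle <- function(y, mu, nu, upper) {
  loglam <- nu * log(mu + (nu - 1) / (2 * nu))
  t <- (0:upper) * loglam - nu * lgamma((0:upper) + 1)
  M <- max(t)
  logZ <- M + log(sum(exp(t - M)))
  y * loglam - nu * lgamma(y + 1) - logZ
}

# A small mixed sample plus its generating truth.
make_mixture <- function(seed = 1, burden = 2000, fe = 0.5,
                         schema = sbs96, max_cosine = 0.3) {
  pair <- random_signature_pair(schema, seed, max_cosine = max_cosine)
  sim <- simulate_sample(schema, burden, pair$background, pair$exposure,
                         theta_split = c(1 - fe, fe), seed = seed)
  list(profile = sim$profile, truth = sim$truth,
       background = pair$background, exposure = pair$exposure)
}

fast_mcmc <- function(seed = 1, chains = 2L, warmup = 300L, sampling = 400L) {
  mcmc_config(chains = chains, warmup = warmup, sampling = sampling,
              seed = seed)
}
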