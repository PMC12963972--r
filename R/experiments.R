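# Synthetic robustness experiments: run-to-run stability, prior
# sensitivity, reconstruction fidelity, null safety, and parameter
# recovery. Each experiment builds its own seeded synthetic data and runs
# the full Bayesian rescue, so results are reproducible end to end from a
# single seed.

experiment_mcmc <- function(seed, chains, warmup, sampling) {
  mcmc_config(chains = chains, warmup = warmup, sampling = sampling,
              seed = seed)
}

#' Run-to-run stability experiment
#'
#' One fixed synthetic SBS96 sample (equal background/exposure mixture of a
#' well-separated seeded signature pair) is rescued `n_runs` times with
#' distinct sampler seeds; reports the spread (max minus min) of the
#' posterior-median exposure activity and the minimum pairwise cosine
#' similarity among the inferred exposure signatures.
#'
#' @param n_runs Number of independent inference runs (default 20).
#' @param burden Sample burden (default 2000).
#' @param seed Master seed for data generation; run seeds are
#'   `(seed-1)*n_runs + 1 .. (seed-1)*n_runs + n_runs`.
#' @param model A [model_config()].
#' @param chains,warmup,sampling MCMC effort per run.
#' @return List with `activity_spread`, `min_pairwise_cosine`,
#'   `theta_e_hat` (per run), `relative_exposure` (per run), and the
#'   simulated `sample`/`truth`.
#' @export
stability_experiment <- function(n_runs = 20, burden = 2000, seed = 1,
                                 model = model_config(), chains = 4,
                                 warmup = 500, sampling = 750) {
  sch <- channel_schema("SBS96")
  pair <- random_signature_pair(sch, seed)
  sim <- simulate_sample(sch, burden, pair$background, pair$exposure,
                         theta_split = c(0.5, 0.5), seed = seed)
  runs <- lapply(seq_len(n_runs), function(i)
    rescue(sim$profile, pair$background, model = model,
           mcmc = experiment_mcmc((seed - 1) * n_runs + i, chains, warmup,
                                  sampling)))
  theta_e <- vapply(runs, `[[`, numeric(1), "theta_e_hat")
  rel <- vapply(runs, function(r) r$relative_activities[["exposure"]],
                numeric(1))
  S <- vapply(runs, function(r) r$s_e_hat$proportions, numeric(sch$size))
  pc <- utils::combn(n_runs, 2, function(ij)
    cosine_similarity(S[, ij[1]], S[, ij[2]]))
  list(activity_spread = max(theta_e) - min(theta_e),
       min_pairwise_cosine = min(pc),
       theta_e_hat = theta_e, relative_exposure = rel,
       sample = sim$profile, truth = sim$truth)
}

#' Exposure-prior sensitivity experiment
#'
#' Rescues one fixed synthetic mixed sample once under each exposure-
#' activity prior preset (Gamma(1,10), Gamma(1,5), Gamma(1,2), Gamma(1,1))
#' with a fixed sampler seed, and reports the minimum pairwise cosine
#' similarity among the four inferred exposure signatures.
#'
#' @inheritParams stability_experiment
#' @return List with `min_pairwise_cosine`, per-preset `theta_e_hat`, and
#'   the `results` list.
#' @export
prior_sensitivity_experiment <- function(burden = 2000, seed = 1,
                                         chains = 4, warmup = 500,
                                         sampling = 750) {
  sch <- channel_schema("SBS96")
  pair <- random_signature_pair(sch, seed)
  sim <- simulate_sample(sch, burden, pair$background, pair$exposure,
                         theta_split = c(0.5, 0.5), seed = seed)
  presets <- theta_e_prior_presets()
  runs <- lapply(presets, function(p)
    rescue(sim$profile, pair$background,
           model = model_config(theta_e_prior = p),
           mcmc = experiment_mcmc(seed, chains, warmup, sampling)))
  S <- vapply(runs, function(r) r$s_e_hat$proportions, numeric(sch$size))
  pc <- utils::combn(length(runs), 2, function(ij)
    cosine_similarity(S[, ij[1]], S[, ij[2]]))
  list(min_pairwise_cosine = min(pc),
       theta_e_hat = vapply(runs, `[[`, numeric(1), "theta_e_hat"),
       results = runs)
}

#' Reconstruction-fidelity experiment
#'
#' Simulates equal mixtures of well-separated signature pairs at a given
#' burden, rescues each, and reports the cosine similarity between the
#' observed counts and the reconstruction at posterior-median parameters.
#'
#' @param n Number of samples (seeds `(seed-1)*n + 1..n`).
#' @inheritParams stability_experiment
#' @return List with `mean_cosine` and per-sample `fit_cosine`.
#' @export
reconstruction_experiment <- function(n = 5, burden = 2000, seed = 1,
                                      chains = 4, warmup = 500,
                                      sampling = 750) {
  sch <- channel_schema("SBS96")
  fits <- vapply(seq_len(n), function(i) {
    s <- (seed - 1) * n + i
    pair <- random_signature_pair(sch, s)
    sim <- simulate_sample(sch, burden, pair$background, pair$exposure,
                           theta_split = c(0.5, 0.5), seed = s)
    rescue(sim$profile, pair$background,
           mcmc = experiment_mcmc(s, chains, warmup, sampling))$fit_cosine
  }, numeric(1))
  list(mean_cosine = mean(fits), fit_cosine = fits)
}

#' Null-safety experiment
#'
#' Draws background-only multinomial samples (no exposure component) from
#' one seeded background signature and rescues them against that
#' background; a safe method attributes nearly all mutations to the
#' background. Reports the median relative exposure activity as a
#' percentage.
#'
#' @param n Number of samples (multinomial seeds `(seed-1)*n + 1..n`).
#' @inheritParams stability_experiment
#' @return List with `median_relative_exposure_pct` and per-sample values.
#' @export
null_safety_experiment <- function(n = 5, burden = 5000, seed = 1,
                                   chains = 4, warmup = 500,
                                   sampling = 750) {
  sch <- channel_schema("SBS96")
  bg <- random_signature(sch, chain_seed(seed, 0L), name = "background")
  rel <- vapply(seq_len(n), function(i) {
    s <- (seed - 1) * n + i
    sim <- simulate_sample(sch, burden, bg, bg, theta_split = c(1, 0),
                           seed = s, sample_id = paste0("null_", i))
    r <- rescue(sim$profile, bg,
                mcmc = experiment_mcmc(s, chains, warmup, sampling))
    r$relative_activities[["exposure"]]
  }, numeric(1))
  list(median_relative_exposure_pct = 100 * stats::median(rel),
       relative_exposure = rel)
}

#' Parameter-recovery experiment
#'
#' Simulates mixed samples from the generative model with known exposure
#' fractions (drawn uniformly from `fe_range`) and well-separated
#' signature pairs, rescues each, and scores recovery of the relative
#' exposure activity and of the exposure signature.
#'
#' @param n Number of simulations.
#' @param fe_range Range of true exposure fractions.
#' @inheritParams stability_experiment
#' @return List with `coverage` (fraction of runs whose 95% credible
#'   interval contains the true exposure fraction), `median_abs_error`,
#'   `median_cosine` (of the inferred vs true exposure signature), and a
#'   per-run `details` data frame.
#' @export
recovery_experiment <- function(n = 50, burden = 2000, seed = 1,
                                fe_range = c(0.3, 0.7), chains = 4,
                                warmup = 500, sampling = 750) {
  sch <- channel_schema("SBS96")
  rows <- lapply(seq_len(n), function(i) {
    s <- (seed - 1) * n + i
    pair <- random_signature_pair(sch, chain_seed(s, 1L))
    set.seed(chain_seed(s, 2L))
    fe <- stats::runif(1, fe_range[1], fe_range[2])
    sim <- simulate_sample(sch, burden, pair$background, pair$exposure,
                           theta_split = c(1 - fe, fe),
                           seed = chain_seed(s, 3L))
    r <- rescue(sim$profile, pair$background,
                mcmc = experiment_mcmc(s, chains, warmup, sampling))
    data.frame(
      fe_true = fe,
      fe_est = r$relative_activities[["exposure"]],
      covered = fe >= r$relative_credible["exposure", 1] &
        fe <= r$relative_credible["exposure", 2],
      cosine = cosine_similarity(r$s_e_hat$proportions,
                                 pair$exposure$proportions))
  })
  details <- do.call(rbind, rows)
  list(coverage = mean(details$covered),
       median_abs_error = stats::median(abs(details$fe_est -
                                              details$fe_true)),
       median_cosine = stats::median(details$cosine),
       details = details)
}
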