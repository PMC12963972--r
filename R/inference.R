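#' MCMC configuration
#'
#' Defaults: 4 chains, 1000 warmup iterations, 1500 sampling iterations per
#' chain; these can be reduced to trade estimation precision for runtime.
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup iterations per chain (default 1000).
#' @param sampling Post-warmup iterations per chain (default 1500).
#' @param seed Master seed; chain seeds are derived deterministically.
#' @param parallel_chains Unused placeholder for API symmetry; chains run
#'   serially so runs are bit-reproducible on any worker count.
#' @param max_parallel_samples Cap on concurrently processed samples in
#'   [rescue_many()] (default 20).
#' @param max_leapfrog Maximum leapfrog steps per HMC trajectory.
#' @param target_accept Dual-averaging target acceptance rate.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4L, warmup = 1000L, sampling = 1500L,
                        seed = 1L, parallel_chains = FALSE,
                        max_parallel_samples = 20L,
                        max_leapfrog = 32L, target_accept = 0.8) {
  stopifnot(chains >= 1, warmup >= 1, sampling >= 1,
            max_parallel_samples >= 1, max_leapfrog >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling), seed = as.integer(seed),
                 parallel_chains = parallel_chains,
                 max_parallel_samples = as.integer(max_parallel_samples),
                 max_leapfrog = as.integer(max_leapfrog),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Configure a baseline-correction run
#'
#' Validates and bundles the observed profile, background signatures,
#' model configuration and sampler settings into an immutable spec.
#' Count-scale background profiles are normalized to signatures; each
#' background gets its own activity parameter.
#'
#' @param observed A `mutation_profile` with positive burden.
#' @param backgrounds A background `mutation_profile`/`signature_vector` or
#'   list of them.
#' @param model A [model_config()].
#' @param mcmc An [mcmc_config()].
#' @return A `rescue_spec`.
#' @export
rescue_setup <- function(observed, backgrounds, model = model_config(),
                         mcmc = mcmc_config()) {
  data <- model_data(observed, backgrounds)
  y <- as.numeric(data$observed$counts)
  if (data$observed$weighted)
    stop("count likelihoods require an integer (unweighted) profile",
         call. = FALSE)
  B <- background_matrix(data)
  dp <- model$dispersion_prior
  dat <- list(
    y = y, N = data$observed$burden, B = B,
    upper = truncation_bound(y, model),
    p = smooth_proportions(y),
    ab = model$theta_b_prior$shape, bb = model$theta_b_prior$rate,
    ae = model$theta_e_prior$shape, be = model$theta_e_prior$rate,
    nu_mean = dp$mean, nu_sd = dp$sd, nu_lb = dp$lower_bound,
    rw = model$reward_weight, rt = model$reward_threshold,
    rh = model$reward_scale,
    dscale = model$dirichlet_scale, dfloor = model$conc_floor
  )
  structure(list(data = data, model = model, mcmc = mcmc, dat = dat,
                 n_backgrounds = ncol(B)),
            class = "rescue_spec")
}

#' @export
print.rescue_spec <- function(x, ...) {
  cat("<rescue_spec> sample ", x$data$observed$sample_id,
      " (", x$data$observed$schema$name, ", burden ",
      x$data$observed$burden, "), ", x$n_backgrounds, " background(s); ",
      x$mcmc$chains, " chains x (", x$mcmc$warmup, " + ", x$mcmc$sampling,
      ")\n", sep = "")
  invisible(x)
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 97 + chain * 1009) %% 2147483646 + 1)
}

init_unconstrained <- function(K, C) {
  c(log(0.5 / K) + 0.2 * stats::rnorm(K),
    log(0.2) + 0.2 * stats::rnorm(1),
    0.3 * stats::rnorm(C - 1),
    log(0.9) + 0.1 * stats::rnorm(1))
}

unconstrain_to_params <- function(u, K, C, nu_lb) {
  z <- c(u[(K + 2):(K + C)], 0)
  ez <- exp(z - max(z))
  list(theta_b = exp(u[seq_len(K)]), theta_e = exp(u[K + 1]),
       s_e = ez / sum(ez), nu = nu_lb + exp(u[K + C + 1]))
}

#' Draw from the model posterior
#'
#' Runs the configured number of HMC chains on the unconstrained
#' reparameterization (log activities, additive-log-ratio simplex for the
#' exposure signature, shifted-log dispersion) and returns constrained
#' posterior draws with convergence diagnostics. A warning is emitted when
#' any split-R-hat exceeds 1.05 or post-warmup divergences occur.
#'
#' @param spec A [rescue_setup()] spec.
#' @return A `posterior_draws` object: matrices `theta_b` (draws x
#'   backgrounds) and `s_e` (draws x channels; every row a simplex),
#'   vectors `theta_e`, `nu`, `lp`, `chain_ids`, and a `diagnostics` data
#'   frame with split-R-hat and effective sample sizes.
#' @export
rescue_run <- function(spec) {
  stopifnot(inherits(spec, "rescue_spec"))
  K <- spec$n_backgrounds
  C <- spec$data$observed$schema$size
  mc <- spec$mcmc
  nu_lb <- spec$model$dispersion_prior$lower_bound

  res <- vector("list", mc$chains)
  for (ch in seq_len(mc$chains)) {
    set.seed(chain_seed(mc$seed, ch))
    u0 <- init_unconstrained(K, C)
    res[[ch]] <- hmc_run_cpp(u0, mc$warmup, mc$sampling, spec$dat,
                             mc$max_leapfrog, mc$target_accept)
  }
  U <- do.call(rbind, lapply(res, `[[`, "draws"))
  lp <- unlist(lapply(res, `[[`, "lp"))
  chain_ids <- rep(seq_len(mc$chains), each = mc$sampling)

  theta_b <- exp(U[, seq_len(K), drop = FALSE])
  colnames(theta_b) <- paste0("theta_b[", seq_len(K), "]")
  theta_e <- exp(U[, K + 1])
  Z <- cbind(U[, (K + 2):(K + C), drop = FALSE], 0)
  EZ <- exp(Z - apply(Z, 1L, max))
  s_e <- EZ / rowSums(EZ)
  colnames(s_e) <- spec$data$observed$schema$labels
  nu <- nu_lb + exp(U[, K + C + 1])

  diag_mat <- cbind(theta_b, theta_b_total = rowSums(theta_b),
                    theta_e = theta_e, nu = nu, lp = lp)
  diagnostics <- diagnose_draws(diag_mat, chain_ids)
  divergences <- sum(vapply(res, `[[`, numeric(1), "divergences"))
  accept <- vapply(res, `[[`, numeric(1), "accept_rate")

  if (any(diagnostics$rhat > 1.05, na.rm = TRUE))
    warning("possible non-convergence: max split-R-hat = ",
            format(max(diagnostics$rhat, na.rm = TRUE), digits = 4),
            call. = FALSE)
  if (divergences > 0.01 * length(lp))
    warning(divergences, " divergent transitions after warmup; ",
            "posterior geometry may be poorly explored", call. = FALSE)

  structure(list(theta_b = theta_b, theta_e = theta_e, s_e = s_e, nu = nu,
                 lp = lp, chain_ids = chain_ids, diagnostics = diagnostics,
                 divergences = divergences, accept_rate = accept,
                 stepsize = vapply(res, `[[`, numeric(1), "stepsize")),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", length(x$theta_e), " draws from ",
      length(unique(x$chain_ids)), " chains; max R-hat ",
      format(max(x$diagnostics$rhat, na.rm = TRUE), digits = 4),
      ", divergences ", x$divergences, "\n", sep = "")
  invisible(x)
}

#' Summarize posterior draws into a rescue result
#'
#' Point estimates are posterior medians of the activities (the background
#' activity is the summed activity over background components). The
#' denoised exposure signature is the per-channel 2.5% posterior quantile
#' of `s_e`, renormalized to the simplex; the rescued (count-scale)
#' exposure profile is `burden * theta_e_hat * s_e_hat`.
#'
#' @param draws A [rescue_run()] result.
#' @param spec The matching [rescue_setup()] spec.
#' @param s_e_quantile Posterior quantile summarizing `s_e` (default 0.025,
#'   the lower bound of the 95% credible interval).
#' @return A `rescue_result`.
#' @export
rescue_analyze <- function(draws, spec, s_e_quantile = 0.025) {
  stopifnot(inherits(draws, "posterior_draws"), length(draws$theta_e) > 0)
  obs <- spec$data$observed
  B <- background_matrix(spec$data)

  tb_total <- rowSums(draws$theta_b)
  theta_b_hat <- stats::median(tb_total)
  theta_e_hat <- stats::median(draws$theta_e)
  theta_b_comp_hat <- apply(draws$theta_b, 2L, stats::median)
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  theta_credible <- rbind(background = ci(tb_total),
                          exposure = ci(draws$theta_e))
  colnames(theta_credible) <- c("2.5%", "97.5%")
  rel_e_draws <- draws$theta_e / (tb_total + draws$theta_e)
  relative_credible <- rbind(background = ci(1 - rel_e_draws),
                             exposure = ci(rel_e_draws))
  colnames(relative_credible) <- c("2.5%", "97.5%")

  q <- apply(draws$s_e, 2L, stats::quantile, probs = s_e_quantile,
             names = FALSE)
  s_e_hat <- signature_vector(paste0(obs$sample_id, "_exposure"),
                              q / sum(q), obs$schema)
  s_e_med <- apply(draws$s_e, 2L, stats::median)
  s_e_med <- s_e_med / sum(s_e_med)

  rescued <- obs$burden * theta_e_hat * s_e_hat$proportions
  reconstructed <- as.numeric(
    obs$burden * (B %*% theta_b_comp_hat + theta_e_hat * s_e_med))
  names(reconstructed) <- obs$schema$labels
  rel <- c(background = theta_b_hat, exposure = theta_e_hat) /
    (theta_b_hat + theta_e_hat)

  structure(list(
    sample_id = obs$sample_id,
    schema = obs$schema,
    observed = obs$counts,
    burden = obs$burden,
    theta_b_hat = theta_b_hat,
    theta_e_hat = theta_e_hat,
    theta_b_components = theta_b_comp_hat,
    theta_mean = c(background = mean(tb_total),
                   exposure = mean(draws$theta_e)),
    theta_credible = theta_credible,
    relative_credible = relative_credible,
    relative_activities = rel,
    nu_hat = stats::median(draws$nu),
    s_e_hat = s_e_hat,
    rescued_profile = rescued,
    reconstructed = reconstructed,
    fit_cosine = cosine_similarity(as.numeric(obs$counts), reconstructed),
    max_rhat = max(draws$diagnostics$rhat, na.rm = TRUE),
    divergences = draws$divergences
  ), class = "rescue_result")
}

#' @export
print.rescue_result <- function(x, ...) {
  cat("<rescue_result> ", x$sample_id, " (", x$schema$name, ", burden ",
      x$burden, ")\n", sep = "")
  cat(sprintf("  activities (posterior median): background %.3f, exposure %.3f\n",
              x$theta_b_hat, x$theta_e_hat))
  cat(sprintf("  relative: background %.1f%%, exposure %.1f%%\n",
              100 * x$relative_activities[["background"]],
              100 * x$relative_activities[["exposure"]]))
  cat(sprintf("  exposure 95%% CI [%.3f, %.3f]; fit cosine %.4f; max R-hat %.3f\n",
              x$theta_credible["exposure", 1], x$theta_credible["exposure", 2],
              x$fit_cosine, x$max_rhat))
  invisible(x)
}

#' One-call baseline correction
#'
#' Convenience wrapper: [rescue_setup()] then [rescue_run()] then
#' [rescue_analyze()].
#'
#' @inheritParams rescue_setup
#' @param return_draws If `TRUE`, attach the full `posterior_draws` as
#'   `$draws` on the result.
#' @return A `rescue_result`.
#' @export
rescue <- function(observed, backgrounds, model = model_config(),
                   mcmc = mcmc_config(), return_draws = FALSE) {
  spec <- rescue_setup(observed, backgrounds, model, mcmc)
  draws <- rescue_run(spec)
  res <- rescue_analyze(draws, spec)
  if (return_draws) res$draws <- draws
  res
}

#' Batch baseline correction over many samples
#'
#' Processes samples with deterministically derived per-sample seeds;
#' results are identical whether samples are processed serially or in
#' parallel. Individual sample failures are collected and reported
#' without aborting the batch.
#'
#' @param samples List of `mutation_profile`s.
#' @param backgrounds Backgrounds passed to [rescue_setup()].
#' @param model A [model_config()].
#' @param mcmc An [mcmc_config()]; its `seed` is the batch master seed.
#' @param parallel Process samples with [parallel::mclapply()] (capped at
#'   `mcmc$max_parallel_samples` workers).
#' @return List with `results` (per successful sample) and `errors`
#'   (named condition messages for failed samples).
#' @export
rescue_many <- function(samples, backgrounds, model = model_config(),
                        mcmc = mcmc_config(), parallel = FALSE) {
  if (length(samples) == 0L) stop("no samples supplied", call. = FALSE)
  one <- function(i) {
    mci <- mcmc
    mci$seed <- chain_seed(mcmc$seed, i * 7919L)
    tryCatch(list(ok = TRUE, value = rescue(samples[[i]], backgrounds,
                                            model, mci)),
             error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  }
  idx <- seq_along(samples)
  out <- if (parallel) {
    cores <- min(mcmc$max_parallel_samples,
                 max(1L, parallel::detectCores(logical = FALSE)))
    parallel::mclapply(idx, one, mc.cores = cores)
  } else {
    lapply(idx, one)
  }
  ok <- vapply(out, `[[`, logical(1), "ok")
  errors <- setNames(lapply(out[!ok], `[[`, "value"),
                     vapply(samples[!ok], `[[`, character(1), "sample_id"))
  if (length(errors))
    warning(length(errors), " sample(s) failed: ",
            paste(names(errors), collapse = ", "), call. = FALSE)
  list(results = setNames(lapply(out[ok], `[[`, "value"),
                          vapply(samples[ok], `[[`, character(1), "sample_id")),
       errors = errors)
}

#' Consensus rescued signature across samples
#'
#' TMB-weighted average of the rescued (count-scale) exposure profiles —
#' weights `w_i = TMB_i / sum(TMB)` from each sample's original burden —
#' normalized to a signature vector.
#'
#' @param results List of `rescue_result`s on one schema.
#' @param name Name of the consensus signature.
#' @return A `signature_vector`.
#' @export
consensus_signature <- function(results, name = "consensus") {
  if (length(results) == 0L) stop("no results supplied", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "rescue_result")))
  sch <- results[[1L]]$schema
  for (r in results[-1L])
    if (!schemas_identical(sch, r$schema)) stop_schema_mismatch(sch, r$schema)
  tmb <- vapply(results, `[[`, numeric(1), "burden")
  w <- tmb / sum(tmb)
  avg <- Reduce(`+`, Map(function(r, wi) wi * r$rescued_profile, results, w))
  signature_vector(name, avg / sum(avg), sch)
}
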