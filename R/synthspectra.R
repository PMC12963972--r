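#' Seeded random signature on the simplex
#'
#' A Dirichlet(concentration, ..., concentration) draw over the schema's
#' channels; deterministic given the seed. Large concentrations approach
#' the uniform signature `1/K`.
#'
#' @param schema A [channel_schema()].
#' @param seed Integer seed.
#' @param concentration Positive symmetric Dirichlet concentration
#'   (default 1: uniform on the simplex).
#' @param name Signature name.
#' @return A `signature_vector`.
#' @export
random_signature <- function(schema, seed, concentration = 1,
                             name = paste0("random_", seed)) {
  stopifnot(concentration > 0)
  set.seed(as.integer(seed))
  g <- stats::rgamma(schema$size, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, schema$size)
  signature_vector(name, g / sum(g), schema)
}

#' Seeded pair of well-separated random signatures
#'
#' Draws a background/exposure pair of Dirichlet signatures and
#' rejection-samples until their cosine similarity falls below
#' `max_cosine`; used to build simulation scenarios where the two
#' mutational processes are distinguishable. Deterministic given the seed.
#'
#' @param schema A [channel_schema()].
#' @param seed Integer seed.
#' @param max_cosine Upper bound on the pair's cosine similarity
#'   (default 0.3).
#' @param concentration Symmetric Dirichlet concentration of each draw.
#' @param max_tries Rejection-sampling attempts before erroring.
#' @return List with `background` and `exposure` `signature_vector`s.
#' @export
random_signature_pair <- function(schema, seed, max_cosine = 0.3,
                                  concentration = 1, max_tries = 200000L) {
  for (try in seq_len(max_tries)) {
    sb <- random_signature(schema, chain_seed(seed, 2L * try - 1L),
                           concentration, name = "background")
    se <- random_signature(schema, chain_seed(seed, 2L * try),
                           concentration, name = "exposure")
    if (cosine_similarity(sb$proportions, se$proportions) < max_cosine)
      return(list(background = sb, exposure = se))
  }
  stop("no signature pair with cosine < ", max_cosine, " found in ",
       max_tries, " tries", call. = FALSE)
}

#' Simulate a mixed background/exposure sample
#'
#' Generative mirror of the reconstruction equation: the expected profile
#' is `burden * (f_b * s_b + f_e * s_e)`; counts are a multinomial draw at
#' those proportions (`noise = "multinomial"`) or a deterministic
#' largest-remainder rounding (`noise = "none"`).
#'
#' @param schema A [channel_schema()].
#' @param burden Total mutation count.
#' @param background_sig,exposure_sig `signature_vector`s on `schema`.
#' @param theta_split Length-2 fractions `(background, exposure)` summing
#'   to 1.
#' @param noise `"multinomial"` or `"none"`.
#' @param seed Integer seed.
#' @param sample_id Sample name.
#' @return List with `profile` (a `mutation_profile`) and `truth` (a list
#'   with `f_b`, `f_e`, `s_b`, `s_e`, `expected`).
#' @export
simulate_sample <- function(schema, burden, background_sig, exposure_sig,
                            theta_split = c(0.5, 0.5),
                            noise = c("multinomial", "none"),
                            seed = 1L, sample_id = paste0("sim_", seed)) {
  noise <- match.arg(noise)
  stopifnot(burden > 0, length(theta_split) == 2L,
            all(theta_split >= 0), abs(sum(theta_split) - 1) < 1e-9)
  p <- theta_split[1] * background_sig$proportions +
       theta_split[2] * exposure_sig$proportions
  expected <- burden * p
  counts <- if (noise == "multinomial") {
    set.seed(as.integer(seed))
    as.numeric(stats::rmultinom(1L, size = burden, prob = p))
  } else {
    apportion_counts(burden, p)
  }
  list(profile = mutation_profile(sample_id, counts, schema),
       truth = list(f_b = theta_split[1], f_e = theta_split[2],
                    s_b = background_sig, s_e = exposure_sig,
                    expected = expected))
}

# Deterministic largest-remainder apportionment of n over proportions p.
apportion_counts <- function(n, p) {
  p <- p / sum(p)
  q <- n * p
  fl <- floor(q)
  rem <- as.integer(round(n - sum(fl)))
  if (rem > 0) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

#' Inject a signature into a profile at a fractional level
#'
#' The number of injected mutations is the burden times the ratio of
#' injected to original level: `n = round(burden * level / (1 - level))`,
#' so that post-injection the injected mutations make up approximately
#' `level` of the new total. Counts are distributed over channels
#' proportionally to the normalized injected signature, by deterministic
#' largest-remainder rounding (default) or a seeded multinomial draw.
#'
#' @param profile A `mutation_profile`.
#' @param signature The `signature_vector` to inject.
#' @param level Injection level in (0, 1).
#' @param mode `"deterministic"` or `"multinomial"`.
#' @param seed Seed for `mode = "multinomial"`.
#' @return List with `profile` (post-injection) and `injected` (per-channel
#'   injected counts; `sum(injected)` equals `n` exactly).
#' @export
inject_signature <- function(profile, signature, level,
                             mode = c("deterministic", "multinomial"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "mutation_profile"),
            inherits(signature, "signature_vector"))
  if (!schemas_identical(profile$schema, signature$schema))
    stop_schema_mismatch(profile$schema, signature$schema)
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("injection level must lie strictly between 0 and 1", call. = FALSE)
  n_inject <- round(profile$burden * level / (1 - level))
  injected <- if (mode == "deterministic") {
    apportion_counts(n_inject, signature$proportions)
  } else {
    set.seed(as.integer(seed))
    as.numeric(stats::rmultinom(1L, size = n_inject,
                                prob = signature$proportions))
  }
  names(injected) <- profile$schema$labels
  out <- mutation_profile(paste0(profile$sample_id, "_inj"),
                          profile$counts + injected, profile$schema)
  list(profile = out, injected = injected, level = level,
       n_injected = n_inject)
}

#' Build a synthetic injection cohort
#'
#' Emulates the injection benchmark: `n` base profiles are drawn from
#' seeded random signatures constrained (by rejection sampling) to cosine
#' similarity below `max_cosine` with the injected signature, then each is
#' injected at a level drawn uniformly from `level_range` (default 5%-95%).
#' All randomness derives from `master_seed` via counter substreams.
#'
#' @param n Number of samples.
#' @param burden_range Length-2 integer range of base burdens.
#' @param signature The `signature_vector` to inject.
#' @param level_range Injection-level range (default `c(0.05, 0.95)`).
#' @param master_seed Integer master seed.
#' @param max_cosine Rejection threshold on base-signature similarity to
#'   the injected signature (default 0.3).
#' @param max_tries Rejection-sampling attempts per sample.
#' @return List of per-sample lists: `profile` (post-injection), `base`
#'   (pre-injection profile), `injected`, `level`, `n_injected`,
#'   `base_signature`.
#' @export
make_injection_cohort <- function(n, burden_range, signature,
                                  level_range = c(0.05, 0.95),
                                  master_seed = 1L, max_cosine = 0.3,
                                  max_tries = 200000L) {
  stopifnot(n >= 1, length(burden_range) == 2L,
            level_range[1] > 0, level_range[2] < 1,
            level_range[1] <= level_range[2])
  sch <- signature$schema
  lapply(seq_len(n), function(i) {
    sub <- chain_seed(master_seed, i)
    sig <- NULL
    for (try in seq_len(max_tries)) {
      cand <- random_signature(sch, chain_seed(sub, try),
                               name = paste0("base_", i))
      if (cosine_similarity(cand$proportions, signature$proportions) <
          max_cosine) { sig <- cand; break }
    }
    if (is.null(sig))
      stop("rejection sampling failed to find a base signature with cosine < ",
           max_cosine, " after ", max_tries, " tries", call. = FALSE)
    set.seed(chain_seed(sub, 0L))
    burden <- sample(burden_range[1]:burden_range[2], 1L)
    level <- stats::runif(1L, level_range[1], level_range[2])
    base_counts <- as.numeric(stats::rmultinom(1L, burden, sig$proportions))
    base <- mutation_profile(paste0("sample_", i), base_counts, sch)
    inj <- inject_signature(base, signature, level)
    list(profile = inj$profile, base = base, injected = inj$injected,
         level = level, n_injected = inj$n_injected, base_signature = sig)
  })
}
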