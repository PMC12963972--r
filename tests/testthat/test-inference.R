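test_that("setup validates inputs and normalizes count backgrounds", {
  sch <- tiny_schema(6)
  set.seed(1)
  obs <- mutation_profile("o", rpois(6, 40) + 1, sch)
  bg_counts <- mutation_profile("b", rpois(6, 40) + 1, sch)
  spec <- rescue_setup(obs, bg_counts, mcmc = fast_mcmc())
  expect_s3_class(spec$data$backgrounds[[1]], "signature_vector")
  expect_identical(spec$n_backgrounds, 1L)

  spec3 <- rescue_setup(obs, list(bg_counts, normalize(bg_counts),
                                  random_signature(sch, 2)),
                        mcmc = fast_mcmc())
  expect_identical(spec3$n_backgrounds, 3L)

  expect_error(rescue_setup(obs, list()), "at least one background")
  expect_error(rescue_setup(mutation_profile("z", rep(0, 6), sch), bg_counts),
               "zero burden")
  expect_error(rescue_setup(obs, random_signature(tiny_schema(5), 1)),
               "schema mismatch")
})

test_that("runs are deterministic under a fixed seed", {
  sch <- tiny_schema(8)
  sb <- random_signature(sch, 11)
  se <- random_signature(sch, 12)
  sim <- simulate_sample(sch, 500, sb, se, seed = 13)
  r1 <- rescue(sim$profile, sb, mcmc = fast_mcmc(seed = 7))
  r2 <- rescue(sim$profile, sb, mcmc = fast_mcmc(seed = 7))
  expect_identical(r1$theta_e_hat, r2$theta_e_hat)
  expect_identical(r1$s_e_hat$proportions, r2$s_e_hat$proportions)
  expect_identical(r1$theta_credible, r2$theta_credible)
})

test_that("posterior draws carry simplex signatures and positive activities", {
  sch <- tiny_schema(8)
  sb <- random_signature(sch, 11)
  sim <- simulate_sample(sch, 500, sb, random_signature(sch, 12), seed = 13)
  spec <- rescue_setup(sim$profile, sb, mcmc = fast_mcmc(seed = 1))
  draws <- rescue_run(spec)
  expect_equal(nrow(draws$s_e),
               spec$mcmc$chains * spec$mcmc$sampling)
  expect_true(all(abs(rowSums(draws$s_e) - 1) < 1e-8))
  expect_true(all(draws$theta_b > 0) && all(draws$theta_e > 0))
  expect_true(all(draws$nu > spec$model$dispersion_prior$lower_bound))
  expect_true(all(c("rhat", "ess") %in% names(draws$diagnostics)))
})

test_that("a degenerate point-mass posterior is summarized exactly", {
  sch <- tiny_schema(5)
  set.seed(2)
  obs <- mutation_profile("o", rpois(5, 50) + 1, sch)
  spec <- rescue_setup(obs, normalize(obs), mcmc = fast_mcmc())
  se <- random_signature(sch, 3)$proportions
  n <- 40
  draws <- structure(list(
    theta_b = matrix(0.6, n, 1), theta_e = rep(0.4, n),
    s_e = matrix(se, n, 5, byrow = TRUE), nu = rep(2, n),
    lp = rep(-1, n), chain_ids = rep(1:2, each = n / 2),
    diagnostics = data.frame(param = "theta_e", rhat = 1, ess = n),
    divergences = 0L), class = "posterior_draws")
  res <- rescue_analyze(draws, spec)
  expect_equal(unname(res$s_e_hat$proportions), unname(se), tolerance = 1e-12)
  expect_equal(sum(res$rescued_profile), obs$burden * 0.4, tolerance = 1e-9)
  expect_equal(sum(res$relative_activities), 1)
  expect_equal(unname(res$relative_activities), c(0.6, 0.4))
})

test_that("rescued totals track burden times exposure activity", {
  sch <- tiny_schema(10)
  sb <- random_signature(sch, 21)
  sim <- simulate_sample(sch, 800, sb, random_signature(sch, 22), seed = 23)
  res <- rescue(sim$profile, sb, mcmc = fast_mcmc(seed = 5))
  expect_equal(sum(res$rescued_profile),
               res$burden * res$theta_e_hat, tolerance = 1e-6)
  expect_equal(sum(res$relative_activities), 1)
  expect_gt(res$fit_cosine, 0.95)
})

test_that("an equal mixture at the reported activity split is recovered", {
  mix <- make_mixture(seed = 2, burden = 2000, fe = 0.474)
  res <- rescue(mix$profile, mix$background,
                mcmc = mcmc_config(chains = 2, warmup = 400, sampling = 500,
                                   seed = 2))
  expect_lt(abs(res$relative_activities[["exposure"]] - 0.474), 0.1)
  expect_lt(abs(res$relative_activities[["background"]] - 0.526), 0.1)
  expect_gt(cosine_similarity(res$s_e_hat$proportions,
                              mix$exposure$proportions), 0.9)
})

test_that("consensus signatures are TMB-weighted blends of rescued profiles", {
  sch <- tiny_schema(4)
  mk <- function(id, burden, rescued) {
    structure(list(sample_id = id, schema = sch, burden = burden,
                   rescued_profile = rescued),
              class = "rescue_result")
  }
  r1 <- mk("a", 100, c(10, 0, 0, 0))
  r2 <- mk("b", 300, c(0, 30, 0, 0))
  cons <- consensus_signature(list(r1, r2))
  manual <- 0.25 * c(10, 0, 0, 0) + 0.75 * c(0, 30, 0, 0)
  expect_equal(unname(cons$proportions), manual / sum(manual))

  single <- consensus_signature(list(r1))
  expect_equal(unname(single$proportions), c(1, 0, 0, 0))
  both <- consensus_signature(list(r2, r2))
  expect_equal(unname(both$proportions), c(0, 1, 0, 0))
  expect_error(consensus_signature(list()), "no results")
})

test_that("batch rescue isolates failures and matches serial per-sample seeds", {
  sch <- tiny_schema(6)
  sb <- random_signature(sch, 31)
  good1 <- simulate_sample(sch, 400, sb, random_signature(sch, 32),
                           seed = 33, sample_id = "g1")$profile
  good2 <- simulate_sample(sch, 400, sb, random_signature(sch, 34),
                           seed = 35, sample_id = "g2")$profile
  bad <- mutation_profile("empty", rep(0, 6), sch)
  mc <- fast_mcmc(seed = 9, warmup = 200L, sampling = 200L)
  out <- NULL
  w <- capture_warnings(out <- rescue_many(list(good1, bad, good2), sb,
                                           mcmc = mc))
  expect_true(any(grepl("failed", w)))
  expect_named(out$results, c("g1", "g2"))
  expect_named(out$errors, "empty")
  expect_match(out$errors[["empty"]], "zero burden")

  # serial rerun with the same master seed reproduces the batch exactly
  out2 <- suppressWarnings(rescue_many(list(good1, bad, good2), sb,
                                       mcmc = mc))
  expect_identical(out$results$g1$theta_e_hat, out2$results$g1$theta_e_hat)
  expect_identical(out$results$g2$s_e_hat$proportions,
                   out2$results$g2$s_e_hat$proportions)
})

test_that("result exports produce well-formed TSV tables", {
  sch <- tiny_schema(6)
  sb <- random_signature(sch, 41)
  sim <- simulate_sample(sch, 400, sb, random_signature(sch, 42), seed = 43)
  res <- suppressWarnings(
    rescue(sim$profile, sb, mcmc = fast_mcmc(seed = 3, warmup = 200L,
                                             sampling = 200L),
           return_draws = TRUE))
  pth <- withr::local_tempfile(fileext = ".tsv")
  write_rescue_profile(res, pth)
  tab <- utils::read.delim(pth)
  expect_identical(names(tab), c("channel", "observed", "background",
                                 "exposure"))
  expect_equal(tab$background + tab$exposure, as.numeric(res$reconstructed))

  summ <- write_activity_summary(res)
  expect_identical(summ$sample, sim$profile$sample_id)
  expect_true(all(c("theta_b", "theta_e", "fit_cosine", "max_rhat")
                  %in% names(summ)))

  dpth <- withr::local_tempfile(fileext = ".tsv")
  write_draws(res$draws, dpth)
  dtab <- utils::read.delim(dpth, check.names = FALSE)
  expect_equal(nrow(dtab), length(res$draws$theta_e))
})
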