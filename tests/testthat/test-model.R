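test_that("truncation bound follows y + ceil(6*sqrt(y)) + 10", {
  expect_identical(truncation_bound(0L), 10L)
  expect_identical(truncation_bound(25L), 65L)
  expect_identical(truncation_bound(100L), 170L)
  expect_identical(truncation_bound(c(0L, 7L)), c(10L, 7L + 16L + 10L))
})

test_that("COM-Poisson at nu = 1 is the truncated Poisson", {
  for (mu in c(0.5, 3, 20, 150)) {
    up <- truncation_bound(ceiling(mu) + 20L)
    y <- 0:min(up, 60)
    ours <- com_poisson_logpmf(y, rep(mu, length(y)), 1, rep(up, length(y)))
    ref <- dpois(y, mu, log = TRUE) - ppois(up, mu, log.p = TRUE)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("truncated COM-Poisson pmf sums to one over its support", {
  for (nu in c(1, 1.1, 2, 3.5)) {
    for (mu in c(1, 12, 80)) {
      up <- truncation_bound(ceiling(mu))
      tot <- sum(exp(com_poisson_logpmf(0:up, rep(mu, up + 1), nu,
                                        rep(up, up + 1))))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("adaptive truncation matches a 10x longer sum and the R oracle", {
  cases <- expand.grid(y = c(5L, 50L, 500L), nu = c(1.1, 2, 3))
  for (i in seq_len(nrow(cases))) {
    y <- cases$y[i]; nu <- cases$nu[i]
    mu <- 0.8 * y + 0.1
    up <- truncation_bound(y)
    short <- com_poisson_logpmf(y, mu, nu, up)
    long <- com_poisson_logpmf(y, mu, nu, 10L * up)
    expect_lt(abs(short - long) / abs(long), 1e-8)
    expect_equal(short, cmp_logpmf_oracle(y, mu, nu, up), tolerance = 1e-9)
  }
})

test_that("the mean-constrained rate solve reproduces mu as the truncated mean", {
  for (nu in c(1.3, 2)) {
    for (mu in c(4, 40)) {
      up <- truncation_bound(ceiling(mu))
      lam <- com_poisson_lambda(mu, nu, up, method = "solve")
      j <- 0:up
      w <- exp(j * log(lam) - nu * lgamma(j + 1))
      expect_equal(sum(j * w) / sum(w), mu, tolerance = 1e-6)
    }
  }
})

test_that("Dirichlet spectrum likelihood matches the closed form and stays finite", {
  k <- 96
  u <- rep(1 / k, k)
  # uniform observed == reconstructed at scale s: closed-form logpdf
  s <- 50
  alpha <- rep(s / k, k)
  p_sm <- (u + 1e-6) / (1 + k * 1e-6)
  closed <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * log(p_sm))
  expect_equal(dirichlet_spectrum_loglik(u, u, scale = s), closed,
               tolerance = 1e-10)

  # an exact zero channel stays finite under the epsilon smoothing
  q <- c(0, rep(1 / (k - 1), k - 1))
  expect_true(is.finite(dirichlet_spectrum_loglik(q, u)))
  expect_error(dirichlet_spectrum_loglik(numeric(0), numeric(0)),
               "zero-length")
})

test_that("at large scale the Dirichlet likelihood peaks near the reconstructed spectrum", {
  set.seed(3)
  q <- as.numeric(rgamma(20, 2)); q <- q / sum(q)
  at_q <- dirichlet_spectrum_loglik(q, q, scale = 1e4)
  for (i in 1:5) {
    jitter <- abs(q + rnorm(20, 0, 0.02)); jitter <- jitter / sum(jitter)
    expect_gt(at_q, dirichlet_spectrum_loglik(jitter, q, scale = 1e4))
  }
})

test_that("cosine reward is a smooth step at the threshold", {
  cfg <- model_config()
  expect_equal(cosine_reward(1, cfg), cfg$reward_weight, tolerance = 1e-2)
  expect_lt(cosine_reward(0.5, cfg), 1e-8)
  expect_gt(cosine_reward(0.96, cfg), cosine_reward(0.94, cfg))
  # monotone over a grid
  grid <- cosine_reward(seq(-1, 1, by = 0.01), cfg)
  expect_true(all(diff(grid) >= 0))
})

test_that("priors are centered at 1 (background) and 0.2 (exposure) by construction", {
  cfg <- model_config()
  expect_equal(cfg$theta_b_prior$shape / cfg$theta_b_prior$rate, 1)
  expect_equal(cfg$theta_e_prior$shape / cfg$theta_e_prior$rate, 0.2)
  presets <- theta_e_prior_presets()
  expect_named(presets, c("Gamma(1,10)", "Gamma(1,5)", "Gamma(1,2)",
                          "Gamma(1,1)"))
  expect_equal(vapply(presets, function(p) p$shape, numeric(1)),
               rep(1, 4), ignore_attr = TRUE)
})

test_that("log prior respects supports and its dispersion factor integrates to 1", {
  cfg <- model_config()
  sch <- tiny_schema(4)
  se <- rep(0.25, 4)
  base <- list(theta_b = 1, theta_e = 0.2, s_e = se, nu = 2)
  expect_true(is.finite(log_prior(base, cfg)))
  expect_identical(log_prior(modifyList(base, list(nu = 1.0)), cfg), -Inf)
  expect_true(is.finite(log_prior(modifyList(base, list(nu = 1.1)), cfg)))
  expect_identical(log_prior(modifyList(base, list(theta_e = -1)), cfg), -Inf)

  # truncated-Normal nu factor: integrate the prior ratio over (1.1, Inf)
  f <- function(nu) vapply(nu, function(v)
    exp(log_prior(modifyList(base, list(nu = v)), cfg) -
          log_prior(modifyList(base, list(nu = 2)), cfg)), numeric(1))
  z <- integrate(f, 1.1, Inf)$value
  dp <- cfg$dispersion_prior
  expect_equal(z * dnorm(2, dp$mean, dp$sd) /
                 pnorm(dp$lower_bound, dp$mean, dp$sd, lower.tail = FALSE),
               1, tolerance = 1e-6)
})

test_that("reconstruction conserves activity mass exactly", {
  sch <- tiny_schema(6)
  set.seed(5)
  obs <- mutation_profile("o", rpois(6, 50) + 1, sch)
  b1 <- random_signature(sch, 1); b2 <- random_signature(sch, 2)
  dat <- model_data(obs, list(b1, b2))
  se <- random_signature(sch, 3)
  par <- list(theta_b = c(0.3, 0.4), theta_e = 0.25, s_e = se, nu = 2)
  r <- reconstruct(par, dat)
  expect_equal(sum(r), obs$burden * (0.3 + 0.4 + 0.25), tolerance = 1e-12)
  expect_error(reconstruct(modifyList(par, list(theta_b = 0.3)), dat),
               "one entry per background")
})

test_that("reconstructed total at the reported activity split equals the burden", {
  sch <- tiny_schema(4)
  obs <- mutation_profile("o", c(250, 250, 250, 250), sch)
  sb <- normalize(obs)
  se <- random_signature(sch, 9)
  dat <- model_data(obs, sb)
  r <- reconstruct(list(theta_b = 0.526, theta_e = 0.474, s_e = se, nu = 2),
                   dat)
  expect_equal(sum(r), obs$burden * 1.000, tolerance = 1e-9)
})

test_that("degenerate equal signatures reproduce the background spectrum", {
  sch <- tiny_schema(5)
  sb <- random_signature(sch, 4)
  dat <- model_data(mutation_profile("o", rep(200, 5), sch), sb)
  r <- reconstruct(list(theta_b = 0.5, theta_e = 0.5, s_e = sb, nu = 2), dat)
  expect_equal(unname(r), unname(1000 * sb$proportions), tolerance = 1e-9)
})

test_that("log posterior decomposes additively and is channel-permutation invariant", {
  set.seed(21)
  sch <- tiny_schema(8)
  mix <- local({
    sb <- random_signature(sch, 31); se <- random_signature(sch, 32)
    sim <- simulate_sample(sch, 800, sb, se, seed = 33)
    list(obs = sim$profile, sb = sb, se = se)
  })
  dat <- model_data(mix$obs, mix$sb)
  cfg <- model_config()
  p1 <- list(theta_b = 0.6, theta_e = 0.4, s_e = mix$se, nu = 2)
  p2 <- list(theta_b = 0.9, theta_e = 0.15, s_e = mix$se, nu = 1.6)
  lp1 <- log_posterior(p1, dat, cfg)
  lp2 <- log_posterior(p2, dat, cfg)
  expect_true(is.finite(lp1) && is.finite(lp2))

  comp <- function(p, d) {
    y <- d$observed$counts
    r <- reconstruct(p, d)
    c(log_prior(p, cfg),
      sum(com_poisson_logpmf(y, r, p$nu, truncation_bound(y, cfg))),
      dirichlet_spectrum_loglik(y / sum(y), r / sum(r)),
      cosine_reward(cosine_similarity(y, r), cfg))
  }
  expect_equal(lp1 - lp2, sum(comp(p1, dat) - comp(p2, dat)),
               tolerance = 1e-9)

  perm <- sample(8)
  sch2 <- channel_schema("CUSTOM", labels = sch$labels[perm])
  obs2 <- mutation_profile("o", mix$obs$counts[perm], sch2)
  dat2 <- model_data(obs2, signature_vector("b", mix$sb$proportions[perm],
                                            sch2))
  p1p <- modifyList(p1, list(s_e = mix$se$proportions[perm]))
  expect_equal(log_posterior(p1p, dat2, cfg), lp1, tolerance = 1e-9)
})

test_that("the count term strictly penalizes growing total-count mismatch", {
  sch <- tiny_schema(6)
  sb <- random_signature(sch, 41)
  y <- round(1000 * sb$proportions)
  bounds <- truncation_bound(y)
  lls <- vapply(seq(1, 1.6, by = 0.1), function(f)
    sum(com_poisson_logpmf(y, f * pmax(y, 0.5), 2, bounds)), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("the generating parameters beat a background-only explanation", {
  sch <- tiny_schema(10)
  sb <- random_signature(sch, 51)
  se <- random_signature(sch, 52)
  sim <- simulate_sample(sch, 1500, sb, se, noise = "none", seed = 53)
  dat <- model_data(sim$profile, sb)
  cfg <- model_config()
  at_truth <- log_posterior(list(theta_b = 0.5, theta_e = 0.5, s_e = se,
                                 nu = 2), dat, cfg)
  at_null <- log_posterior(list(theta_b = 1.0, theta_e = 1e-6, s_e = se,
                                nu = 2), dat, cfg)
  expect_gt(at_truth, at_null)
})

test_that("analytic gradients of the joint density match finite differences", {
  sch <- tiny_schema(7)
  sb <- random_signature(sch, 61)
  se <- random_signature(sch, 62)
  sim <- simulate_sample(sch, 600, sb, se, seed = 63)
  spec <- rescue_setup(sim$profile, sb, mcmc = fast_mcmc())
  set.seed(64)
  for (rep in 1:3) {
    u <- cleansig:::init_unconstrained(1L, 7L)
    res <- cleansig:::logpost_u_cpp(u, spec$dat)
    h <- 1e-6
    num <- vapply(seq_along(u), function(i) {
      up <- u; up[i] <- up[i] + h
      dn <- u; dn[i] <- dn[i] - h
      (cleansig:::logpost_u_cpp(up, spec$dat)$value -
         cleansig:::logpost_u_cpp(dn, spec$dat)$value) / (2 * h)
    }, numeric(1))
    expect_equal(res$grad, num, tolerance = 1e-4)
  }
})
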