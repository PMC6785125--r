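test_that("trace bookkeeping matches the chain settings", {
  m <- expansion_model()
  aln <- simulate_sequences(simulate_coalescent(6, m, seed = 1),
                            hky_subst(), 120, seed = 2)
  tr <- suppressWarnings(
    run_tem_mcmc(aln, "logistic", "strict",
                 chain = list(steps = 2000, sample_every = 100,
                              ess_threshold = 0), seed = 3))
  expect_equal(nrow(tr$samples), 2000 / 100 + 1)
  expect_equal(tr$samples$state[1], 0)
  expect_true(all(c("theta1", "theta2", "tt", "kappa", "alpha", "tmrca")
                  %in% colnames(tr$samples)))
  expect_true(all(tr$samples$theta1 <= tr$samples$theta2))
  ## a hopeless convergence gate flags the run
  expect_warning(
    run_tem_mcmc(aln, "logistic", "strict",
                 chain = list(steps = 500, sample_every = 50,
                              ess_threshold = 1e6), seed = 4),
    "not have converged")
  expect_error(run_tem_mcmc(aln, "logistic", "strict",
                            chain = list(steps = 10, sample_every = 100)),
               "chain length")
  tiny <- simulate_sequences(simulate_coalescent(3, m, seed = 9),
                             hky_subst(), 50, seed = 9)
  expect_error(run_tem_mcmc(tiny, "logistic", "strict"), ">= 4")
})

test_that("with the likelihood off the sampler reproduces its priors", {
  m <- expansion_model()
  aln <- simulate_sequences(simulate_coalescent(8, m, seed = 21),
                            hky_subst(), 150, seed = 22)
  tr <- suppressWarnings(
    run_tem_mcmc(aln, "logistic", "strict",
                 chain = list(steps = 200000, sample_every = 100,
                              ess_threshold = 0),
                 seed = 101, likelihood_power = 0))
  tt <- extract_posterior(tr, "tt", 0.2)$samples
  ## uniform prior recovered within Monte-Carlo error of the effective
  ## sample size; a Hastings-ratio defect shifts the mean by far more
  ess <- effective_size(tt)
  se <- stats::sd(tt) / sqrt(ess)
  expect_lt(abs(mean(tt) - 0.025), 4 * se + 1e-4)
  thin <- tt[seq(1, length(tt), by = max(1, floor(length(tt) / ess)))]
  expect_gt(stats::ks.test(thin, stats::punif, 0, 0.05)$p.value, 0.001)
})

test_that("relaxed-clock chains run and record branch-rate hyperparameters", {
  m <- expansion_model()
  aln <- simulate_sequences(simulate_coalescent(6, m, seed = 31),
                            hky_subst(), 200, seed = 32)
  for (ck in c("lognormal_relaxed", "exponential_relaxed")) {
    tr <- suppressWarnings(
      run_tem_mcmc(aln, "exponential", ck,
                   chain = list(steps = 4000, sample_every = 200,
                                ess_threshold = 0), seed = 33))
    expect_true(is.finite(tail(tr$samples$posterior, 1)))
  }
})

test_that("stepping-stone recovers a conjugate normal marginal likelihood", {
  ## y ~ N(mu, 1), mu ~ N(0, 1): marginal y ~ N(0, 2); power posterior at
  ## beta is N(beta y/(beta+1), 1/(beta+1)), sampled analytically
  y <- 1.7
  K <- 16
  betas <- (seq(0, K) / K)^(1 / 0.3)
  set.seed(41)
  ll <- lapply(betas[-length(betas)], function(b) {
    mu <- stats::rnorm(4000, b * y / (b + 1), sqrt(1 / (b + 1)))
    stats::dnorm(y, mu, 1, log = TRUE)
  })
  est <- stepping_stone_ml(ll, betas)
  expect_lt(abs(est - stats::dnorm(y, 0, sqrt(2), log = TRUE)), 0.1)
})

test_that("model comparison builds antisymmetric Bayes factors", {
  cmp <- compare_models(c(m1 = -1012.3, m2 = -1008.9))
  expect_equal(cmp$bayes_factors["m2", "m1"], 6.8)
  expect_equal(cmp$bayes_factors + t(cmp$bayes_factors),
               matrix(0, 2, 2, dimnames = dimnames(cmp$bayes_factors)))
  expect_equal(cmp$best, "m2")
  ## permutation leaves the winner unchanged
  cmp2 <- compare_models(c(m2 = -1008.9, m1 = -1012.3))
  expect_equal(cmp2$best, "m2")
  ## single model: empty matrix
  expect_equal(dim(compare_models(c(only = -10))$bayes_factors), c(0L, 0L))
  expect_error(compare_models(c(a = NA_real_, b = -1)), "missing MML")
})

test_that("posterior extraction applies burn-in and summaries correctly", {
  fake <- list(samples = data.frame(state = 0:9999,
                                    tt = c(rep(9, 1000), rep(2, 9000))))
  out <- extract_posterior(fake, "tt", 0.1)
  expect_equal(length(out$samples), 9000)
  expect_equal(out$median, 2)
  expect_equal(out$hpd, c(2, 2))
  all_ <- extract_posterior(fake, "tt", 0)
  expect_equal(length(all_$samples), 10000)
  expect_error(extract_posterior(fake, "nope", 0.1), "unknown parameter")
  expect_error(extract_posterior(fake, "tt", 1), "burn_in_fraction")
})

test_that("harmonic-mean marginal likelihoods come from the recorded trace", {
  m <- expansion_model()
  aln <- simulate_sequences(simulate_coalescent(6, m, seed = 51),
                            hky_subst(), 150, seed = 52)
  tr <- suppressWarnings(
    run_tem_mcmc(aln, "logistic", "strict",
                 chain = list(steps = 6000, sample_every = 30,
                              ess_threshold = 0), seed = 53))
  ml <- marginal_likelihood(tr, method = "harmonic_mean")
  ## the HM estimate cannot exceed the maximum sampled log-likelihood
  expect_lte(ml$estimate, max(tr$samples$loglik) + 1e-9)
  expect_true(is.finite(ml$se))
})
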