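test_that("a one-group skyline equals the constant-size density exactly", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    gen <- simulate_coalescent(n, constant_model(0.8))
    theta <- stats::runif(1, 0.2, 3)
    skm <- skyline_model(n, 1, rep(theta, 2))
    expect_equal(skyline_loglik(gen, skm),
                 coalescent_loglik(gen, constant_model(theta)),
                 tolerance = 1e-12)
  }
})

test_that("the piecewise-linear skyline density matches quadrature", {
  set.seed(72)
  for (i in 1:8) {
    n <- 6
    gen <- simulate_coalescent(n, constant_model(1))
    sizes <- stats::runif(3, 0.3, 3)
    skm <- skyline_model(n, 2, sizes)
    ct <- sort(genealogy_times(gen)[-(1:n)])
    bounds <- cdtem:::.skyline_boundaries(ct, skm$group_sizes)
    ne_fun <- function(t) stats::approx(bounds, sizes, xout = t,
                                        rule = 2)$y
    ll <- 0; t_prev <- 0
    for (j in seq_along(ct)) {
      k <- n - j + 1
      I <- stats::integrate(function(t) 1 / ne_fun(t), t_prev, ct[j],
                            rel.tol = 1e-12, subdivisions = 4000L)$value
      ll <- ll - k * (k - 1) / 2 * I - log(ne_fun(ct[j]))
      t_prev <- ct[j]
    }
    expect_equal(skyline_loglik(gen, skm), ll, tolerance = 1e-8)
  }
  skm_bad <- skyline_model(6, 2)
  gen5 <- simulate_coalescent(5, constant_model(1), seed = 1)
  expect_error(skyline_loglik(gen5, skm_bad), "group sizes")
})

test_that("skyline density obeys the coalescent rescaling identity", {
  ## scaling all times and all sizes by c multiplies the density by c^-(n-1)
  set.seed(73)
  n <- 7
  gen <- simulate_coalescent(n, constant_model(1))
  sizes <- stats::runif(4, 0.5, 2)
  skm <- skyline_model(n, 3, sizes)
  ll1 <- skyline_loglik(gen, skm)
  gen2 <- gen; gen2$edge.length <- gen$edge.length * 2
  skm2 <- skyline_model(n, 3, sizes * 2)
  expect_equal(skyline_loglik(gen2, skm2), ll1 - (n - 1) * log(2),
               tolerance = 1e-10)
})

test_that("group sizes partition the coalescent intervals evenly", {
  skm <- skyline_model(n_samples = 25, n_groups = 10)
  expect_equal(sum(skm$group_sizes), 24L)
  expect_true(all(diff(skm$group_sizes) >= 0))  # remainder on oldest groups
  expect_true(all(skm$group_sizes %in% c(2L, 3L)))
  expect_error(skyline_model(5, 10), "n_groups")
})

test_that("MCC trees maximize the clade-frequency score", {
  t_a <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t_b <- ape::read.tree(text = "(((a:1,b:1):0.5,c:1.5):0.5,d:2);")
  ## identical trees return that tree with its own heights
  mcc <- mcc_tree(c(ape::write.tree(t_a), ape::write.tree(t_a)))
  expect_equal(sort(genealogy_times(mcc)), sort(genealogy_times(t_a)),
               tolerance = 1e-9)
  ## majority topology wins
  mcc2 <- mcc_tree(list(t_a, t_a, t_b))
  expect_true(ape::all.equal.phylo(mcc2, t_a, use.edge.length = FALSE))
  ## brute-force score check on a sample of random 5-tip trees
  set.seed(74)
  trees <- replicate(60, simulate_coalescent(5, constant_model(1)),
                     simplify = FALSE)
  class(trees) <- "multiPhylo"
  mcc3 <- mcc_tree(trees)
  ## oracle: clade frequencies via ape::prop.part, score every sampled tree
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  freq_of <- function(tipset) {
    key <- sort(match(tipset, labs))
    for (j in seq_along(pp))
      if (length(pp[[j]]) == length(key) && all(sort(pp[[j]]) == key))
        return(attr(pp, "number")[j])
    0
  }
  score_tree <- function(tr) {
    s <- 0
    for (v in seq_len(tr$Nnode)) {
      tips <- ape::extract.clade(tr, ape::Ntip(tr) + v)$tip.label
      s <- s + log(freq_of(tips) / length(trees))
    }
    s
  }
  best_oracle <- max(vapply(trees, score_tree, numeric(1)))
  expect_equal(attr(mcc3, "mcc_log_score"), best_oracle, tolerance = 1e-9)
})

test_that("clade TMRCA posteriors convert heights to years correctly", {
  tr <- ape::read.tree(text = "((a:0.0011,b:0.0011):0.0011,c:0.0022);")
  ## single tree, fixed rate: one division
  sp <- clade_tmrca_posterior(list(tr), c("a", "b", "c"),
                              rate_samples = 2.2e-8)
  expect_equal(sp$median, 0.0022 / 2.2e-8, tolerance = 1e-9)
  expect_equal(sp$monophyly_frequency, 1)
  ## doubling every rate halves the split time exactly
  trees <- replicate(20, simulate_coalescent(6, constant_model(1e-3)),
                     simplify = FALSE)
  rates <- stats::rlnorm(20, log(2e-8), 0.3)
  s1 <- clade_tmrca_posterior(trees, c("t1", "t2", "t3"), rates)
  s2 <- clade_tmrca_posterior(trees, c("t1", "t2", "t3"), 2 * rates)
  expect_equal(s2$median, s1$median / 2, tolerance = 1e-12)
  expect_equal(s2$samples, s1$samples / 2, tolerance = 1e-12)
  ## taxa = all tips equals the TMRCA posterior
  sall <- clade_tmrca_posterior(trees, paste0("t", 1:6))
  tm <- vapply(trees, function(t) max(genealogy_times(t)), numeric(1))
  expect_equal(sort(sall$samples), sort(tm), tolerance = 1e-12)
  expect_error(clade_tmrca_posterior(trees, c("t1", "zz")), "unknown taxa")
})

test_that("a point-mass CDT rate reproduces the fixed-rate conversion exactly", {
  ## degenerate lognormal at the conventional 0.7 %/My
  degenerate <- structure(list(
    lognormal = list(LogMean = log(0.007), LogSD = 0, logLik = NA, AIC = 0),
    gaussian = list(mean = 0.007, sd = 1e-9, logLik = NA, AIC = 1),
    selected = "lognormal", median_rate_pct_per_my = 0.7,
    units = "fit on subst/site/My"), class = "rate_distribution_fit")
  trees <- replicate(15, simulate_coalescent(5, constant_model(1e-3)),
                     simplify = FALSE)
  via_fit <- clade_tmrca_posterior(trees, c("t1", "t2", "t3"),
                                   rate_samples = degenerate, seed = 1)
  via_fixed <- clade_tmrca_posterior(trees, c("t1", "t2", "t3"),
                                     rate_samples = 0.007 * 1e-6)
  expect_equal(via_fit$samples, via_fixed$samples, tolerance = 1e-12)
  expect_equal(via_fit$median, via_fixed$median, tolerance = 1e-12)
})

test_that("trajectory summaries respect generation time and degeneracy", {
  ## hand-built constant posterior
  ns <- 30
  fake <- structure(list(
    samples = data.frame(state = seq_len(ns), tmrca_yr = rep(10000, ns)),
    skyline_sizes = matrix(500, ns, 3),
    skyline_bounds = matrix(rep(c(0, 5000, 10000), each = ns), ns, 3),
    config = list(n_groups = 2, fixed_rate = TRUE)), class = "bsp_trace")
  tj <- summarize_trajectory(fake, grid = 50, burn_in_fraction = 0.1)
  expect_true(all(abs(tj$trajectory$ne_median - 500) < 1e-9))
  expect_true(all(tj$trajectory$ne_hpd_hi - tj$trajectory$ne_hpd_lo < 1e-9))
  ## halving the generation time doubles Ne
  tj2 <- summarize_trajectory(fake, grid = 50, burn_in_fraction = 0.1,
                              generation_time = 0.5)
  expect_equal(tj2$trajectory$ne_median, tj$trajectory$ne_median * 2)
  expect_error(summarize_trajectory(fake, grid = 1), "grid")
  ## HPD ordering invariant on a real-shaped object
  expect_true(all(tj$trajectory$ne_hpd_lo <= tj$trajectory$ne_median + 1e-12))
})

test_that("skyline MCMC recovers a flat trajectory from constant-size data", {
  sm <- hky_subst()
  theta <- 2e-3
  rate <- 2e-8
  gen <- simulate_coalescent(12, constant_model(theta), seed = 81)
  aln <- simulate_sequences(gen, sm, 600, seed = 82)
  tr <- suppressWarnings(run_bsp_mcmc(aln, clock_rate = rate, n_groups = 3,
                     chain = list(steps = 30000, sample_every = 50,
                                  ess_threshold = 0), seed = 83))
  tj <- summarize_trajectory(tr, grid = 40)
  ## no-signal case: recent and mid-depth HPDs overlap
  recent <- tj$trajectory[1, ]
  mid <- tj$trajectory[which.min(abs(tj$trajectory$time_yr_bp -
                                       tj$tmrca$median / 2)), ]
  expect_true(recent$ne_hpd_lo <= mid$ne_hpd_hi &&
                mid$ne_hpd_lo <= recent$ne_hpd_hi)
  expect_error(run_bsp_mcmc(aln, rate, n_groups = 20), "n_groups")
})
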