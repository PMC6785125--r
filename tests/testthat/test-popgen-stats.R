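test_that("haplotype collapsing groups identical sequences", {
  a <- aln_from_strings(rep("ACGTACGT", 5))
  ht <- collapse_haplotypes(a)
  expect_equal(length(ht$counts), 1L)
  expect_equal(length(ht$segregating_sites), 0L)

  b <- aln_from_strings(c("AAA", "AAT", "AAT"))
  ht <- collapse_haplotypes(b)
  expect_equal(sort(ht$counts), c(1L, 2L))
  expect_equal(ht$segregating_sites, 3L)
  expect_equal(sum(ht$counts), 3L)
  ## every sequence maps to exactly one haplotype
  expect_equal(ht$counts[ht$assignment[1]], 1L)

  ## complete deletion removes N/- columns before collapsing
  c_ <- aln_from_strings(c("ANT", "AGT", "AGT"))
  expect_equal(length(collapse_haplotypes(c_)$counts), 1L)
  expect_equal(length(collapse_haplotypes(c_, "pairwise")$counts), 2L)
})

test_that("haplotype diversity follows Nei's formula", {
  one <- collapse_haplotypes(aln_from_strings(rep("ACG", 4)))
  expect_equal(haplotype_diversity(one)$h, 0)
  two <- collapse_haplotypes(aln_from_strings(c("AAA", "AAA", "TTT", "TTT")))
  expect_equal(haplotype_diversity(two)$h, (4 / 3) * 0.5, tolerance = 1e-12)
  expect_error(haplotype_diversity(
    collapse_haplotypes(aln_from_strings("ACG"))), "2 sequences")
})

test_that("nucleotide diversity is the mean pairwise difference per site", {
  x <- c(paste(rep("A", 100), collapse = ""),
         paste(c(rep("A", 99), "T"), collapse = ""))
  expect_equal(nucleotide_diversity(aln_from_strings(x))$pi, 0.01)
  same <- aln_from_strings(rep("ACGTAC", 3))
  expect_equal(nucleotide_diversity(same)$pi, 0)
  ## invariant to sequence reordering
  set.seed(2)
  m <- matrix(sample(c("A", "C", "G", "T"), 60, TRUE), nrow = 6)
  a1 <- alignment(m)
  a2 <- alignment(m[6:1, ], labels = paste0("r", 1:6))
  expect_equal(nucleotide_diversity(a1)$pi, nucleotide_diversity(a2)$pi)
  expect_equal(haplotype_diversity(a1)$h, haplotype_diversity(a2)$h)
})

test_that("Tajima's D matches the hand-computed singleton toy", {
  a <- aln_from_strings(c("AAAA", "AAAA", "AAAA", "AAAT"))
  expect_equal(tajimas_d(a), -0.6123724, tolerance = 1e-6)
  expect_error(tajimas_d(aln_from_strings(rep("AAAA", 4))), "S = 0")
  expect_error(tajimas_d(aln_from_strings(c("AT", "TA", "AA"))), "n >= 4")
})

test_that("Fu's Fs matches direct Ewens summation", {
  ## oracle: coefficients of the rising factorial polynomial
  ## theta (theta+1) ... (theta+n-1) give |s(n,k)| directly
  ewens_oracle <- function(n, theta, k_obs) {
    coef <- 1
    for (i in 0:(n - 1)) coef <- c(0, coef) + c(coef * i, 0)
    ## coef[k+1] = |s(n,k)|
    p <- coef[-1] * theta^(seq_len(n))
    p <- p / sum(p)
    sum(p[k_obs:n])
  }
  for (case in list(c(5, 1.0, 3), c(6, 0.5, 2), c(8, 2.3, 5), c(4, 0.2, 2))) {
    n <- case[1]; th <- case[2]; k <- case[3]
    sp <- ewens_oracle(n, th, k)
    expect_equal(fus_fs(list(n = n, k_obs = k, pi_total = th)),
                 log(sp / (1 - sp)), tolerance = 1e-9)
  }
  ## K >= 1 always: S-prime is 1, signalled as +Inf
  expect_warning(v <- fus_fs(list(n = 3, k_obs = 1, pi_total = 0.7)), "Inf")
  expect_identical(v, Inf)
  expect_error(fus_fs(aln_from_strings(rep("AC", 3))), "pi_total")
})

test_that("R2 matches the hand-computed singleton toy", {
  a <- aln_from_strings(c("AAAT", "AAAA", "AAAA", "AAAA"))
  ## U = (1,0,0,0), pi_total = 0.5, S = 1
  expect_equal(r2_statistic(a), sqrt(0.75 / 4), tolerance = 1e-12)
  expect_error(r2_statistic(aln_from_strings(rep("AAAA", 4))), "S = 0")
})

test_that("coalescent nulls are calibrated for Tajima's D", {
  ## constant-size data should give well-behaved p-values and near-zero D
  set.seed(77)
  n <- 30
  nrep <- 150
  obs <- numeric(nrep)
  svals <- integer(nrep)
  for (i in seq_len(nrep)) {
    mat <- cdtem:::.sim_conditional_sfs(n, 12L)
    obs[i] <- cdtem:::.stats_from_binary(mat)[["tajima_d"]]
    svals[i] <- 12L
  }
  expect_lt(abs(mean(obs)), 3 * stats::sd(obs) / sqrt(nrep) + 0.12)
  ## rejection rate at nominal 5% from a shared null of the same S
  null_d <- replicate(1500, cdtem:::.stats_from_binary(
    cdtem:::.sim_conditional_sfs(n, 12L))[["tajima_d"]])
  crit <- stats::quantile(null_d, 0.05)
  rate <- mean(obs <= crit)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("neutrality_null detects simulated expansions", {
  m <- expansion_model(theta_modern = 5e-2, theta_ancient = 5e-4)
  sm <- hky_subst()
  hits <- 0
  valid <- 0
  for (i in 1:10) {
    gen <- simulate_coalescent(40, m, seed = 500 + i)
    aln <- simulate_sequences(gen, sm, 608, seed = 600 + i)
    if (length(collapse_haplotypes(aln)$segregating_sites) < 3) next
    valid <- valid + 1
    res <- neutrality_null(aln, "tajima_d", n_reps = 200, seed = 700 + i)
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gte(valid, 6)
  expect_gte(hits / valid, 0.7)
  ## p-values are reproducible given the seed
  a <- aln_from_strings(c("AAT", "ATT", "TAT", "AAA", "AAT"))
  p1 <- neutrality_null(a, "r2", 100, seed = 3)$p_value
  p2 <- neutrality_null(a, "r2", 100, seed = 3)$p_value
  expect_identical(p1, p2)
  expect_error(neutrality_null(a, "r2", 0, seed = 1), "n_reps")
})

test_that("population summary tables carry one complete row per population", {
  m <- expansion_model()
  sm <- hky_subst()
  sim <- simulate_split(split_history(2e-3, list(5e-4, 5e-4), c(6, 7), 1e-3),
                        sm, 400, seed = 91)
  tab <- population_summary(sim$alignment, n_reps = 50, seed = 92)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$population, c("deme1", "deme2"))
  expect_equal(tab$n, c(6L, 7L))
  expect_true(all(tab$h >= 0 & tab$h <= 1))
  expect_true(all(tab$pi >= 0))
  expect_true(all(tab$tajima_d_p >= 0 & tab$tajima_d_p <= 1))
  ## reproducible given the seed
  tab2 <- population_summary(sim$alignment, n_reps = 50, seed = 92)
  expect_identical(tab, tab2)
})

test_that("Phi-st behaves at its extremes and under label swapping", {
  ## identical compositions across populations
  seqs <- c("AAAA", "AAAT", "AAAA", "AAAT")
  a <- aln_from_strings(seqs, populations = c("x", "x", "y", "y"))
  res <- pairwise_phi_st(a, "x", "y", n_perms = 200, seed = 1)
  expect_lte(res$phi_st, 1e-9)
  expect_gt(res$p_value, 0.05)
  ## fixed distinct haplotypes
  b <- aln_from_strings(c("AAAA", "AAAA", "TTTT", "TTTT"),
                        populations = c("x", "x", "y", "y"))
  expect_equal(pairwise_phi_st(b, "x", "y", n_perms = 50, seed = 1)$phi_st, 1)
  ## swap invariance
  set.seed(9)
  m <- matrix(sample(c("A", "T"), 80, TRUE), nrow = 8)
  c_ <- alignment(m, populations = rep(c("p", "q"), each = 4))
  f1 <- pairwise_phi_st(c_, "p", "q", n_perms = 10, seed = 2)$phi_st
  f2 <- pairwise_phi_st(c_, "q", "p", n_perms = 10, seed = 2)$phi_st
  expect_equal(f1, f2)
  small <- aln_from_strings(c("AA", "AT", "TT"),
                            populations = c("x", "x", "y"))
  expect_error(pairwise_phi_st(small, "x", "y", 10), ">= 2")
})

test_that("T92+Gamma distances match a direct-formula oracle", {
  a <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(t92_gamma_distance(a, alpha = 0.5)$matrix[1, 2], 0)
  ## oracle: direct evaluation from P, Q, GC computed by hand
  s1 <- "ACGTACGTACGTACGTACGT"
  s2 <- "ACGTACGCACGTATGTACGA"   # one C->T-ish set of changes
  b <- aln_from_strings(c(s1, s2))
  x1 <- strsplit(s1, "")[[1]]; x2 <- strsplit(s2, "")[[1]]
  L <- length(x1)
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- x1 != x2
  P <- sum(diff & pur[x1] == pur[x2]) / L
  Q <- sum(diff & pur[x1] != pur[x2]) / L
  gc <- (sum(x1 %in% c("G", "C")) + sum(x2 %in% c("G", "C"))) / (2 * L)
  C <- 2 * gc * (1 - gc)
  for (alpha in c(0.3, 1, 5)) {
    d_oracle <- alpha * (C * ((1 - P / C - Q)^(-1 / alpha) - 1) +
                           (1 - C) / 2 * ((1 - 2 * Q)^(-1 / alpha) - 1))
    expect_equal(t92_gamma_distance(b, alpha = alpha)$matrix[1, 2], d_oracle,
                 tolerance = 1e-9)
  }
  ## alpha -> Inf approaches the uncorrected T92 distance; cross-check the
  ## uncorrected value against the independent implementation in ape
  d_inf <- t92_gamma_distance(b, alpha = Inf)$matrix[1, 2]
  d_big <- t92_gamma_distance(b, alpha = 1e6)$matrix[1, 2]
  expect_equal(d_big, d_inf, tolerance = 1e-5)
  dnab <- ape::as.DNAbin(rbind(s1 = x1, s2 = x2))
  expect_equal(d_inf, as.numeric(ape::dist.dna(dnab, model = "T92")),
               tolerance = 1e-9)
  expect_error(t92_gamma_distance(b, alpha = NULL), "alpha")
})

test_that("the minimum spanning tree is the brute-force minimum", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("h1", "h2", "h3"), c("h1", "h2", "h3")))
  mst <- minimum_spanning_tree(D)
  expect_equal(attr(mst, "total_weight"), 3)
  expect_setequal(paste(mst$from, mst$to), c("h1 h2", "h1 h3"))
  ## two haplotypes: single edge
  D2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nrow(minimum_spanning_tree(D2)), 1L)
  ## star configuration: Kruskal drops all dominated peripheral edges
  Ds <- matrix(2, 5, 5); Ds[1, ] <- Ds[, 1] <- 1; diag(Ds) <- 0
  dimnames(Ds) <- list(paste0("h", 1:5), paste0("h", 1:5))
  msts <- minimum_spanning_tree(Ds)
  expect_true(all(msts$from == "h1"))
  expect_equal(attr(msts, "total_weight"), 4)

  ## brute force over all spanning trees for random matrices up to 7 nodes
  brute_mst_weight <- function(D) {
    n <- nrow(D)
    ij <- which(upper.tri(D), arr.ind = TRUE)
    best <- Inf
    for (sel in utils::combn(nrow(ij), n - 1, simplify = FALSE)) {
      comp <- seq_len(n)
      for (e in sel) {
        a <- comp[ij[e, 1]]; b <- comp[ij[e, 2]]
        comp[comp == b] <- a
      }
      if (length(unique(comp)) == 1)
        best <- min(best, sum(D[ij[sel, , drop = FALSE]]))
    }
    best
  }
  set.seed(4)
  for (n in c(5, 6, 7)) {
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 1, 10)
    D <- D + t(D)
    dimnames(D) <- list(paste0("h", 1:n), paste0("h", 1:n))
    expect_equal(attr(minimum_spanning_tree(D), "total_weight"),
                 brute_mst_weight(D), tolerance = 1e-12)
  }
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- NaN
  expect_error(minimum_spanning_tree(Dn), "undefined")
})
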