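#' HKY+Gamma substitution model
#'
#' Hasegawa–Kishino–Yano nucleotide model (transition/transversion ratio
#' `kappa`, arbitrary stationary base frequencies) with discrete-Gamma
#' among-site rate variation (mean-of-bin discretization, as in
#' [phangorn::discrete.gamma()]).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_frequencies numeric length-4 vector in A, C, G, T order,
#'   summing to 1.
#' @param gamma_shape Gamma shape alpha (> 0); `Inf` means equal rates.
#' @param n_categories number of discrete rate categories (default 4).
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(kappa = 2, base_frequencies = rep(0.25, 4),
                               gamma_shape = Inf, n_categories = 4L) {
  if (!is.numeric(kappa) || kappa <= 0) stop_invalid("kappa must be > 0")
  bf <- base_frequencies
  if (length(bf) != 4L || any(bf <= 0) || abs(sum(bf) - 1) > 1e-9)
    stop_invalid("base_frequencies must be 4 positive values summing to 1")
  if (!is.numeric(gamma_shape) || gamma_shape <= 0)
    stop_invalid("gamma_shape must be > 0 (Inf for equal rates)")
  structure(list(kappa = kappa, base_frequencies = as.numeric(bf),
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "substitution_model")
}

## discrete-Gamma category rates (mean 1); Inf shape collapses to one category
gamma_category_rates <- function(subst) {
  if (is.infinite(subst$gamma_shape)) return(1)
  phangorn::discrete.gamma(subst$gamma_shape, subst$n_categories)
}

## normalized HKY rate matrix (rows/cols in A,C,G,T order), mean rate 1
hky_rate_matrix <- function(kappa, bf) {
  purine <- c(TRUE, FALSE, TRUE, FALSE)  # A, G
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    transition <- purine[i] == purine[j]
    Q[i, j] <- ifelse(transition, kappa, 1) * bf[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q / mu
}

#' HKY transition-probability matrix
#'
#' P(t) = exp(Qt) for the normalized HKY generator, computed by
#' eigendecomposition of the pi-symmetrized generator. `t` is in expected
#' substitutions per site.
#'
#' @param t branch length (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @param bf base frequencies (A, C, G, T).
#' @return 4x4 stochastic matrix, rows = ancestral state.
#' @export
hky_transition_matrix <- function(t, kappa, bf) {
  Q <- hky_rate_matrix(kappa, bf)
  sq <- sqrt(bf)
  B <- outer(sq, 1 / sq) * Q        # symmetric for reversible Q
  B <- (B + t(B)) / 2               # clean numeric symmetry
  es <- eigen(B, symmetric = TRUE)
  P <- outer(1 / sq, sq) * (es$vectors %*% (exp(es$values * t) * t(es$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate sequences on a genealogy under HKY+Gamma
#'
#' Evolves site-independent nucleotide sequences down the genealogy using
#' [phangorn::simSeq()] with an HKY exchangeability matrix; Gamma rate
#' variation is realized by multinomial assignment of sites to the discrete
#' rate categories.
#'
#' @param genealogy a `phylo` tree timed in substitutions/site.
#' @param subst a [substitution_model()].
#' @param length number of sites (>= 1).
#' @param seed integer seed (optional).
#' @return an [alignment()] with one sequence per tip (populations unset).
#' @export
simulate_sequences <- function(genealogy, subst, length, seed = NULL) {
  stopifnot(inherits(genealogy, "phylo"), inherits(subst, "substitution_model"))
  if (length < 1) stop_invalid("length must be >= 1")
  if (any(genealogy$edge.length < 0))
    stop_invalid("genealogy has negative branch lengths")
  if (!is.null(seed)) set.seed(seed)
  k <- subst$kappa
  Qvec <- c(1, k, 1, 1, k, 1)  # ac, ag, at, cg, ct, gt
  rates <- gamma_category_rates(subst)
  ncat <- length(rates)
  counts <- as.vector(stats::rmultinom(1, length, rep(1 / ncat, ncat)))
  blocks <- list()
  for (ci in seq_len(ncat)) {
    if (counts[ci] == 0) next
    sim <- phangorn::simSeq(genealogy, l = counts[ci], Q = Qvec,
                            bf = subst$base_frequencies, type = "DNA",
                            rate = rates[ci])
    blocks[[base::length(blocks) + 1L]] <- toupper(as.character(sim))
  }
  mat <- do.call(cbind, blocks)
  mat <- mat[genealogy$tip.label, , drop = FALSE]
  alignment(mat, labels = genealogy$tip.label)
}
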