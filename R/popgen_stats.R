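## Summary statistics for mitochondrial population samples: haplotype
## collapsing, diversity indices, neutrality tests (Tajima's D, Fu's Fs, R2)
## with coalescent nulls, pairwise Phi-st, T92+Gamma distances and the
## minimum spanning haplotype network.
##
## Missing-data policy: by default sites containing '-' or 'N' in any
## sequence are excluded from every statistic (complete deletion);
## policy = "pairwise" keeps all sites and ignores missing bases pair by pair.

## pairwise difference-count matrix
pairwise_differences <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  m <- aln$sequences
  n <- nrow(m)
  if (policy == "complete") {
    m <- m[, .usable_sites(aln, "complete"), drop = FALSE]
    if (ncol(m) == 0) stop_invalid("no comparable sites after filtering")
  }
  d <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  np <- matrix(ncol(m), n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    if (policy == "pairwise") {
      ok <- a != "N" & a != "-" & b != "N" & b != "-"
      a <- a[ok]; b <- b[ok]
      np[i, j] <- np[j, i] <- length(a)
      if (length(a) == 0) stop_invalid("no comparable sites for pair %d,%d", i, j)
    }
    d[i, j] <- d[j, i] <- sum(a != b)
  }
  attr(d, "n_sites") <- np
  d
}

#' Collapse an alignment into haplotypes
#'
#' Haplotypes are equivalence classes of identical sequences after applying
#' the missing-data policy (complete deletion by default). Segregating sites
#' are the polymorphic columns among the retained sites, reported in 1-based
#' original alignment coordinates.
#'
#' @param aln an [alignment()].
#' @param policy `"complete"` (drop sites with any N/-) or `"pairwise"`
#'   (haplotypes on the raw sequences).
#' @return object of class `haplotype_table` with fields
#'   `haplotype_sequences`, `counts`, `per_population_counts` (NULL when the
#'   alignment carries no populations), `segregating_sites`, `assignment`
#'   (haplotype index per input sequence), `n`.
#' @export
collapse_haplotypes <- function(aln, policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "alignment"))
  policy <- match.arg(policy)
  use <- if (policy == "complete") .usable_sites(aln, "complete")
         else seq_len(ncol(aln$sequences))
  if (length(use) == 0) stop_invalid("no usable sites after filtering")
  m <- aln$sequences[, use, drop = FALSE]
  key <- apply(m, 1, paste, collapse = "")
  uk <- unique(key)
  assignment <- match(key, uk)
  counts <- as.integer(table(factor(assignment, levels = seq_along(uk))))
  seg <- use[apply(m[match(uk, key), , drop = FALSE], 2,
                   function(col) length(unique(col)) > 1L)]
  per_pop <- NULL
  if (!is.null(aln$populations))
    per_pop <- table(haplotype = assignment, population = aln$populations)
  structure(list(haplotype_sequences = uk, counts = counts,
                 per_population_counts = per_pop,
                 segregating_sites = as.integer(seg),
                 assignment = assignment, n = nrow(m)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("%d haplotypes from %d sequences; %d segregating sites\n",
              length(x$counts), x$n, length(x$segregating_sites)))
  invisible(x)
}

#' Haplotype (gene) diversity
#'
#' h = n/(n-1) (1 - sum p_i^2) with Nei's sampling variance.
#'
#' @param table a `haplotype_table` from [collapse_haplotypes()], or an
#'   [alignment()] (collapsed first).
#' @return list with `h` and `se`.
#' @export
haplotype_diversity <- function(table) {
  if (inherits(table, "alignment")) table <- collapse_haplotypes(table)
  stopifnot(inherits(table, "haplotype_table"))
  n <- table$n
  if (n < 2) stop_invalid("need at least 2 sequences")
  p <- table$counts / n
  s2 <- sum(p^2)
  h <- n / (n - 1) * (1 - s2)
  ## Nei (1987) eq. 8.12
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  list(h = h, se = sqrt(max(v, 0)))
}

#' Nucleotide diversity
#'
#' Average pairwise proportion of differing sites under the missing-data
#' policy, with the standard coalescent sampling variance
#' (Tajima 1983 / Nei 1987 eq. 10.7).
#'
#' @param aln an [alignment()].
#' @param policy missing-data policy, see [collapse_haplotypes()].
#' @return list with `pi` (per site) and `se`.
#' @export
nucleotide_diversity <- function(aln, policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "alignment"))
  policy <- match.arg(policy)
  n <- n_sequences(aln)
  if (n < 2) stop_invalid("need at least 2 sequences")
  d <- pairwise_differences(aln, policy)
  if (policy == "complete") {
    L <- length(.usable_sites(aln, "complete"))
    pi <- mean(d[upper.tri(d)]) / L
  } else {
    np <- attr(d, "n_sites")
    pi <- mean((d / np)[upper.tri(d)])
    L <- mean(np[upper.tri(np)])
  }
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, se = sqrt(max(v, 0)))
}

## mean pairwise difference count and segregating-site count
.pi_total_S <- function(aln, policy = "complete") {
  d <- pairwise_differences(aln, policy)
  ht <- collapse_haplotypes(aln, policy)
  list(pi_total = mean(d[upper.tri(d)]), S = length(ht$segregating_sites),
       k_obs = length(ht$counts))
}

#' Tajima's D
#'
#' D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1)) with the constants of
#' Tajima (1989); pi_total is the mean pairwise difference count (not per
#' site).
#'
#' @param aln an [alignment()] (or a list with elements `n`, `S`,
#'   `pi_total` for pre-computed inputs).
#' @param policy missing-data policy.
#' @return the D statistic (numeric scalar).
#' @export
tajimas_d <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (inherits(aln, "alignment")) {
    n <- n_sequences(aln)
    st <- .pi_total_S(aln, policy)
    S <- st$S; pi_total <- st$pi_total
  } else {
    n <- aln$n; S <- aln$S; pi_total <- aln$pi_total
  }
  if (n < 4) stop_invalid("Tajima's D needs n >= 4")
  if (S < 1) stop_invalid("Tajima's D is undefined when S = 0")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## log unsigned Stirling numbers of the first kind, row n: log|s(n,k)|, k=1..n
log_stirling_first <- function(n) {
  ls <- 0  # row 1: |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 1:(n - 1)) {
    new <- numeric(m + 1)
    ## |s(m+1,k)| = |s(m,k-1)| + m |s(m,k)|
    new[1] <- log(m) + ls[1]
    if (m > 1)
      for (k in 2:m) new[k] <- logsumexp(c(ls[k - 1], log(m) + ls[k]))
    new[m + 1] <- 0
    ls <- new
  }
  ls
}

## Ewens sampling-formula distribution of the number of alleles K:
## P(K = k) = |s(n,k)| theta^k / (theta)_n
ewens_k_distribution <- function(n, theta) {
  ls <- log_stirling_first(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp - logsumexp(lp))
}

#' Fu's Fs
#'
#' Fs = ln(S'/(1 - S')) where S' = P(K >= k_obs | theta = pi_total) under the
#' Ewens sampling formula; k_obs is the observed number of haplotypes and
#' pi_total the mean pairwise difference count.
#'
#' @param aln an [alignment()] (or a list with `n`, `k_obs`, `pi_total`).
#' @param policy missing-data policy.
#' @return the Fs statistic; `+Inf`/`-Inf` are returned (with a warning) when
#'   S' is exactly 1 or 0.
#' @export
fus_fs <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  if (inherits(aln, "alignment")) {
    n <- n_sequences(aln)
    st <- .pi_total_S(aln, policy)
    k_obs <- st$k_obs; pi_total <- st$pi_total
  } else {
    n <- aln$n; k_obs <- aln$k_obs; pi_total <- aln$pi_total
  }
  if (n < 2) stop_invalid("Fu's Fs needs n >= 2")
  if (pi_total <= 0) stop_invalid("Fu's Fs is undefined when pi_total = 0")
  p <- ewens_k_distribution(n, pi_total)
  sprime <- sum(p[k_obs:n])
  if (sprime >= 1 - 1e-15) {
    warning("S' = 1: Fu's Fs is +Inf")
    return(Inf)
  }
  if (sprime <= 1e-300) {
    warning("S' = 0: Fu's Fs is -Inf")
    return(-Inf)
  }
  log(sprime / (1 - sprime))
}

## number of singleton variants carried by each sequence: at each site, an
## allele seen exactly once marks its carrier
.singleton_counts <- function(m) {
  n <- nrow(m)
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    singles <- names(tab)[tab == 1]
    if (length(singles))
      U <- U + as.numeric(m[, j] %in% singles)
  }
  U
}

#' Ramos-Onsins & Rozas R2
#'
#' R2 = sqrt( mean_i (U_i - pi_total/2)^2 ) / S, with U_i the number of
#' singleton variants carried by sequence i. Small values indicate
#' population growth.
#'
#' @param aln an [alignment()].
#' @param policy missing-data policy.
#' @return the R2 statistic.
#' @export
r2_statistic <- function(aln, policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "alignment"))
  policy <- match.arg(policy)
  n <- n_sequences(aln)
  if (n < 2) stop_invalid("R2 needs n >= 2")
  use <- .usable_sites(aln, policy)
  m <- aln$sequences[, use, drop = FALSE]
  st <- .pi_total_S(aln, policy)
  if (st$S < 1) stop_invalid("R2 is undefined when S = 0")
  U <- .singleton_counts(m)
  sqrt(mean((U - st$pi_total / 2)^2)) / st$S
}

## ---- coalescent null distributions -------------------------------------

## simulate a constant-size Kingman genealogy and drop S infinite-sites
## mutations uniformly on its branches; returns derived-allele counts and
## the tip x site binary matrix
.sim_conditional_sfs <- function(n, S) {
  ## lineages carry tip sets; record branch (tipset, length) pieces
  tipsets <- as.list(seq_len(n))
  birth <- rep(0, n)
  t_cur <- 0
  branch_sets <- vector("list", 2 * n - 2)
  branch_len <- numeric(2 * n - 2)
  nb <- 0L
  k <- n
  while (k > 1L) {
    t_cur <- t_cur + stats::rexp(1, k * (k - 1) / 2)
    ij <- sort(sample.int(k, 2L))
    for (x in ij) {
      nb <- nb + 1L
      branch_sets[[nb]] <- tipsets[[x]]
      branch_len[nb] <- t_cur - birth[x]
    }
    tipsets[[ij[1L]]] <- c(tipsets[[ij[1L]]], tipsets[[ij[2L]]])
    birth[ij[1L]] <- t_cur
    tipsets <- tipsets[-ij[2L]]; birth <- birth[-ij[2L]]
    k <- k - 1L
  }
  picks <- sample.int(nb, S, replace = TRUE, prob = branch_len[seq_len(nb)])
  mat <- matrix(0L, n, S)
  for (s in seq_len(S)) mat[branch_sets[[picks[s]]], s] <- 1L
  mat
}

## D, Fs, R2 from a 0/1 derived-allele matrix (infinite sites)
.stats_from_binary <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  cc <- colSums(mat)
  pi_total <- sum(cc * (n - cc)) / (n * (n - 1) / 2)
  key <- apply(mat, 1, paste, collapse = "")
  k_obs <- length(unique(key))
  ## folded singletons: derived count 1 (carrier) or n-1 (the odd ancestral)
  U <- numeric(n)
  one <- which(cc == 1)
  if (length(one)) U <- U + rowSums(mat[, one, drop = FALSE])
  nm1 <- which(cc == n - 1)
  if (length(nm1)) U <- U + rowSums(1L - mat[, nm1, drop = FALSE])
  d <- if (n >= 4 && S >= 1)
    tajimas_d(list(n = n, S = S, pi_total = pi_total)) else NA_real_
  fs <- if (pi_total > 0)
    suppressWarnings(fus_fs(list(n = n, k_obs = k_obs, pi_total = pi_total)))
  else NA_real_
  r2 <- if (S >= 1) sqrt(mean((U - pi_total / 2)^2)) / S else NA_real_
  c(tajima_d = d, fu_fs = fs, r2 = r2)
}

#' Coalescent null distribution for a neutrality statistic
#'
#' Significance of Tajima's D, Fu's Fs or R2 against the constant-size
#' neutral coalescent conditioned on the observed sample size and number of
#' segregating sites: replicate genealogies receive exactly S infinite-sites
#' mutations placed uniformly on their branches. The one-tailed p-value is
#' the fraction of replicates with a statistic less than or equal to the
#' observed one (small/negative values indicate expansion for all three
#' statistics).
#'
#' @param aln an [alignment()].
#' @param statistic `"tajima_d"`, `"fu_fs"` or `"r2"`.
#' @param n_reps number of coalescent replicates (default 1000).
#' @param seed integer seed.
#' @param policy missing-data policy.
#' @return object of class `neutrality_result`: list with `statistic_name`,
#'   `value`, `p_value`, `n_reps`, `null_values`.
#' @export
neutrality_null <- function(aln, statistic = c("tajima_d", "fu_fs", "r2"),
                            n_reps = 1000, seed = NULL,
                            policy = c("complete", "pairwise")) {
  statistic <- match.arg(statistic)
  policy <- match.arg(policy)
  if (n_reps < 1) stop_invalid("n_reps must be >= 1")
  obs <- switch(statistic,
                tajima_d = tajimas_d(aln, policy),
                fu_fs = fus_fs(aln, policy),
                r2 = r2_statistic(aln, policy))
  n <- n_sequences(aln)
  S <- length(collapse_haplotypes(aln, policy)$segregating_sites)
  if (!is.null(seed)) set.seed(seed)
  null_values <- vapply(seq_len(n_reps), function(i) {
    .stats_from_binary(.sim_conditional_sfs(n, S))[[statistic]]
  }, numeric(1))
  p <- mean(null_values <= obs, na.rm = TRUE)
  structure(list(statistic_name = statistic, value = obs, p_value = p,
                 n_reps = n_reps, null_values = null_values),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("%s = %.4f, one-tailed p = %.4f (%d coalescent replicates)\n",
              x$statistic_name, x$value, x$p_value, x$n_reps))
  invisible(x)
}

## ---- Phi-st -------------------------------------------------------------

.phi_st_estimate <- function(d, pop) {
  N <- nrow(d)
  pops <- unique(pop)
  ssd_t <- sum(d[upper.tri(d)]) / N
  ssd_w <- 0
  for (p in pops) {
    idx <- which(pop == p)
    dp <- d[idx, idx, drop = FALSE]
    ssd_w <- ssd_w + sum(dp[upper.tri(dp)]) / length(idx)
  }
  ssd_a <- ssd_t - ssd_w
  P <- length(pops)
  sigma_w <- ssd_w / (N - P)
  n_eff <- (N - sum(table(pop)^2) / N) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_w) / n_eff
  if (sigma_a + sigma_w == 0) return(0)  # no molecular variation at all
  sigma_a / (sigma_a + sigma_w)
}

#' Pairwise Phi-st with a permutation test
#'
#' AMOVA-based fixation index between two populations computed from squared
#' molecular distances between individuals (default: pairwise difference
#' counts; `distance = "t92_gamma"` uses the Tamura 1992 + Gamma distance
#' with shape `alpha`). Significance by random reassignment of individuals
#' to populations holding sample sizes fixed.
#'
#' @param aln an [alignment()] with populations set.
#' @param pop_a,pop_b the two population labels.
#' @param n_perms number of permutations (default 1000).
#' @param seed integer seed.
#' @param distance `"differences"` or `"t92_gamma"`.
#' @param alpha Gamma shape for `"t92_gamma"` (required for that choice).
#' @param policy missing-data policy.
#' @return list with `phi_st`, `p_value`, `n_perms`.
#' @export
pairwise_phi_st <- function(aln, pop_a, pop_b, n_perms = 1000, seed = NULL,
                            distance = c("differences", "t92_gamma"),
                            alpha = NULL,
                            policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "alignment"))
  distance <- match.arg(distance)
  policy <- match.arg(policy)
  sub <- subset_population(aln, c(pop_a, pop_b))
  pop <- sub$populations
  if (sum(pop == pop_a) < 2 || sum(pop == pop_b) < 2)
    stop_invalid("each population needs >= 2 sequences")
  d <- if (distance == "differences") pairwise_differences(sub, policy)
       else {
         dm <- t92_gamma_distance(sub, alpha = alpha, policy = policy)$matrix
         if (any(!is.finite(dm))) stop_invalid("undefined T92 distances present")
         dm
       }
  obs <- .phi_st_estimate(d, pop)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perms), function(i) {
    .phi_st_estimate(d, sample(pop))
  }, numeric(1))
  list(phi_st = obs, p_value = mean(perm >= obs), n_perms = n_perms)
}

## ---- T92 + Gamma distances ---------------------------------------------

#' Tamura (1992) distance with Gamma rate correction
#'
#' Three-parameter distance accounting for GC content and transition bias.
#' For each pair: P = transition proportion, Q = transversion proportion,
#' theta = mean GC content of the two sequences, C = 2 theta (1 - theta);
#' with Gamma shape a the distance is
#' a \[ C ((1-P/C-Q)^(-1/a) - 1) + ((1-C)/2) ((1-2Q)^(-1/a) - 1) \];
#' the a -> Inf limit is the uncorrected T92 distance
#' -C ln(1-P/C-Q) - ((1-C)/2) ln(1-2Q). Saturated pairs (non-positive log or
#' power arguments) are flagged `NaN`.
#'
#' @param aln an [alignment()].
#' @param alpha Gamma shape (> 0, or `Inf` for no rate variation). Required:
#'   there is no hidden default.
#' @param policy missing-data policy.
#' @return list of class `distance_matrix`: `labels`, `matrix`,
#'   `distance_kind`.
#' @export
t92_gamma_distance <- function(aln, alpha, policy = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "alignment"))
  if (missing(alpha) || is.null(alpha) || !is.numeric(alpha) || alpha <= 0)
    stop_invalid("alpha (Gamma shape) must be given and > 0")
  policy <- match.arg(policy)
  m <- aln$sequences
  if (policy == "complete") m <- m[, .usable_sites(aln, "complete"), drop = FALSE]
  n <- nrow(m)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  D <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    a <- a[ok]; b <- b[ok]
    L <- length(a)
    if (L == 0) { D[i, j] <- D[j, i] <- NaN; next }
    diff <- a != b
    ts <- diff & (purine[a] == purine[b])
    P <- sum(ts) / L
    Q <- sum(diff & !ts) / L
    gc <- (sum(a %in% c("G", "C")) + sum(b %in% c("G", "C"))) / (2 * L)
    C <- 2 * gc * (1 - gc)
    w1 <- 1 - P / C - Q
    w2 <- 1 - 2 * Q
    if (P == 0 && Q == 0) { D[i, j] <- 0; next }
    if (C == 0 || w1 <= 0 || w2 <= 0) { D[i, j] <- D[j, i] <- NaN; next }
    d <- if (is.infinite(alpha)) {
      -C * log(w1) - (1 - C) / 2 * log(w2)
    } else {
      alpha * (C * (w1^(-1 / alpha) - 1) + (1 - C) / 2 * (w2^(-1 / alpha) - 1))
    }
    D[i, j] <- D[j, i] <- d
  }
  structure(list(labels = aln$labels, matrix = D,
                 distance_kind = if (is.infinite(alpha)) "t92" else "t92_gamma",
                 alpha = alpha),
            class = "distance_matrix")
}

## ---- minimum spanning network ------------------------------------------

#' Minimum spanning tree over haplotypes
#'
#' Kruskal's algorithm on the complete haplotype graph with a deterministic
#' tie-break: edges are taken in increasing (distance, label_i, label_j)
#' order.
#'
#' @param dist a `distance_matrix` (e.g. from [t92_gamma_distance()]) or a
#'   plain symmetric matrix with dimnames.
#' @param freqs optional haplotype counts (node sizes), named or in label
#'   order.
#' @return data.frame with columns `from`, `to`, `distance`; attribute
#'   `node_sizes` carries the frequencies, attribute `total_weight` the MST
#'   weight.
#' @export
minimum_spanning_tree <- function(dist, freqs = NULL) {
  D <- if (inherits(dist, "distance_matrix")) dist$matrix else dist
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("h", seq_len(nrow(D)))
  n <- nrow(D)
  if (any(!is.finite(D[upper.tri(D)])))
    stop_invalid("undefined distances present; clean or replace them first")
  if (n == 1)
    return(structure(data.frame(from = character(0), to = character(0),
                                distance = numeric(0)),
                     node_sizes = freqs, total_weight = 0))
  ij <- which(upper.tri(D), arr.ind = TRUE)
  edges <- data.frame(i = ij[, 1], j = ij[, 2], w = D[ij])
  edges <- edges[order(edges$w, labels[edges$i], labels[edges$j]), ]
  comp <- seq_len(n)
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ci <- comp[edges$i[e]]; cj <- comp[edges$j[e]]
    if (ci != cj) {
      keep[e] <- TRUE
      comp[comp == cj] <- ci
    }
  }
  sel <- edges[keep, ]
  out <- data.frame(from = labels[sel$i], to = labels[sel$j],
                    distance = sel$w, stringsAsFactors = FALSE)
  attr(out, "node_sizes") <- freqs
  attr(out, "total_weight") <- sum(sel$w)
  out
}

#' Per-population summary statistics table
#'
#' Computes, for each population in the alignment, the Table-2-style row:
#' sample size, number of haplotypes, haplotype diversity (with SE),
#' nucleotide diversity (with SE), Tajima's D, Fu's Fs and R2, with
#' one-tailed coalescent p-values.
#'
#' @param aln an [alignment()] with populations set.
#' @param n_reps replicates for the neutrality nulls (default 1000).
#' @param seed integer seed for the nulls.
#' @return data.frame with one row per population.
#' @export
population_summary <- function(aln, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(aln, "alignment"), !is.null(aln$populations))
  pops <- unique(aln$populations)
  rows <- lapply(seq_along(pops), function(k) {
    p <- pops[k]
    sub <- subset_population(aln, p)
    ht <- collapse_haplotypes(sub)
    hd <- haplotype_diversity(ht)
    nd <- nucleotide_diversity(sub)
    sd_ <- if (!is.null(seed)) split_seed(seed, k) else NULL
    d <- neutrality_null(sub, "tajima_d", n_reps, sd_)
    fs <- neutrality_null(sub, "fu_fs", n_reps, sd_)
    r2 <- neutrality_null(sub, "r2", n_reps, sd_)
    data.frame(population = p, n = ht$n, H = length(ht$counts),
               h = hd$h, h_se = hd$se, pi = nd$pi, pi_se = nd$se,
               tajima_d = d$value, tajima_d_p = d$p_value,
               fu_fs = fs$value, fu_fs_p = fs$p_value,
               r2 = r2$value, r2_p = r2$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
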