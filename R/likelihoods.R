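#' Molecular clock model
#'
#' Strict clock (all branch-rate multipliers 1) or uncorrelated relaxed
#' clocks with lognormal or exponential branch-rate distributions (mean 1,
#' acting as multipliers of `mean_rate`).
#'
#' @param kind `"strict"`, `"lognormal_relaxed"` or `"exponential_relaxed"`.
#' @param mean_rate mean substitution rate in substitutions/site per unit of
#'   tree time (1 for mutation-scaled inference).
#' @param spread lognormal standard deviation (log scale) for the lognormal
#'   relaxed clock; ignored otherwise.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "lognormal_relaxed",
                                 "exponential_relaxed"),
                        mean_rate = 1, spread = 0.5) {
  kind <- match.arg(kind)
  if (mean_rate <= 0) stop_invalid("mean_rate must be > 0")
  if (kind == "lognormal_relaxed" && spread <= 0)
    stop_invalid("spread must be > 0 for the lognormal relaxed clock")
  structure(list(kind = kind, mean_rate = mean_rate, spread = spread),
            class = "clock_model")
}

## draw mean-1 branch-rate multipliers for a clock
draw_branch_rates <- function(clock, n_edges) {
  switch(clock$kind,
         strict = rep(1, n_edges),
         lognormal_relaxed = stats::rlnorm(n_edges,
                                           -clock$spread^2 / 2, clock$spread),
         exponential_relaxed = stats::rexp(n_edges, 1))
}

#' Coalescent log-density of a genealogy under a two-epoch model
#'
#' Log-density of an ultrametric genealogy under the inhomogeneous
#' coalescent with rate k(k-1)/(2 N(t)): over each internode interval the
#' term -k(k-1)/2 * (Lambda(t_i) - Lambda(t_(i-1))) with Lambda the
#' closed-form cumulative intensity, plus -log N(t_c) at each coalescence.
#'
#' @param gen an ultrametric `phylo` genealogy (mutation-scaled) or a sorted
#'   vector of its n-1 coalescent times.
#' @param model a [two_epoch_model()].
#' @return log-density (numeric scalar).
#' @export
coalescent_loglik <- function(gen, model) {
  stopifnot(inherits(model, "two_epoch_model"))
  if (inherits(gen, "phylo")) {
    times <- genealogy_times(gen)
    tip_t <- times[seq_len(ape::Ntip(gen))]
    if (max(tip_t) - min(tip_t) > 1e-8 * max(times))
      stop_invalid("genealogy is not ultrametric")
    ct <- sort(times[-seq_len(ape::Ntip(gen))])
    n <- ape::Ntip(gen)
  } else {
    ct <- sort(as.numeric(gen))
    n <- length(ct) + 1L
  }
  k <- n - seq_along(ct) + 1L
  lam <- coalescent_intensity(model, ct)
  dlam <- diff(c(0, lam))
  -sum(k * (k - 1) / 2 * dlam) - sum(log(demographic_size(model, ct)))
}

## pattern-compress an alignment into integer states for the pruning kernel
alignment_patterns <- function(aln, tip_order) {
  m <- aln$sequences[tip_order, , drop = FALSE]
  code <- matrix(match(m, c("A", "C", "G", "T"), nomatch = 5L) - 1L,
                 nrow = nrow(m))
  key <- apply(code, 2, paste, collapse = ",")
  tab <- table(key)
  uk <- names(tab)
  first <- match(uk, key)
  states <- code[, first, drop = FALSE]
  list(states = states, weights = as.numeric(tab))
}

#' HKY+Gamma tree log-likelihood (Felsenstein pruning)
#'
#' Likelihood of the alignment given a time-scaled genealogy, substitution
#' model and clock: branch lengths in substitutions/site are edge durations
#' times `clock$mean_rate` times the per-branch rate multiplier. Site
#' patterns are compressed and the discrete-Gamma mixture averaged with
#' equal category weights.
#'
#' @param aln an [alignment()]; labels must match the genealogy's tips.
#' @param gen a `phylo` genealogy.
#' @param subst a [substitution_model()].
#' @param clock a [clock_model()] (default strict, rate 1).
#' @param branch_rates per-branch multipliers in the order of `gen$edge`
#'   rows; default all 1.
#' @return log-likelihood (numeric scalar).
#' @export
tree_loglik <- function(aln, gen, subst, clock = clock_model("strict"),
                        branch_rates = NULL) {
  stopifnot(inherits(aln, "alignment"), inherits(gen, "phylo"),
            inherits(subst, "substitution_model"))
  if (!setequal(gen$tip.label, aln$labels))
    stop_invalid("tip labels do not match alignment labels")
  if (is.null(branch_rates)) branch_rates <- rep(1, nrow(gen$edge))
  stopifnot(length(branch_rates) == nrow(gen$edge))
  po <- ape::reorder.phylo(gen, "postorder")
  ## carry branch_rates through the reordering by matching child nodes
  rate_of_child <- numeric(max(gen$edge))
  rate_of_child[gen$edge[, 2]] <- branch_rates
  brlen <- po$edge.length * clock$mean_rate * rate_of_child[po$edge[, 2]]
  pat <- alignment_patterns(aln, match(po$tip.label, aln$labels))
  ## kernel expects (child, parent) columns; ape stores (parent, child)
  .hky_pruning_cpp(pat$states, pat$weights, po$edge[, c(2L, 1L), drop = FALSE],
                   brlen,
                   subst$kappa, subst$base_frequencies,
                   gamma_category_rates(subst))
}
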