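## Genealogies are ape "phylo" objects with an extra attribute "time_units"
## ("substitutions_per_site" or "years"); tips are contemporaneous (time 0)
## and node times increase into the past.

#' Node times of an ultrametric genealogy
#'
#' @param phy an ultrametric `phylo` tree.
#' @return numeric vector of times before present for all nodes (tips first,
#'   then internal nodes, in ape numbering).
#' @export
genealogy_times <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  d <- ape::node.depth.edgelength(phy)   # depth from root
  max(d[seq_len(ape::Ntip(phy))]) - d
}

## join subtree newick fragments at given times into a phylo object
.assemble_coalescent_tree <- function(labels, event_times, picks) {
  n <- length(labels)
  frag <- as.list(labels)
  height <- rep(0, n)
  for (ev in seq_len(n - 1L)) {
    ij <- picks[[ev]]
    t_ev <- event_times[ev]
    i <- ij[1L]; j <- ij[2L]
    newf <- sprintf("(%s:%.12g,%s:%.12g)", frag[[i]], t_ev - height[i],
                    frag[[j]], t_ev - height[j])
    frag[[i]] <- newf; height[i] <- t_ev
    frag <- frag[-j]; height <- height[-j]
  }
  phy <- ape::read.tree(text = paste0(frag[[1L]], ";"))
  attr(phy, "time_units") <- "substitutions_per_site"
  phy
}

#' Simulate a coalescent genealogy under a two-epoch model
#'
#' Draws an ultrametric binary genealogy of `n_samples` contemporaneous tips
#' from the inhomogeneous coalescent with rate k(k-1)/(2 N(t)), using exact
#' time rescaling: for each interval an Exp(1) variate is mapped through the
#' closed-form cumulative intensity of the model.
#'
#' @param n_samples number of tips (>= 2).
#' @param model a [two_epoch_model()]; a constant population of size theta is
#'   the degenerate case theta_ancient == theta_modern.
#' @param seed integer seed (optional); given the seed the genealogy is
#'   reproducible bit for bit.
#' @param labels tip labels (default `t1..tn`).
#' @return a `phylo` genealogy with times in the model's units.
#' @export
simulate_coalescent <- function(n_samples, model, seed = NULL, labels = NULL) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop_invalid("n_samples must be >= 2")
  stopifnot(inherits(model, "two_epoch_model"))
  n <- as.integer(n_samples)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n)

  t_cur <- 0
  event_times <- numeric(n - 1L)
  picks <- vector("list", n - 1L)
  k <- n
  m <- n  # current number of lineages in the fragment list
  for (ev in seq_len(n - 1L)) {
    e <- stats::rexp(1)
    t_cur <- invert_intensity(model, 2 * e / (k * (k - 1)), t_lower = t_cur)
    event_times[ev] <- t_cur
    ij <- sample.int(m, 2L)
    picks[[ev]] <- sort(ij)
    k <- k - 1L; m <- m - 1L
  }
  .assemble_coalescent_tree(labels, event_times, picks)
}

#' Two-deme clean-split history
#'
#' Describes two populations that diverged at `split_time` with no migration
#' afterwards. Each deme has its own demographic model (a [two_epoch_model()]
#' or a constant size given as a single number); the merged ancestral
#' population is constant at `ancestral_theta`.
#'
#' @param split_time divergence time (> 0), substitutions/site unless stated
#'   otherwise by the caller.
#' @param deme_sizes list of two elements, each a `two_epoch_model` or a
#'   positive number (constant size).
#' @param sample_sizes integer vector of two sample sizes (each >= 1).
#' @param ancestral_theta constant size of the ancestral population (> 0).
#' @return an object of class `split_history`.
#' @export
split_history <- function(split_time, deme_sizes, sample_sizes,
                          ancestral_theta) {
  if (!is.numeric(split_time) || split_time <= 0)
    stop_invalid("split_time must be > 0")
  if (length(deme_sizes) != 2L) stop_invalid("deme_sizes must have 2 elements")
  deme_sizes <- lapply(deme_sizes, function(d) {
    if (inherits(d, "two_epoch_model")) return(d)
    if (is.numeric(d) && d > 0) return(d)
    stop_invalid("each deme size must be a two_epoch_model or a positive number")
  })
  if (length(sample_sizes) != 2L || any(sample_sizes < 1))
    stop_invalid("sample_sizes must be two counts >= 1")
  if (!is.numeric(ancestral_theta) || ancestral_theta <= 0)
    stop_invalid("ancestral_theta must be > 0")
  structure(list(split_time = split_time, deme_sizes = deme_sizes,
                 sample_sizes = as.integer(sample_sizes),
                 ancestral_theta = ancestral_theta),
            class = "split_history")
}

## cumulative intensity for a deme spec (model or constant)
.deme_intensity <- function(spec, t) {
  if (inherits(spec, "two_epoch_model")) coalescent_intensity(spec, t)
  else t / spec
}
.deme_invert <- function(spec, target, t_lower) {
  if (inherits(spec, "two_epoch_model")) invert_intensity(spec, target, t_lower)
  else t_lower + target * spec
}

#' Simulate a structured-coalescent genealogy and alignment under a clean split
#'
#' Runs independent coalescents inside each deme up to the split time (events
#' whose rescaled waiting time would pass the split are censored), pools the
#' surviving lineages at the split, and finishes under a constant ancestral
#' population. Sequences are then evolved on the genealogy under the given
#' substitution model.
#'
#' @param history a [split_history()] (times in substitutions/site).
#' @param subst a [substitution_model()].
#' @param length number of sites (>= 1).
#' @param seed integer seed.
#' @return list with `alignment` (an [alignment()] whose populations are
#'   `"deme1"`/`"deme2"`) and `genealogy` (the true labelled `phylo`).
#' @export
simulate_split <- function(history, subst, length, seed = NULL) {
  stopifnot(inherits(history, "split_history"))
  if (any(history$sample_sizes < 1)) stop_invalid("empty deme sample")
  if (!is.null(seed)) set.seed(seed)
  n1 <- history$sample_sizes[1L]; n2 <- history$sample_sizes[2L]
  labels <- c(paste0("d1_", seq_len(n1)), paste0("d2_", seq_len(n2)))
  pops <- rep(c("deme1", "deme2"), c(n1, n2))

  ## per-deme fragments (newick strings + heights)
  frag <- as.list(labels)
  height <- rep(0, n1 + n2)
  deme_of <- rep(1:2, c(n1, n2))

  for (d in 1:2) {
    spec <- history$deme_sizes[[d]]
    t_cur <- 0
    repeat {
      idx <- which(deme_of == d)
      k <- length(idx)
      if (k < 2L) break
      e <- stats::rexp(1)
      need <- 2 * e / (k * (k - 1))
      avail <- .deme_intensity(spec, history$split_time) -
        .deme_intensity(spec, t_cur)
      if (need > avail) break  # censored at the split
      t_cur <- .deme_invert(spec, need, t_cur)
      ij <- sort(sample(idx, 2L))
      frag[[ij[1L]]] <- sprintf("(%s:%.12g,%s:%.12g)",
                                frag[[ij[1L]]], t_cur - height[ij[1L]],
                                frag[[ij[2L]]], t_cur - height[ij[2L]])
      height[ij[1L]] <- t_cur
      frag <- frag[-ij[2L]]; height <- height[-ij[2L]]
      deme_of <- deme_of[-ij[2L]]
    }
  }

  ## ancestral phase: constant size
  t_cur <- history$split_time
  th <- history$ancestral_theta
  while (length(frag) > 1L) {
    k <- length(frag)
    t_cur <- t_cur + stats::rexp(1) * th / (k * (k - 1) / 2)
    ij <- sort(sample.int(k, 2L))
    frag[[ij[1L]]] <- sprintf("(%s:%.12g,%s:%.12g)",
                              frag[[ij[1L]]], t_cur - height[ij[1L]],
                              frag[[ij[2L]]], t_cur - height[ij[2L]])
    height[ij[1L]] <- t_cur
    frag <- frag[-ij[2L]]; height <- height[-ij[2L]]
    deme_of <- deme_of[-ij[2L]]
  }
  phy <- ape::read.tree(text = paste0(frag[[1L]], ";"))
  attr(phy, "time_units") <- "substitutions_per_site"
  aln <- simulate_sequences(phy, subst, length)
  aln$populations <- pops[match(aln$labels, labels)]
  list(alignment = aln, genealogy = phy)
}
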