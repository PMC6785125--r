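## Bayesian MCMC over (genealogy, theta1, theta2, TT, HKY parameters,
## branch rates) with the two-epoch coalescent prior. The mean clock rate is
## fixed at 1 so that node times are in substitutions/site and the sampled
## transition time is mutation-scaled; relaxed clocks enter as mean-1
## branch-rate multipliers.
##
## Internal genealogy state: `parent` (0 at root) and `time` vectors over
## nodes 1..2n-1 (tips 1..n at time 0). Because the genealogy is ultrametric
## with strictly increasing internal times, ordering edges by parent time
## yields a valid postorder for the pruning kernel.

#' Default priors for two-epoch model inference
#'
#' theta1, theta2: broad lognormal; TT: uniform(0, tt_max) in subst/site;
#' kappa: lognormal(1, 1.25); Gamma shape alpha: exponential(rate 2);
#' base frequencies: flat Dirichlet; lognormal-relaxed-clock spread:
#' exponential(rate 2).
#'
#' @param tt_max upper bound of the uniform transition-time prior
#'   (substitutions/site).
#' @return named list of prior hyperparameters.
#' @export
tem_default_priors <- function(tt_max = 0.05) {
  list(theta_meanlog = log(0.005), theta_sdlog = 2,
       tt_max = tt_max,
       kappa_meanlog = 1, kappa_sdlog = 1.25,
       alpha_rate = 2,
       spread_rate = 2)
}

## log prior of the scalar parameters (not the genealogy); the two-epoch
## model is an expansion model, so the prior enforces theta1 <= theta2
.tem_log_prior <- function(st, pr, clock_kind) {
  if (st$theta1 > st$theta2) return(-Inf)
  lp <- stats::dlnorm(st$theta1, pr$theta_meanlog, pr$theta_sdlog, log = TRUE) +
    stats::dlnorm(st$theta2, pr$theta_meanlog, pr$theta_sdlog, log = TRUE) +
    stats::dunif(st$tt, 0, pr$tt_max, log = TRUE) +
    stats::dlnorm(st$kappa, pr$kappa_meanlog, pr$kappa_sdlog, log = TRUE) +
    stats::dexp(st$alpha, pr$alpha_rate, log = TRUE)
  if (clock_kind == "lognormal_relaxed") {
    lp <- lp + stats::dexp(st$spread, pr$spread_rate, log = TRUE) +
      sum(stats::dlnorm(st$rates, -st$spread^2 / 2, st$spread, log = TRUE))
  } else if (clock_kind == "exponential_relaxed") {
    lp <- lp + sum(stats::dexp(st$rates, 1, log = TRUE))
  }
  lp
}

.tem_model <- function(st, kind) {
  two_epoch_model(kind, theta_modern = st$theta2, theta_ancient = st$theta1,
                  transition_time = st$tt, logistic_shape = st$tt / 10)
}

## fast vectorized two-epoch N(t) and cumulative intensity (no S3 overhead;
## must stay numerically identical to demographic_size/coalescent_intensity)
.fast_n_lambda <- function(t, kind, th1, th2, tt) {
  if (kind == "logistic") {
    s <- tt / 10
    z <- (t - tt) / s
    pos <- z > 0
    sig <- numeric(length(z))
    sig[pos] <- exp(-z[pos]) / (1 + exp(-z[pos]))
    sig[!pos] <- 1 / (1 + exp(z[!pos]))
    nt <- th1 + (th2 - th1) * sig
    lg <- numeric(length(z))
    lg[pos] <- z[pos] + log(th1 + th2 * exp(-z[pos]))
    lg[!pos] <- log(th2 + th1 * exp(z[!pos]))
    z0 <- -tt / s
    lg0 <- if (z0 > 0) z0 + log(th1 + th2 * exp(-z0)) else
      log(th2 + th1 * exp(z0))
    lam <- (t / th2) + s * (1 / th1 - 1 / th2) * (lg - lg0)
  } else {
    if (th1 == th2) return(list(n = rep(th2, length(t)), lam = t / th2))
    g <- log(th2 / th1) / tt
    below <- t < tt
    nt <- numeric(length(t)); lam <- numeric(length(t))
    nt[below] <- th2 * exp(-g * t[below]); nt[!below] <- th1
    lam_tt <- (exp(g * tt) - 1) / (g * th2)
    lam[below] <- (exp(g * t[below]) - 1) / (g * th2)
    lam[!below] <- lam_tt + (t[!below] - tt) / th1
  }
  list(n = nt, lam = lam)
}

## coalescent prior of the internal-node times
.tem_log_coal <- function(st, kind, n) {
  ct <- sort(st$time[(n + 1L):(2L * n - 1L)])
  nl <- .fast_n_lambda(ct, kind, st$theta1, st$theta2, st$tt)
  k <- n - seq_along(ct) + 1L
  -sum(k * (k - 1) / 2 * diff(c(0, nl$lam))) - sum(log(nl$n))
}

## postorder edges + branch lengths from the internal state
.tem_edges <- function(st, n) {
  child <- setdiff(seq_len(2L * n - 1L), st$root)
  ord <- order(st$time[st$parent[child]], child)
  child <- child[ord]
  cbind(child, st$parent[child])
}

.tem_loglik <- function(st, edges, pat, n) {
  brlen <- (st$time[edges[, 2L]] - st$time[edges[, 1L]]) * st$rates[edges[, 1L]]
  .hky_pruning_cpp(pat$states, pat$weights, edges, brlen,
                   st$kappa, st$bf, st$gamma_rates)
}

## ultrametric starting genealogy from UPGMA of raw distances, with strict
## positive internal times
.initial_state_tree <- function(aln, n) {
  d <- pairwise_differences(aln) / max(1, length(.usable_sites(aln)))
  tr <- phangorn::upgma(stats::as.dist(d))
  tr <- ape::reorder.phylo(tr, "postorder")
  tim <- genealogy_times(tr)
  parent <- integer(2L * n - 1L)
  tipmap <- match(aln$labels, tr$tip.label)
  ## renumber so that tips follow alignment order
  nodemap <- integer(2L * n - 1L)
  nodemap[tipmap] <- seq_len(n)
  nodemap[(n + 1L):(2L * n - 1L)] <- (n + 1L):(2L * n - 1L)
  time2 <- numeric(2L * n - 1L)
  time2[nodemap] <- tim
  for (e in seq_len(nrow(tr$edge)))
    parent[nodemap[tr$edge[e, 2L]]] <- nodemap[tr$edge[e, 1L]]
  root <- which(parent == 0L)
  ## enforce strictly increasing internal times; process children before
  ## parents (UPGMA can return tied node heights, so topological depth
  ## breaks the ties)
  eps <- max(max(time2), 1e-6) * 1e-6
  ints <- (n + 1L):(2L * n - 1L)
  depth <- integer(2L * n - 1L)
  for (v in seq_len(2L * n - 1L)) {
    u <- v
    while (parent[u] != 0L) { depth[v] <- depth[v] + 1L; u <- parent[u] }
  }
  for (v in ints[order(time2[ints], -depth[ints])]) {
    ch <- which(parent == v)
    time2[v] <- max(time2[v], max(time2[ch]) + eps)
  }
  list(parent = parent, time = time2, root = root)
}

## convert an ape phylo into the internal (parent, time, root) arrays with
## tips renumbered to alignment label order
.phylo_to_state <- function(phy, labels, n) {
  stopifnot(ape::Ntip(phy) == n)
  if (!setequal(phy$tip.label, labels))
    stop_invalid("genealogy tips do not match alignment labels")
  tim <- genealogy_times(phy)
  nodemap <- integer(2L * n - 1L)
  nodemap[match(labels, phy$tip.label)] <- seq_len(n)
  nodemap[(n + 1L):(2L * n - 1L)] <- (n + 1L):(2L * n - 1L)
  time2 <- numeric(2L * n - 1L)
  time2[nodemap] <- tim
  parent <- integer(2L * n - 1L)
  for (e in seq_len(nrow(phy$edge)))
    parent[nodemap[phy$edge[e, 2L]]] <- nodemap[phy$edge[e, 1L]]
  list(parent = parent, time = time2, root = which(parent == 0L))
}

## convert internal state to an ape phylo genealogy
.tem_state_phylo <- function(st, labels, n) {
  frag <- as.list(labels)
  names(frag) <- NULL
  node_frag <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) node_frag[[i]] <- labels[i]
  ints <- (n + 1L):(2L * n - 1L)
  for (v in ints[order(st$time[ints])]) {
    ch <- which(st$parent == v)
    parts <- vapply(ch, function(cn)
      sprintf("%s:%.12g", node_frag[[cn]], st$time[v] - st$time[cn]), "")
    node_frag[[v]] <- paste0("(", paste(parts, collapse = ","), ")")
  }
  phy <- ape::read.tree(text = paste0(node_frag[[st$root]], ";"))
  attr(phy, "time_units") <- "substitutions_per_site"
  phy
}

#' MCMC inference of a two-epoch demographic model
#'
#' Metropolis-Hastings sampler over the genealogy, the two-epoch parameters
#' (theta1, theta2, transition time), the HKY+Gamma substitution parameters
#' and (for relaxed clocks) per-branch rate multipliers. The mean clock rate
#' is fixed at 1, so all times are in substitutions/site.
#'
#' @param aln an [alignment()] (>= 4 sequences).
#' @param tem_kind `"logistic"` or `"exponential"`.
#' @param clock_kind `"strict"`, `"lognormal_relaxed"` or
#'   `"exponential_relaxed"`.
#' @param priors prior hyperparameters, see [tem_default_priors()].
#' @param chain list with `steps`, `sample_every`, and optionally
#'   `ess_threshold` (convergence gate, default 100) and `n_chains`
#'   (independent chains run from overdispersed starting points and pooled
#'   after per-chain burn-in, as is common practice for multimodal
#'   genealogy posteriors; default 1, `steps` is the per-chain length).
#'   `heated` (default 0) adds Metropolis-coupled companion chains at data
#'   powers 1/(1 + `heat_delta` * m) with periodic state swaps, which
#'   greatly improves mixing across the expansion-like and diffuse modes
#'   of the transition-time posterior.
#' @param seed integer seed.
#' @param likelihood_power power on the data likelihood (0 samples the
#'   prior; used by stepping-stone marginal likelihoods).
#' @param keep_trees record sampled genealogies as newick strings.
#' @param init optional named list overriding the default initial state:
#'   any of `theta1`, `theta2`, `tt`, `kappa`, `alpha`, `genealogy` (an
#'   ultrametric `phylo` with the alignment's tips).
#' @return object of class `tem_trace`: `samples` (data.frame with state,
#'   posterior, loglik, prior, theta1, theta2, tt, kappa, alpha, spread,
#'   tmrca), `trees`, `acceptance`, `ess`, `converged`, `config`.
#' @export
run_tem_mcmc <- function(aln, tem_kind = c("logistic", "exponential"),
                         clock_kind = c("strict", "lognormal_relaxed",
                                        "exponential_relaxed"),
                         priors = tem_default_priors(),
                         chain = list(steps = 200000, sample_every = 100),
                         seed = NULL, likelihood_power = 1,
                         keep_trees = FALSE, init = NULL) {
  stopifnot(inherits(aln, "alignment"))
  tem_kind <- match.arg(tem_kind)
  clock_kind <- match.arg(clock_kind)
  n <- n_sequences(aln)
  if (n < 4) stop_invalid("need >= 4 sequences")
  steps <- as.integer(chain$steps)
  sample_every <- as.integer(chain$sample_every)
  if (steps < sample_every) stop_invalid("chain length < sample interval")
  ess_threshold <- if (is.null(chain$ess_threshold)) 100 else chain$ess_threshold
  n_chains <- if (is.null(chain$n_chains)) 1L else as.integer(chain$n_chains)
  if (n_chains > 1L) {
    ## overdispersed starts: chain 1 from the data-driven defaults, chain 2
    ## from a strong-expansion configuration, later chains from prior draws
    traces <- vector("list", n_chains)
    for (ci in seq_len(n_chains)) {
      ci_init <- init
      if (ci == 2L) {
        ci_init$theta1 <- 1e-4; ci_init$theta2 <- 0.05
      } else if (ci > 2L) {
        sd_i <- if (!is.null(seed)) split_seed(seed, 500 + ci) else NULL
        if (!is.null(sd_i)) set.seed(sd_i)
        b <- sort(stats::rlnorm(2, priors$theta_meanlog, priors$theta_sdlog))
        ci_init$theta1 <- b[1]; ci_init$theta2 <- b[2]
        ci_init$tt <- stats::runif(1, 0, priors$tt_max)
      }
      ch1 <- chain; ch1$n_chains <- 1L; ch1$ess_threshold <- 0
      traces[[ci]] <- run_tem_mcmc(aln, tem_kind, clock_kind, priors, ch1,
                                   seed = if (!is.null(seed))
                                     split_seed(seed, ci) else NULL,
                                   likelihood_power = likelihood_power,
                                   keep_trees = keep_trees, init = ci_init)
    }
    burn <- function(x) x[-seq_len(ceiling(nrow(x) * 0.1)), , drop = FALSE]
    samples <- do.call(rbind, lapply(traces, function(t) burn(t$samples)))
    trees <- if (keep_trees)
      do.call(c, lapply(traces, function(t)
        t$trees[-seq_len(ceiling(length(t$trees) * 0.1))])) else NULL
    ess <- Reduce(`+`, lapply(traces, function(t) t$ess))
    converged <- all(ess >= ess_threshold)
    if (!converged)
      warning(sprintf("chains may not have converged: min ESS %.1f < %g",
                      min(ess), ess_threshold))
    acceptance <- Reduce(`+`, lapply(traces, function(t)
      t$acceptance)) / n_chains
    return(structure(list(samples = samples, trees = trees,
                          acceptance = acceptance, ess = ess,
                          converged = converged, pooled_burn_in = TRUE,
                          config = list(tem_kind = tem_kind,
                                        clock_kind = clock_kind,
                                        priors = priors, chain = chain,
                                        seed = seed,
                                        likelihood_power = likelihood_power,
                                        n = n, n_sites = n_sites(aln)),
                          aln = aln),
                     class = "tem_trace"))
  }
  if (!is.null(seed)) set.seed(seed)

  pat <- alignment_patterns(aln, seq_len(n))
  init_tree <- if (!is.null(init$genealogy))
    .phylo_to_state(init$genealogy, aln$labels, n)
  else .initial_state_tree(aln, n)
  st <- list(parent = init_tree$parent, time = init_tree$time,
             root = init_tree$root,
             theta1 = 0.002, theta2 = 0.02,
             tt = max(min(priors$tt_max / 2,
                          max(init_tree$time[(n + 1L):(2L * n - 1L)]) / 2),
                      priors$tt_max / 100),
             kappa = 4, alpha = 0.5, bf = .empirical_bf(aln),
             spread = 0.3,
             rates = rep(1, 2L * n - 1L))
  for (nm in intersect(names(init), c("theta1", "theta2", "tt", "kappa",
                                      "alpha")))
    st[[nm]] <- init[[nm]]
  if (clock_kind != "strict") {
    nonroot <- setdiff(seq_len(2L * n - 1L), st$root)
    st$rates[nonroot] <- draw_branch_rates(
      clock_model(clock_kind, 1, st$spread), length(nonroot))
  }
  st$gamma_rates <- phangorn::discrete.gamma(st$alpha, 4L)

  edges <- .tem_edges(st, n)
  cur_ll <- .tem_loglik(st, edges, pat, n)
  cur_coal <- .tem_log_coal(st, tem_kind, n)
  cur_prior <- .tem_log_prior(st, priors, clock_kind)

  moves <- c("theta1", "theta2", "tt", "kappa", "alpha", "bf",
             "slide", "exchange", "rootscale", "treescale", "subtimes")
  wts <- c(2, 2, 3, 1, 1, 1, 6, 4, 1, 2, 4)
  if (clock_kind != "strict") {
    moves <- c(moves, "rate1")
    wts <- c(wts, 5)
    if (clock_kind == "lognormal_relaxed") {
      moves <- c(moves, "spread"); wts <- c(wts, 1)
    }
  }
  wts <- wts / sum(wts)
  acc <- stats::setNames(numeric(length(moves)), moves)
  try_ <- stats::setNames(numeric(length(moves)), moves)

  n_rec <- steps %/% sample_every + 1L
  rec <- matrix(NA_real_, n_rec, 10,
                dimnames = list(NULL, c("state", "posterior", "loglik",
                                        "prior", "theta1", "theta2", "tt",
                                        "kappa", "alpha", "tmrca")))
  spreads <- numeric(n_rec)
  trees <- if (keep_trees) character(n_rec) else NULL
  record <- function(idx, step) {
    rec[idx, ] <<- c(step,
                     likelihood_power * cur_ll + cur_coal + cur_prior,
                     cur_ll, cur_coal + cur_prior,
                     st$theta1, st$theta2, st$tt, st$kappa, st$alpha,
                     st$time[st$root])
    spreads[idx] <<- st$spread
    if (keep_trees) trees[idx] <<- ape::write.tree(.tem_state_phylo(st, aln$labels, n))
  }
  record(1L, 0L)

  ints <- (n + 1L):(2L * n - 1L)
  scale_of <- c(theta1 = 1.5, theta2 = 1.5, tt = 1.2, kappa = 0.5,
                alpha = 0.7, rootscale = 0.4, treescale = 0.25, rate1 = 0.8,
                spread = 0.5)

  ## one Metropolis-Hastings update of a chain state at data power `beta`;
  ## `count` switches acceptance bookkeeping (cold chain only)
  step_one <- function(cst, beta, count) {
    st <- cst$st
    mv <- sample(moves, 1L, prob = wts)
    if (count) try_[mv] <<- try_[mv] + 1
    lhr <- 0          # log Hastings ratio
    new <- st
    need_lik <- FALSE
    ok <- TRUE

    if (mv %in% c("theta1", "theta2", "tt", "kappa", "alpha", "spread")) {
      m <- exp(scale_of[[if (mv %in% names(scale_of)) mv else "tt"]] *
                 (stats::runif(1) - 0.5))
      new[[mv]] <- st[[mv]] * m
      lhr <- log(m)
      if (mv == "tt" && new$tt >= priors$tt_max) ok <- FALSE
      if (mv %in% c("kappa", "alpha")) {
        need_lik <- TRUE
        if (mv == "alpha")
          new$gamma_rates <- phangorn::discrete.gamma(new$alpha, 4L)
      }
    } else if (mv == "bf") {
      ij <- sample.int(4L, 2L)
      d <- stats::runif(1, 0, 0.05)
      new$bf[ij[1L]] <- st$bf[ij[1L]] + d
      new$bf[ij[2L]] <- st$bf[ij[2L]] - d
      if (any(new$bf <= 0.01)) ok <- FALSE
      need_lik <- TRUE
    } else if (mv == "slide") {
      cand <- setdiff(ints, st$root)
      v <- cand[sample.int(length(cand), 1L)]
      ch <- which(st$parent == v)
      lo <- max(st$time[ch]); hi <- st$time[st$parent[v]]
      new$time[v] <- stats::runif(1, lo, hi)
      need_lik <- TRUE
    } else if (mv == "rootscale") {
      r <- st$root
      ch <- which(st$parent == r)
      lo <- max(st$time[ch])
      m <- exp(scale_of[["rootscale"]] * (stats::runif(1) - 0.5))
      new$time[r] <- lo + (st$time[r] - lo) * m
      lhr <- log(m)
      need_lik <- TRUE
    } else if (mv == "treescale") {
      m <- exp(scale_of[["treescale"]] * (stats::runif(1) - 0.5))
      new$time[ints] <- st$time[ints] * m
      lhr <- (n - 1) * log(m)
      need_lik <- TRUE
    } else if (mv == "subtimes") {
      ## rescale the k most recent coalescence times together: lets the
      ## recent part of the genealogy collapse or stretch en masse, which
      ## is the direction separating expansion-like and constant-like modes
      k <- sample.int(n - 2L, 1L)
      m <- exp(1.0 * (stats::runif(1) - 0.5))
      ord <- ints[order(st$time[ints])]
      sel <- ord[seq_len(k)]
      new$time[sel] <- st$time[sel] * m
      ## validity: every non-root node must stay strictly below its parent,
      ## and the scaled set must remain the k most recent events so the
      ## reverse move selects the same set (reversibility)
      nonroot <- setdiff(ints, st$root)
      if (any(new$time[nonroot] >= new$time[st$parent[nonroot]]))
        ok <- FALSE
      if (max(new$time[sel]) >= min(st$time[setdiff(ints, sel)]))
        ok <- FALSE
      lhr <- k * log(m)
      need_lik <- TRUE
    } else if (mv == "exchange") {
      ## narrow exchange: swap a child of p with p's sibling (the uncle)
      cand <- setdiff(ints, st$root)
      p <- cand[sample.int(length(cand), 1L)]
      g <- st$parent[p]
      sibs <- setdiff(which(st$parent == g), p)
      u <- sibs[sample.int(length(sibs), 1L)]
      chp <- which(st$parent == p)
      a <- chp[sample.int(length(chp), 1L)]
      if (st$time[u] >= st$time[p]) { ok <- FALSE } else {
        new$parent[a] <- g
        new$parent[u] <- p
        need_lik <- TRUE
      }
    } else if (mv == "rate1") {
      cand <- setdiff(seq_len(2L * n - 1L), st$root)
      v <- cand[sample.int(length(cand), 1L)]
      m <- exp(scale_of[["rate1"]] * (stats::runif(1) - 0.5))
      new$rates[v] <- st$rates[v] * m
      lhr <- log(m)
      need_lik <- TRUE
    }

    if (ok) {
      new_coal <- .tem_log_coal(new, tem_kind, n)
      new_prior <- .tem_log_prior(new, priors, clock_kind)
      if (is.finite(new_coal) && is.finite(new_prior)) {
        new_ll <- if (need_lik && beta > 0)
          .tem_loglik(new, .tem_edges(new, n), pat, n) else cst$ll
        logr <- beta * (new_ll - cst$ll) +
          (new_coal - cst$coal) + (new_prior - cst$prior) + lhr
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          if (count) acc[mv] <<- acc[mv] + 1
          return(list(st = new, ll = new_ll, coal = new_coal,
                      prior = new_prior))
        }
      }
    }
    cst
  }

  ## Metropolis coupling: optional heated companions at reduced data power
  ## (beta_m = 1/(1 + heat_delta * m)) with periodic state swaps
  n_heated <- if (is.null(chain$heated)) 0L else as.integer(chain$heated)
  heat_delta <- if (is.null(chain$heat_delta)) 0.3 else chain$heat_delta
  betas_heat <- 1 / (1 + heat_delta * (0:n_heated))
  chains <- lapply(seq_len(n_heated + 1L), function(i)
    list(st = st, ll = cur_ll, coal = cur_coal, prior = cur_prior))
  swap_every <- 5L
  n_swap_try <- 0; n_swap_acc <- 0

  for (step in seq_len(steps)) {
    for (m in seq_along(chains))
      chains[[m]] <- step_one(chains[[m]], likelihood_power * betas_heat[m],
                              count = (m == 1L))
    if (n_heated > 0L && step %% swap_every == 0L) {
      i <- sample.int(n_heated, 1L)   # adjacent pair (i, i+1)
      pi_ <- likelihood_power * betas_heat[i]
      pj <- likelihood_power * betas_heat[i + 1L]
      logr <- (pi_ - pj) * (chains[[i + 1L]]$ll - chains[[i]]$ll)
      n_swap_try <- n_swap_try + 1
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        tmp <- chains[[i]]
        chains[[i]] <- chains[[i + 1L]]
        chains[[i + 1L]] <- tmp
        n_swap_acc <- n_swap_acc + 1
      }
    }
    if (step %% sample_every == 0L) {
      st <- chains[[1L]]$st
      cur_ll <- chains[[1L]]$ll
      cur_coal <- chains[[1L]]$coal
      cur_prior <- chains[[1L]]$prior
      record(step %/% sample_every + 1L, step)
    }
  }
  st <- chains[[1L]]$st

  samples <- as.data.frame(rec)
  samples$spread <- spreads
  half <- samples[-seq_len(ceiling(n_rec * 0.1)), ]
  ess <- vapply(c("theta1", "theta2", "tt", "kappa", "alpha", "tmrca",
                  "loglik"),
                function(p) effective_size(half[[p]]), numeric(1))
  converged <- all(ess >= ess_threshold)
  if (!converged)
    warning(sprintf("chain may not have converged: min ESS %.1f < %g",
                    min(ess), ess_threshold))
  structure(list(samples = samples, trees = trees,
                 acceptance = ifelse(try_ > 0, acc / try_, NA),
                 swap_acceptance = if (n_swap_try > 0)
                   n_swap_acc / n_swap_try else NA,
                 ess = ess, converged = converged,
                 config = list(tem_kind = tem_kind, clock_kind = clock_kind,
                               priors = priors, chain = chain, seed = seed,
                               likelihood_power = likelihood_power,
                               n = n, n_sites = n_sites(aln)),
                 aln = aln),
            class = "tem_trace")
}

#' Write an MCMC trace as a tab-separated log
#'
#' Column 1 is the state index, making the file loadable in common
#' trace-inspection tools.
#'
#' @param trace a `tem_trace` or `bsp_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace$samples, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write sampled genealogies as a NEXUS trees block
#'
#' @param trace a trace with recorded trees (`run_tem_mcmc(...,
#'   keep_trees = TRUE)` or any `bsp_trace`), or a list of `phylo` trees.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trees_nexus <- function(trace, path) {
  trees <- if (is.list(trace) && !is.null(trace$trees)) trace$trees else trace
  if (is.null(trees)) stop_invalid("no recorded trees (use keep_trees = TRUE)")
  ape::write.nexus(.as_multiphylo(trees), file = path)
  invisible(path)
}

.empirical_bf <- function(aln) {
  m <- aln$sequences
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), numeric(1))
  counts <- pmax(counts, 1)
  unname(counts / sum(counts))
}

#' @export
print.tem_trace <- function(x, ...) {
  cat(sprintf("Two-epoch MCMC trace: %s TEM, %s clock, %d samples\n",
              x$config$tem_kind, x$config$clock_kind, nrow(x$samples)))
  cat(sprintf("  converged: %s (min ESS %.1f)\n", x$converged, min(x$ess)))
  invisible(x)
}

#' Posterior samples and summaries for one parameter
#'
#' @param trace a `tem_trace` (or any object with a `samples` data.frame).
#' @param parameter column name, e.g. `"tt"`, `"theta1"`, `"tmrca"`.
#' @param burn_in_fraction fraction of records discarded from the start
#'   (default 0.1).
#' @return list with `samples`, `median`, `mean`, `hpd` (95% interval).
#' @export
extract_posterior <- function(trace, parameter, burn_in_fraction = 0.1) {
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop_invalid("burn_in_fraction must be in [0, 1)")
  samples <- trace$samples
  if (!parameter %in% colnames(samples))
    stop_invalid("unknown parameter '%s'", parameter)
  drop <- floor(nrow(samples) * burn_in_fraction)
  x <- samples[[parameter]]
  if (drop > 0) x <- x[-seq_len(drop)]
  list(samples = x, median = stats::median(x), mean = mean(x),
       hpd = hpd_interval(x, 0.95))
}
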