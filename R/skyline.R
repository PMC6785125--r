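## Piecewise-linear Bayesian skyline: the n-1 coalescent intervals are
## partitioned into groups (as evenly as possible, remainder on the oldest
## groups); effective size is specified at the G+1 group boundaries
## (present, each group's last coalescent event) and interpolated linearly.

#' Skyline model structure
#'
#' @param n_samples number of sequences n (the genealogy has n-1 coalescent
#'   events).
#' @param n_groups number of groups (default 10).
#' @param group_population_sizes positive sizes at the G+1 group boundaries
#'   (present first).
#' @return object of class `skyline_model` with fields `n_groups`,
#'   `group_sizes` (events per group, oldest groups get the remainder),
#'   `group_population_sizes`.
#' @export
skyline_model <- function(n_samples, n_groups = 10,
                          group_population_sizes = NULL) {
  n_events <- n_samples - 1L
  if (n_groups < 1 || n_groups > n_events)
    stop_invalid("n_groups must be in [1, n-1]")
  base <- n_events %/% n_groups
  rem <- n_events %% n_groups
  ## oldest groups (last listed) absorb the remainder
  sizes <- rep(base, n_groups) + c(rep(0L, n_groups - rem), rep(1L, rem))
  if (is.null(group_population_sizes))
    group_population_sizes <- rep(1, n_groups + 1L)
  if (length(group_population_sizes) != n_groups + 1L ||
      any(group_population_sizes <= 0))
    stop_invalid("need %d positive boundary sizes", n_groups + 1L)
  structure(list(n_groups = as.integer(n_groups), group_sizes = sizes,
                 group_population_sizes = as.numeric(group_population_sizes)),
            class = "skyline_model")
}

## boundary times: 0, then the last coalescent time of each group
.skyline_boundaries <- function(coal_times, group_sizes) {
  c(0, coal_times[cumsum(group_sizes)])
}

## integral of 1/Ne over [u, v] inside one linear segment (a + b t)
.seg_int <- function(a, b, u, v) {
  if (abs(b) < 1e-300) (v - u) / a
  else log((a + b * v) / (a + b * u)) / b
}

## piecewise-linear Ne evaluation
.skyline_ne <- function(t, bounds, sizes) {
  stats::approx(bounds, sizes, xout = pmin(t, bounds[length(bounds)]),
                rule = 2)$y
}

#' Coalescent log-density under a piecewise-linear skyline
#'
#' @param gen an ultrametric `phylo` genealogy or sorted coalescent times.
#' @param model a [skyline_model()] whose group sizes sum to n-1.
#' @return log-density.
#' @export
skyline_loglik <- function(gen, model) {
  stopifnot(inherits(model, "skyline_model"))
  ct <- if (inherits(gen, "phylo")) {
    tms <- genealogy_times(gen)
    sort(tms[-seq_len(ape::Ntip(gen))])
  } else sort(as.numeric(gen))
  n <- length(ct) + 1L
  if (sum(model$group_sizes) != n - 1L)
    stop_invalid("group sizes sum to %d but genealogy has %d events",
                 sum(model$group_sizes), n - 1L)
  bounds <- .skyline_boundaries(ct, model$group_sizes)
  sizes <- model$group_population_sizes
  ## linear coefficients per segment
  nb <- length(bounds)
  slope <- diff(sizes) / pmax(diff(bounds), 1e-300)
  inter <- sizes[-nb] - slope * bounds[-nb]
  seg_of <- function(t) min(max(findInterval(t, bounds, left.open = TRUE), 1L),
                            nb - 1L)
  ll <- 0
  t_prev <- 0
  for (i in seq_along(ct)) {
    k <- n - i + 1L
    ## integrate 1/Ne from t_prev to ct[i], splitting at boundaries
    u <- t_prev
    acc <- 0
    while (u < ct[i] - 1e-300) {
      sgm <- seg_of(u + (ct[i] - u) * 1e-9)
      v <- min(ct[i], bounds[sgm + 1L])
      acc <- acc + .seg_int(inter[sgm], slope[sgm], u, v)
      u <- v
    }
    ne_i <- .skyline_ne(ct[i], bounds, sizes)
    ll <- ll - k * (k - 1) / 2 * acc - log(ne_i)
    t_prev <- ct[i]
  }
  ll
}

#' Bayesian skyline MCMC
#'
#' Joint MCMC over the genealogy (times in calendar years), HKY+Gamma
#' substitution parameters, the G+1 skyline boundary sizes and the clock
#' rate. The rate is either fixed (`clock_rate` a number, subst/site/year)
#' or sampled under the lognormal CDT prior (`clock_rate` a
#' `rate_distribution_fit`). `clock_kind` adds mean-1 branch-rate
#' multipliers for relaxed clocks.
#'
#' @param aln an [alignment()] (n >= n_groups + 1).
#' @param clock_rate fixed rate (subst/site/year) or a
#'   `rate_distribution_fit` used as the rate prior.
#' @param clock_kind `"strict"`, `"lognormal_relaxed"` or
#'   `"exponential_relaxed"`.
#' @param n_groups skyline groups (default 10).
#' @param chain list with `steps`, `sample_every`, optional `ess_threshold`.
#' @param seed integer seed.
#' @param size_prior lognormal hyperparameters for the boundary sizes
#'   (defaults meanlog log(1e5), sdlog 3).
#' @return object of class `bsp_trace`: `samples` (incl. `rate`,
#'   `tmrca_yr`), `skyline_sizes`, `skyline_bounds` (per-sample matrices),
#'   `trees` (newick, years), `acceptance`, `ess`, `converged`, `config`.
#' @export
run_bsp_mcmc <- function(aln, clock_rate, clock_kind = c("strict",
                                                         "lognormal_relaxed",
                                                         "exponential_relaxed"),
                         n_groups = 10,
                         chain = list(steps = 200000, sample_every = 100),
                         seed = NULL,
                         size_prior = list(meanlog = log(1e5), sdlog = 3)) {
  stopifnot(inherits(aln, "alignment"))
  clock_kind <- match.arg(clock_kind)
  n <- n_sequences(aln)
  if (n < n_groups + 1) stop_invalid("n_groups must be <= n-1")
  steps <- as.integer(chain$steps)
  sample_every <- as.integer(chain$sample_every)
  ess_threshold <- if (is.null(chain$ess_threshold)) 100 else chain$ess_threshold
  if (!is.null(seed)) set.seed(seed)

  fixed_rate <- is.numeric(clock_rate)
  rate_prior <- NULL
  if (!fixed_rate) {
    stopifnot(inherits(clock_rate, "rate_distribution_fit"))
    rate_prior <- list(meanlog = clock_rate$lognormal$LogMean - log(1e6),
                       sdlog = clock_rate$lognormal$LogSD)
  }

  skm <- skyline_model(n, n_groups)
  pat <- alignment_patterns(aln, seq_len(n))
  init <- .initial_state_tree(aln, n)
  r0 <- if (fixed_rate) clock_rate else exp(rate_prior$meanlog)
  st <- list(parent = init$parent, time = init$time / r0, root = init$root,
             rate = r0, kappa = 4, alpha = 0.5, bf = .empirical_bf(aln),
             sizes = rep(max(init$time) / r0 / 2, n_groups + 1L),
             rates = rep(1, 2L * n - 1L), spread = 0.3)
  st$gamma_rates <- phangorn::discrete.gamma(st$alpha, 4L)
  if (clock_kind != "strict") {
    nonroot <- setdiff(seq_len(2L * n - 1L), st$root)
    st$rates[nonroot] <- draw_branch_rates(
      clock_model(clock_kind, 1, st$spread), length(nonroot))
  }
  ints <- (n + 1L):(2L * n - 1L)

  sky_prior <- function(s) {
    lp <- sum(stats::dlnorm(s$sizes, size_prior$meanlog, size_prior$sdlog,
                            log = TRUE)) +
      stats::dlnorm(s$kappa, 1, 1.25, log = TRUE) +
      stats::dexp(s$alpha, 2, log = TRUE)
    if (!fixed_rate)
      lp <- lp + stats::dlnorm(s$rate, rate_prior$meanlog, rate_prior$sdlog,
                               log = TRUE)
    if (clock_kind == "lognormal_relaxed")
      lp <- lp + stats::dexp(s$spread, 2, log = TRUE) +
        sum(stats::dlnorm(s$rates[-s$root], -s$spread^2 / 2, s$spread,
                          log = TRUE))
    if (clock_kind == "exponential_relaxed")
      lp <- lp + sum(stats::dexp(s$rates[-s$root], 1, log = TRUE))
    lp
  }
  sky_coal <- function(s) {
    ct <- sort(s$time[ints])
    skyline_loglik(ct, skyline_model(n, n_groups, s$sizes))
  }
  sky_lik <- function(s) {
    edges <- .tem_edges(s, n)
    brlen <- (s$time[edges[, 2L]] - s$time[edges[, 1L]]) * s$rate *
      s$rates[edges[, 1L]]
    .hky_pruning_cpp(pat$states, pat$weights, edges, brlen,
                     s$kappa, s$bf, s$gamma_rates)
  }

  cur_ll <- sky_lik(st)
  cur_coal <- sky_coal(st)
  cur_prior <- sky_prior(st)

  moves <- c("kappa", "alpha", "bf", "slide", "exchange", "rootscale",
             "treescale", "subtimes", "size1", "sizeall")
  wts <- c(1, 1, 1, 6, 4, 1, 2, 3, 5, 1)
  if (!fixed_rate) { moves <- c(moves, "rate", "ratetree"); wts <- c(wts, 2, 3) }
  if (clock_kind != "strict") { moves <- c(moves, "brate"); wts <- c(wts, 5) }
  if (clock_kind == "lognormal_relaxed") { moves <- c(moves, "spread"); wts <- c(wts, 1) }
  wts <- wts / sum(wts)
  acc <- stats::setNames(numeric(length(moves)), moves)
  try_ <- stats::setNames(numeric(length(moves)), moves)

  n_rec <- steps %/% sample_every + 1L
  rec <- matrix(NA_real_, n_rec, 8,
                dimnames = list(NULL, c("state", "posterior", "loglik",
                                        "prior", "kappa", "alpha", "rate",
                                        "tmrca_yr")))
  sizes_rec <- matrix(NA_real_, n_rec, n_groups + 1L)
  bounds_rec <- matrix(NA_real_, n_rec, n_groups + 1L)
  trees <- character(n_rec)
  record <- function(idx, step) {
    rec[idx, ] <<- c(step, cur_ll + cur_coal + cur_prior, cur_ll,
                     cur_coal + cur_prior, st$kappa, st$alpha, st$rate,
                     st$time[st$root])
    sizes_rec[idx, ] <<- st$sizes
    bounds_rec[idx, ] <<- .skyline_boundaries(sort(st$time[ints]),
                                              skm$group_sizes)
    trees[idx] <<- ape::write.tree(.tem_state_phylo(st, aln$labels, n))
  }
  record(1L, 0L)

  for (step in seq_len(steps)) {
    mv <- sample(moves, 1L, prob = wts)
    try_[mv] <- try_[mv] + 1
    new <- st
    lhr <- 0
    need_lik <- FALSE
    ok <- TRUE

    if (mv %in% c("kappa", "alpha", "spread")) {
      m <- exp(0.6 * (stats::runif(1) - 0.5))
      new[[mv]] <- st[[mv]] * m
      lhr <- log(m)
      if (mv != "spread") {
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
      new$time[v] <- stats::runif(1, max(st$time[ch]), st$time[st$parent[v]])
      need_lik <- TRUE
    } else if (mv == "exchange") {
      cand <- setdiff(ints, st$root)
      p <- cand[sample.int(length(cand), 1L)]
      g <- st$parent[p]
      u <- setdiff(which(st$parent == g), p)[1L]
      chp <- which(st$parent == p)
      a <- chp[sample.int(length(chp), 1L)]
      if (st$time[u] >= st$time[p]) ok <- FALSE
      else { new$parent[a] <- g; new$parent[u] <- p; need_lik <- TRUE }
    } else if (mv == "rootscale") {
      r <- st$root
      lo <- max(st$time[which(st$parent == r)])
      m <- exp(0.4 * (stats::runif(1) - 0.5))
      new$time[r] <- lo + (st$time[r] - lo) * m
      lhr <- log(m)
      need_lik <- TRUE
    } else if (mv == "treescale") {
      m <- exp(0.25 * (stats::runif(1) - 0.5))
      new$time[ints] <- st$time[ints] * m
      lhr <- (n - 1) * log(m)
      need_lik <- TRUE
    } else if (mv == "subtimes") {
      ## joint rescale of the k most recent coalescence times (reversible:
      ## the scaled set must remain the k most recent)
      k <- sample.int(n - 2L, 1L)
      m <- exp(1.0 * (stats::runif(1) - 0.5))
      ord <- ints[order(st$time[ints])]
      sel <- ord[seq_len(k)]
      new$time[sel] <- st$time[sel] * m
      nonroot <- setdiff(ints, st$root)
      if (any(new$time[nonroot] >= new$time[st$parent[nonroot]]) ||
          max(new$time[sel]) >= min(st$time[setdiff(ints, sel)]))
        ok <- FALSE
      lhr <- k * log(m)
      need_lik <- TRUE
    } else if (mv == "size1") {
      j <- sample.int(n_groups + 1L, 1L)
      m <- exp(1.2 * (stats::runif(1) - 0.5))
      new$sizes[j] <- st$sizes[j] * m
      lhr <- log(m)
    } else if (mv == "sizeall") {
      m <- exp(0.8 * (stats::runif(1) - 0.5))
      new$sizes <- st$sizes * m
      lhr <- (n_groups + 1L) * log(m)
    } else if (mv == "rate") {
      m <- exp(0.5 * (stats::runif(1) - 0.5))
      new$rate <- st$rate * m
      lhr <- log(m)
      need_lik <- TRUE
    } else if (mv == "ratetree") {
      ## rescale rate up, tree times down: branch substitutions unchanged
      m <- exp(0.4 * (stats::runif(1) - 0.5))
      new$rate <- st$rate * m
      new$time[ints] <- st$time[ints] / m
      lhr <- log(m) - (n - 1) * log(m)
    } else if (mv == "brate") {
      cand <- setdiff(seq_len(2L * n - 1L), st$root)
      v <- cand[sample.int(length(cand), 1L)]
      m <- exp(0.8 * (stats::runif(1) - 0.5))
      new$rates[v] <- st$rates[v] * m
      lhr <- log(m)
      need_lik <- TRUE
    }

    if (ok) {
      new_coal <- sky_coal(new)
      new_prior <- sky_prior(new)
      if (is.finite(new_coal) && is.finite(new_prior)) {
        new_ll <- if (need_lik) sky_lik(new) else cur_ll
        logr <- (new_ll - cur_ll) + (new_coal - cur_coal) +
          (new_prior - cur_prior) + lhr
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          st <- new; cur_ll <- new_ll; cur_coal <- new_coal
          cur_prior <- new_prior
          acc[mv] <- acc[mv] + 1
        }
      }
    }
    if (step %% sample_every == 0L) record(step %/% sample_every + 1L, step)
  }

  samples <- as.data.frame(rec)
  half <- samples[-seq_len(ceiling(n_rec * 0.1)), ]
  pars <- c("kappa", "alpha", "tmrca_yr", "loglik")
  if (!fixed_rate) pars <- c(pars, "rate")
  ess <- vapply(pars, function(p) effective_size(half[[p]]), numeric(1))
  converged <- all(ess >= ess_threshold)
  if (!converged)
    warning(sprintf("chain may not have converged: min ESS %.1f < %g",
                    min(ess), ess_threshold))
  structure(list(samples = samples, skyline_sizes = sizes_rec,
                 skyline_bounds = bounds_rec, trees = trees,
                 acceptance = ifelse(try_ > 0, acc / try_, NA),
                 ess = ess, converged = converged,
                 config = list(clock_kind = clock_kind, n_groups = n_groups,
                               fixed_rate = fixed_rate, chain = chain,
                               seed = seed, n = n)),
            class = "bsp_trace")
}

#' @export
print.bsp_trace <- function(x, ...) {
  cat(sprintf("Bayesian skyline trace: %d samples, %d groups, %s rate\n",
              nrow(x$samples), x$config$n_groups,
              if (x$config$fixed_rate) "fixed" else "CDT-prior"))
  invisible(x)
}

#' Summarize a skyline posterior into a demographic trajectory
#'
#' Evaluates each post-burn-in sample's piecewise-linear Ne on a common
#' calendar grid (0 to the 97.5% TMRCA quantile) and returns per-time
#' median and 95% HPD. Sizes are divided by `generation_time` to convert
#' the year-scaled coalescent sizes into effective numbers of individuals.
#'
#' @param trace a `bsp_trace`.
#' @param grid number of grid points (default 200).
#' @param burn_in_fraction burn-in (default 0.1).
#' @param generation_time generation time in years (default 1).
#' @return object of class `skyline_trajectory`: data.frame `trajectory`
#'   (time_yr_bp, ne_median, ne_hpd_lo, ne_hpd_hi) plus `tmrca` summary.
#' @export
summarize_trajectory <- function(trace, grid = 200, burn_in_fraction = 0.1,
                                 generation_time = 1) {
  stopifnot(inherits(trace, "bsp_trace"))
  if (grid < 2) stop_invalid("grid must be >= 2")
  keep <- seq_len(nrow(trace$samples))
  drop <- floor(length(keep) * burn_in_fraction)
  if (drop > 0) keep <- keep[-seq_len(drop)]
  tmrca <- trace$samples$tmrca_yr[keep]
  tmax <- stats::quantile(tmrca, 0.975)
  tgrid <- seq(0, tmax, length.out = grid)
  ne <- vapply(keep, function(i) {
    .skyline_ne(tgrid, trace$skyline_bounds[i, ], trace$skyline_sizes[i, ]) /
      generation_time
  }, numeric(grid))
  med <- apply(ne, 1, stats::median)
  hpd <- apply(ne, 1, hpd_interval)
  structure(list(trajectory = data.frame(time_yr_bp = tgrid, ne_median = med,
                                         ne_hpd_lo = hpd[1, ],
                                         ne_hpd_hi = hpd[2, ]),
                 tmrca = list(median = stats::median(tmrca),
                              hpd = hpd_interval(tmrca))),
            class = "skyline_trajectory")
}

#' Write a skyline trajectory as TSV
#' @param traj a `skyline_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(traj$trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## ---- MCC tree and split times ------------------------------------------

.as_multiphylo <- function(trees) {
  if (inherits(trees, "multiPhylo")) return(trees)
  if (inherits(trees, "phylo")) return(structure(list(trees),
                                                 class = "multiPhylo"))
  if (is.character(trees)) {
    tl <- ape::read.tree(text = trees)
    if (inherits(tl, "phylo")) tl <- structure(list(tl), class = "multiPhylo")
    return(tl)
  }
  if (is.list(trees) && length(trees) &&
      all(vapply(trees, inherits, logical(1), "phylo")))
    return(structure(trees, class = "multiPhylo"))
  stop_invalid("trees must be newick strings, phylo or multiPhylo")
}

#' Maximum clade credibility tree with median node heights
#'
#' Scores every sampled topology by the sum of log clade posterior
#' frequencies (clades from [ape::prop.part()]) and returns the
#' best-scoring sampled tree with each internal node's height replaced by
#' the median height of its clade across all trees containing that clade.
#'
#' @param trees posterior tree sample (newick character vector, `phylo` or
#'   `multiPhylo`); shared tip set required.
#' @param burn_in_fraction fraction of trees discarded from the start.
#' @return the MCC `phylo` tree; attribute `mcc_log_score` holds its score.
#' @export
mcc_tree <- function(trees, burn_in_fraction = 0) {
  tl <- .as_multiphylo(trees)
  drop <- floor(length(tl) * burn_in_fraction)
  if (drop > 0) tl <- tl[-seq_len(drop)]
  if (length(tl) < 1) stop_invalid("no post-burn-in trees")
  tipsets <- lapply(tl, function(t) sort(t$tip.label))
  if (length(unique(vapply(tipsets, paste, "", collapse = ","))) != 1)
    stop_invalid("inconsistent tip sets across trees")
  nt <- length(tl)
  ## clade table: key = sorted tip labels of each internal node
  clade_freq <- new.env(hash = TRUE)
  clade_heights <- new.env(hash = TRUE)
  tree_clades <- vector("list", nt)
  for (i in seq_len(nt)) {
    tr <- tl[[i]]
    tms <- genealogy_times(tr)
    ntip <- ape::Ntip(tr)
    keys <- character(tr$Nnode)
    for (v in seq_len(tr$Nnode)) {
      node <- ntip + v
      tips <- ape::extract.clade(tr, node)$tip.label
      key <- paste(sort(tips), collapse = "|")
      keys[v] <- key
      clade_freq[[key]] <- (if (is.null(clade_freq[[key]])) 0 else
        clade_freq[[key]]) + 1
      clade_heights[[key]] <- c(clade_heights[[key]], tms[node])
    }
    tree_clades[[i]] <- keys
  }
  scores <- vapply(seq_len(nt), function(i)
    sum(log(vapply(tree_clades[[i]], function(k) clade_freq[[k]],
                   numeric(1)) / nt)), numeric(1))
  best <- which.max(scores)
  tr <- tl[[best]]
  ntip <- ape::Ntip(tr)
  ## set node heights to per-clade medians
  heights <- numeric(ntip + tr$Nnode)
  for (v in seq_len(tr$Nnode))
    heights[ntip + v] <- stats::median(clade_heights[[tree_clades[[best]][v]]])
  for (e in seq_len(nrow(tr$edge)))
    tr$edge.length[e] <- max(heights[tr$edge[e, 1]] - heights[tr$edge[e, 2]],
                             0)
  attr(tr, "mcc_log_score") <- scores[best]
  tr
}

#' Posterior of a clade's TMRCA (population split time)
#'
#' For each posterior tree the height of the most recent common ancestor of
#' `taxa` is extracted and, when the trees are mutation-scaled, converted to
#' calendar years by dividing by a rate (per-tree rates, independent draws
#' from a `rate_distribution_fit`, or a single fixed rate). The fraction of
#' trees in which `taxa` is monophyletic is reported alongside.
#'
#' @param trees posterior tree sample.
#' @param taxa tip labels of the clade (e.g. one population's individuals).
#' @param rate_samples `NULL` (trees already in years), a single rate, a
#'   vector of per-tree rates (subst/site/year), or a
#'   `rate_distribution_fit` to draw from.
#' @param burn_in_fraction fraction of trees dropped from the start.
#' @param seed integer seed (used when drawing from a fit).
#' @return object of class `split_time_posterior`: `samples` (years BP),
#'   `median`, `ci95` (central), `hpd`, `monophyly_frequency`.
#' @export
clade_tmrca_posterior <- function(trees, taxa, rate_samples = NULL,
                                  burn_in_fraction = 0, seed = NULL) {
  tl <- .as_multiphylo(trees)
  drop <- floor(length(tl) * burn_in_fraction)
  if (drop > 0) tl <- tl[-seq_len(drop)]
  if (length(taxa) < 1) stop_invalid("taxa must be nonempty")
  miss <- setdiff(taxa, tl[[1]]$tip.label)
  if (length(miss)) stop_invalid("unknown taxa: %s", paste(miss, collapse = ","))
  nt <- length(tl)
  heights <- numeric(nt)
  mono <- logical(nt)
  for (i in seq_len(nt)) {
    tr <- tl[[i]]
    tms <- genealogy_times(tr)
    if (length(taxa) == 1L) {
      heights[i] <- 0; mono[i] <- TRUE; next
    }
    node <- if (length(taxa) == ape::Ntip(tr))
      ape::Ntip(tr) + 1L else ape::getMRCA(tr, taxa)
    heights[i] <- tms[node]
    mono[i] <- length(ape::extract.clade(tr, node)$tip.label) == length(taxa)
  }
  if (!is.null(rate_samples)) {
    rates <- if (inherits(rate_samples, "rate_distribution_fit"))
      sample_cdt_rates(rate_samples, nt, seed)
    else if (length(rate_samples) == 1L) rep(rate_samples, nt)
    else if (length(rate_samples) == nt) rate_samples
    else stop_invalid("rate_samples length must be 1 or the number of trees")
    heights <- heights / rates
  }
  structure(list(samples = heights, median = stats::median(heights),
                 ci95 = stats::quantile(heights, c(0.025, 0.975)),
                 hpd = hpd_interval(heights),
                 monophyly_frequency = mean(mono)),
            class = "split_time_posterior")
}

#' @export
print.split_time_posterior <- function(x, ...) {
  cat(sprintf("Split-time posterior: median %.0f, 95%% CI [%.0f, %.0f], monophyly %.2f\n",
              x$median, x$ci95[1], x$ci95[2], x$monophyly_frequency))
  invisible(x)
}
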