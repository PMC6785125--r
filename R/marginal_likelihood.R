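#' Stepping-stone marginal-likelihood estimator from power-posterior samples
#'
#' Given log-likelihood samples drawn under the power posteriors at each
#' rung beta_k (prior at 0, posterior at 1), the log marginal likelihood is
#' the sum over rungs of log mean exp((beta_(k+1) - beta_k) * loglik),
#' evaluated with the samples of the lower rung (Xie et al. 2011).
#'
#' @param loglik_by_beta list of numeric vectors; element k holds data
#'   log-likelihood values sampled under power `betas[k]`.
#' @param betas increasing vector of powers starting at 0 and ending at 1;
#'   samples are needed for all but the last rung.
#' @return log marginal likelihood estimate.
#' @export
stepping_stone_ml <- function(loglik_by_beta, betas) {
  K <- length(betas)
  stopifnot(K >= 2, abs(betas[1]) < 1e-12, abs(betas[K] - 1) < 1e-12,
            length(loglik_by_beta) >= K - 1)
  total <- 0
  for (k in seq_len(K - 1)) {
    ll <- loglik_by_beta[[k]]
    db <- betas[k + 1] - betas[k]
    total <- total + (logsumexp(db * ll) - log(length(ll)))
  }
  total
}

## harmonic-mean log marginal likelihood (Tracer parity; high variance)
harmonic_mean_ml <- function(loglik) {
  -(logsumexp(-loglik) - log(length(loglik)))
}

#' Marginal likelihood of a two-epoch model run
#'
#' `"harmonic_mean"` uses the recorded post-burn-in likelihood trace (the
#' estimator used by common trace-analysis tools; fast but high-variance).
#' `"stepping_stone"` (recommended) re-runs shortened chains at a ladder of
#' likelihood powers beta_k = (k/K)^(1/0.3) and applies
#' [stepping_stone_ml()]. The reported value is the median of bootstrap
#' replicates (median marginal likelihood, MML) with a bootstrap standard
#' error.
#'
#' @param trace a `tem_trace` from [run_tem_mcmc()].
#' @param method `"stepping_stone"` or `"harmonic_mean"`.
#' @param power_ladder list with `n_powers` (default 16) and
#'   `steps_per_power` (default a quarter of the original chain).
#' @param burn_in_fraction burn-in fraction (default 0.1).
#' @param n_boot bootstrap replicates for the SE (default 100).
#' @return list with `estimate` (MML), `se`, `method`, `boot`.
#' @export
marginal_likelihood <- function(trace,
                                method = c("stepping_stone", "harmonic_mean"),
                                power_ladder = list(),
                                burn_in_fraction = 0.1, n_boot = 100) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "tem_trace"))
  if (nrow(trace$samples) < 2) stop_invalid("empty trace")
  if (method == "harmonic_mean") {
    ll <- extract_posterior(trace, "loglik", burn_in_fraction)$samples
    boot <- vapply(seq_len(n_boot), function(b)
      harmonic_mean_ml(sample(ll, replace = TRUE)), numeric(1))
    return(list(estimate = stats::median(boot), se = stats::sd(boot),
                method = method, boot = boot))
  }
  K <- if (is.null(power_ladder$n_powers)) 16L else power_ladder$n_powers
  steps <- if (is.null(power_ladder$steps_per_power))
    max(2000L, trace$config$chain$steps %/% 4L) else power_ladder$steps_per_power
  betas <- (seq(0, K) / K)^(1 / 0.3)
  cfg <- trace$config
  ll_by_beta <- vector("list", K)
  for (k in seq_len(K)) {
    seed_k <- if (!is.null(cfg$seed)) split_seed(cfg$seed, 1000 + k) else NULL
    tr <- run_tem_mcmc(trace$aln, cfg$tem_kind, cfg$clock_kind, cfg$priors,
                       chain = list(steps = steps,
                                    sample_every = max(10L, steps %/% 500L),
                                    ess_threshold = 0),
                       seed = seed_k, likelihood_power = betas[k])
    ll_by_beta[[k]] <- extract_posterior(tr, "loglik", burn_in_fraction)$samples
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    res <- lapply(ll_by_beta, function(x) sample(x, replace = TRUE))
    stepping_stone_ml(res, betas)
  }, numeric(1))
  list(estimate = stats::median(boot), se = stats::sd(boot), method = method,
       boot = boot)
}

#' Compare two-epoch model runs by Bayes factors
#'
#' Builds the pairwise 2 ln BF matrix 2 (lnML_i - lnML_j) from per-model
#' marginal-likelihood estimates and identifies the best model (maximum
#' MML). The matrix is antisymmetric by construction.
#'
#' @param mml named numeric vector of log marginal likelihoods, or a list of
#'   `tem_trace` objects (marginal likelihoods are then computed with
#'   [marginal_likelihood()] and `...` passed on).
#' @param ... forwarded to [marginal_likelihood()] when traces are given.
#' @return object of class `model_comparison`: `mml`, `bayes_factors`
#'   (2 ln BF matrix), `best`, `convergence` (flags when traces carry them).
#' @export
compare_models <- function(mml, ...) {
  convergence <- NULL
  if (is.list(mml) && length(mml) && inherits(mml[[1]], "tem_trace")) {
    convergence <- vapply(mml, function(t) isTRUE(t$converged), logical(1))
    vals <- vapply(mml, function(t) marginal_likelihood(t, ...)$estimate,
                   numeric(1))
    nm <- names(mml)
    if (is.null(nm))
      nm <- vapply(mml, function(t)
        paste(t$config$tem_kind, t$config$clock_kind, sep = "+"), "")
    names(vals) <- nm
    mml <- vals
  }
  if (!is.numeric(mml) || length(mml) < 1) stop_invalid("need MML estimates")
  if (any(!is.finite(mml))) stop_invalid("missing MML estimate")
  k <- length(mml)
  bf <- outer(mml, mml, function(a, b) 2 * (a - b))
  if (k == 1) bf <- matrix(numeric(0), 0, 0)
  structure(list(mml = mml, bayes_factors = bf,
                 best = names(mml)[which.max(mml)],
                 convergence = convergence),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (2 ln Bayes factors):\n")
  print(round(x$bayes_factors, 2))
  cat("Best model:", x$best, "\n")
  invisible(x)
}
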