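#' @useDynLib cdtem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rexp rnorm rbinom rmultinom approx integrate
#'   uniroot median quantile sd var acf dlnorm dnorm dexp dunif optimize
#'   ks.test setNames aggregate
#' @importFrom utils write.table read.table head tail
NULL

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Shortest highest-posterior-density interval
#'
#' Computes the HPD interval of a univariate sample by the shortest-interval
#' method on the sorted draws.
#'
#' @param x numeric vector of posterior draws.
#' @param prob target probability mass (default 0.95).
#' @return length-2 numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 1, prob > 0, prob <= 1)
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Effective sample size of an MCMC scalar trace
#'
#' Autocorrelation-based ESS: n / (1 + 2 * sum of positive-lag
#' autocorrelations), truncated at the first non-positive value
#' (initial positive sequence estimator).
#'
#' @param x numeric vector of sequential MCMC samples.
#' @return effective sample size (numeric, <= length(x)).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 2000L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Derive a child seed from a root seed
#'
#' Deterministic seed splitting: all package randomness in fixture sets and
#' pipelines flows from one root seed through this function (repeated
#' 31-bit multiplicative congruential steps, so results stay valid R
#' integer seeds).
#'
#' @param seed root seed (integer).
#' @param index child index (>= 1).
#' @return derived integer seed.
#' @export
split_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (i in seq_len(index)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
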