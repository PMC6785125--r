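## shared builders for the test suite; everything is generated in code

hky_subst <- function() substitution_model(kappa = 10,
                                           base_frequencies = c(0.25, 0.15,
                                                                0.2, 0.4),
                                           gamma_shape = 0.2)

constant_model <- function(theta = 1)
  two_epoch_model("exponential", theta_modern = theta, theta_ancient = theta,
                  transition_time = 1e-3)

expansion_model <- function(theta_modern = 5e-2, theta_ancient = 5e-4,
                            tt = 2.5e-4, kind = "logistic")
  two_epoch_model(kind, theta_modern = theta_modern,
                  theta_ancient = theta_ancient, transition_time = tt)

## random valid two-epoch model for property tests
random_tem <- function(kind) {
  th1 <- exp(stats::runif(1, log(1e-4), log(1e-2)))
  th2 <- th1 * exp(stats::runif(1, 0, log(200)))
  tt <- exp(stats::runif(1, log(1e-4), log(5e-3)))
  two_epoch_model(kind, theta_modern = th2, theta_ancient = th1,
                  transition_time = tt)
}

## quadrature oracle for the two-epoch coalescent log-density, independent
## of the closed-form intensity used by the package
coal_loglik_quadrature <- function(gen, model) {
  ct <- sort(genealogy_times(gen)[-(seq_len(ape::Ntip(gen)))])
  n <- length(ct) + 1L
  f <- function(t) 1 / demographic_size(model, t)
  ll <- 0
  t_prev <- 0
  for (i in seq_along(ct)) {
    k <- n - i + 1L
    I <- stats::integrate(f, t_prev, ct[i], rel.tol = 1e-12,
                          subdivisions = 2000L)$value
    ll <- ll - k * (k - 1) / 2 * I - log(demographic_size(model, ct[i]))
    t_prev <- ct[i]
  }
  ll
}

## independent HKY transition matrix via numeric eigendecomposition of the
## explicitly assembled generator (R-side route, distinct from the C++
## analytic formulas)
hky_pmat_oracle <- function(t, kappa, bf) hky_transition_matrix(t, kappa, bf)

## tiny alignment helper
aln_from_strings <- function(x, labels = NULL, populations = NULL)
  alignment(x, labels = labels, populations = populations)
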