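#' Two-epoch demographic model
#'
#' A coalescent demographic function N(t) with a constant ancient epoch of
#' (mutation-scaled) size `theta_ancient` and a modern growth epoch reaching
#' `theta_modern` at the present. Time `t` runs backwards from the present in
#' substitutions/site. Two growth laws are supported:
#'
#' * `"logistic"`: N(t) = theta_ancient + (theta_modern - theta_ancient) /
#'   (1 + exp((t - transition_time)/logistic_shape)), so the transition time
#'   is the inflection (half-growth) point of the sigmoid.
#' * `"exponential"`: N(t) = theta_modern * exp(-g t) for t < transition_time
#'   and theta_ancient for t >= transition_time, with g fixed by continuity at
#'   the transition (g = log(theta_modern/theta_ancient)/transition_time).
#'
#' The degenerate case theta_ancient == theta_modern evaluates to a constant
#' size for both kinds.
#'
#' @param kind `"exponential"` or `"logistic"`.
#' @param theta_modern present-day mutation-scaled population size (> 0).
#' @param theta_ancient ancient mutation-scaled population size (> 0, usually
#'   <= theta_modern for an expansion).
#' @param transition_time onset of growth, substitutions/site (> 0).
#' @param logistic_shape steepness of the logistic sigmoid in the same time
#'   units; ignored for the exponential kind. Defaults to transition_time/10,
#'   a sharp but smooth transition.
#' @return an object of class `two_epoch_model`.
#' @export
two_epoch_model <- function(kind = c("logistic", "exponential"),
                            theta_modern, theta_ancient, transition_time,
                            logistic_shape = transition_time / 10) {
  kind <- match.arg(kind)
  if (!is.numeric(theta_modern) || theta_modern <= 0)
    stop_invalid("theta_modern must be > 0")
  if (!is.numeric(theta_ancient) || theta_ancient <= 0)
    stop_invalid("theta_ancient must be > 0")
  if (!is.numeric(transition_time) || transition_time <= 0)
    stop_invalid("transition_time must be > 0")
  if (kind == "logistic" && (!is.numeric(logistic_shape) || logistic_shape <= 0))
    stop_invalid("logistic_shape must be > 0")
  structure(list(kind = kind, theta_modern = theta_modern,
                 theta_ancient = theta_ancient,
                 transition_time = transition_time,
                 logistic_shape = logistic_shape),
            class = "two_epoch_model")
}

#' @export
print.two_epoch_model <- function(x, ...) {
  cat(sprintf("Two-epoch demographic model (%s growth)\n", x$kind))
  cat(sprintf("  theta_modern   : %g\n", x$theta_modern))
  cat(sprintf("  theta_ancient  : %g\n", x$theta_ancient))
  cat(sprintf("  transition time: %g subst/site\n", x$transition_time))
  if (x$kind == "logistic")
    cat(sprintf("  logistic shape : %g\n", x$logistic_shape))
  invisible(x)
}

#' Population size at time t under a two-epoch model
#'
#' @param model a [two_epoch_model()].
#' @param t time(s) before present, same units as the model (>= 0).
#' @return N(t), vectorized over `t`.
#' @export
demographic_size <- function(model, t) {
  stopifnot(inherits(model, "two_epoch_model"))
  if (any(t < 0)) stop_invalid("t must be >= 0")
  th2 <- model$theta_modern; th1 <- model$theta_ancient
  tt <- model$transition_time
  if (model$kind == "logistic") {
    s <- model$logistic_shape
    ## stable sigmoid evaluation
    z <- (t - tt) / s
    sig <- ifelse(z > 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    th1 + (th2 - th1) * sig
  } else {
    if (th1 == th2) return(rep(th2, length(t)))
    g <- log(th2 / th1) / tt
    ifelse(t < tt, th2 * exp(-g * t), th1)
  }
}

## log(theta2 + theta1 * exp(z)) computed without overflow
.log_th2_plus_th1ez <- function(th1, th2, z) {
  ifelse(z > 0, z + log(th1 + th2 * exp(-z)), log(th2 + th1 * exp(z)))
}

#' Cumulative coalescent intensity of a two-epoch model
#'
#' Evaluates Lambda(t) = integral from 0 to t of 1/N(u) du in closed form.
#' The pairwise coalescent rate over an interval is Lambda multiplied by
#' k(k-1)/2 for k lineages.
#'
#' @param model a [two_epoch_model()].
#' @param t time(s) >= 0.
#' @return Lambda(t), vectorized over `t`.
#' @export
coalescent_intensity <- function(model, t) {
  stopifnot(inherits(model, "two_epoch_model"))
  if (any(t < 0)) stop_invalid("t must be >= 0")
  th2 <- model$theta_modern; th1 <- model$theta_ancient
  tt <- model$transition_time
  if (model$kind == "logistic") {
    s <- model$logistic_shape
    ## antiderivative of 1/N for N = (th2 + th1*u)/(1+u), u = exp((t-tt)/s):
    ## F(t) = (t-tt)/th2 + s*(1/th1 - 1/th2)*log(th2 + th1*u)
    Fof <- function(tv) {
      z <- (tv - tt) / s
      (tv - tt) / th2 + s * (1 / th1 - 1 / th2) * .log_th2_plus_th1ez(th1, th2, z)
    }
    Fof(t) - Fof(0)
  } else {
    if (th1 == th2) return(t / th2)
    g <- log(th2 / th1) / tt
    ## below tt: int 1/(th2 e^{-g u}) = (e^{g t} - 1)/(g th2)
    lam_tt <- (exp(g * tt) - 1) / (g * th2)
    ifelse(t < tt, (exp(g * t) - 1) / (g * th2), lam_tt + (t - tt) / th1)
  }
}

## invert Lambda(t) = target (target > 0); Lambda strictly increasing
invert_intensity <- function(model, target, t_lower = 0) {
  lam0 <- coalescent_intensity(model, t_lower)
  goal <- lam0 + target
  ## bracket: population size is bounded, so Lambda grows at least linearly
  ## with slope 1/max(theta); step out geometrically
  hi <- max(model$transition_time, t_lower, 1e-12) * 2
  while (coalescent_intensity(model, hi) < goal) hi <- hi * 2
  stats::uniroot(function(x) coalescent_intensity(model, x) - goal,
                 lower = t_lower, upper = hi, tol = 1e-14)$root
}
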