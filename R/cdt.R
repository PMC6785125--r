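## Calibration of demographic transition (CDT): convert the mutation-scaled
## transition-time posterior into a calendar substitution-rate distribution
## using expansion dates drawn from the warming rate of a temperature proxy.

#' Temperature proxy record
#'
#' @param ages years before present, strictly increasing, >= 0.
#' @param temperatures temperature anomaly (deg C) aligned to `ages`.
#' @return object of class `temperature_record`.
#' @export
temperature_record <- function(ages, temperatures) {
  stopifnot(length(ages) == length(temperatures), length(ages) >= 2)
  if (any(ages < 0)) stop_invalid("ages must be >= 0")
  if (any(diff(ages) <= 0)) stop_invalid("ages must be strictly increasing")
  structure(list(ages = as.numeric(ages),
                 temperatures = as.numeric(temperatures)),
            class = "temperature_record")
}

#' Synthetic glacial-interglacial temperature record
#'
#' Sigmoidal warming from a cold glacial baseline to the present, centred at
#' `warming_onset`, with `warming_width` the 10-90% transition width and
#' optional additive Gaussian noise. Emulates the rapid post-glacial warming
#' of polar proxy records.
#'
#' @param warming_onset centre of the warming ramp, years BP.
#' @param warming_width 10-90% width of the ramp, years (> 0).
#' @param amplitude total warming, deg C.
#' @param noise_sd additive noise SD, deg C (0 for a deterministic record).
#' @param span oldest age, years BP (default 25000).
#' @param step grid step, years (default 100).
#' @param seed integer seed for the noise.
#' @return a [temperature_record()].
#' @export
synth_temperature <- function(warming_onset = 12000, warming_width = 1000,
                              amplitude = 8, noise_sd = 0, span = 25000,
                              step = 100, seed = NULL) {
  if (warming_width <= 0) stop_invalid("warming_width must be > 0")
  if (warming_onset <= 0 || warming_onset >= span)
    stop_invalid("warming_onset must lie inside (0, span)")
  if (step <= 0) stop_invalid("step must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ages <- seq(0, span, by = step)
  s <- warming_width / (2 * log(9))   # logistic scale from the 10-90% width
  temp <- amplitude / (1 + exp((ages - warming_onset) / s)) - amplitude
  if (noise_sd > 0) temp <- temp + stats::rnorm(length(ages), 0, noise_sd)
  temperature_record(ages, temp)
}

#' Read a temperature record from a two-column CSV
#'
#' Expected columns: `age_yr_bp`, `temp_anomaly_c` (header required).
#'
#' @param path CSV path.
#' @return a [temperature_record()].
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  tab <- utils::read.table(path, sep = ",", header = TRUE)
  if (ncol(tab) < 2) stop_invalid("temperature CSV needs 2 columns")
  ord <- order(tab[[1]])
  temperature_record(tab[[1]][ord], tab[[2]][ord])
}

#' Write a temperature record as CSV
#' @param record a [temperature_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(record, path) {
  utils::write.table(data.frame(age_yr_bp = record$ages,
                                temp_anomaly_c = record$temperatures),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Warming-rate weights over a calendar-age grid
#'
#' Interpolates the record onto a regular grid and weights each grid age by
#' the rate of warming toward the present (central differences; one-sided at
#' the boundaries), clamped at zero during cooling intervals and normalized
#' to sum to one. These weights are the discretized "change rate of
#' temperature" from which expansion dates are drawn.
#'
#' @param record a [temperature_record()].
#' @param window `c(young, old)` age window in years BP (default
#'   c(0, 25000)).
#' @param grid_step grid step in years (default 100).
#' @return list with `ages` (grid) and `weights` (sum 1).
#' @export
warming_rate_weights <- function(record, window = c(0, 25000),
                                 grid_step = 100) {
  stopifnot(inherits(record, "temperature_record"))
  if (grid_step <= 0) stop_invalid("grid_step must be > 0")
  if (window[1] < min(record$ages) - 1e-9 || window[2] > max(record$ages) + 1e-9)
    stop_invalid("record does not span the window")
  ages <- seq(window[1], window[2], by = grid_step)
  temp <- stats::approx(record$ages, record$temperatures, xout = ages)$y
  m <- length(ages)
  ## warming rate toward the present: -dT/d(age)
  rate <- numeric(m)
  rate[1] <- (temp[1] - temp[2]) / grid_step
  rate[m] <- (temp[m - 1] - temp[m]) / grid_step
  if (m > 2) rate[2:(m - 1)] <- (temp[1:(m - 2)] - temp[3:m]) / (2 * grid_step)
  w <- pmax(rate, 0)
  ## an expansion dated to the present (age 0) cannot calibrate a rate
  w[ages <= 0] <- 0
  if (sum(w) <= 0)
    stop_invalid("no warming anywhere in the window: no admissible expansion dates")
  list(ages = ages, weights = w / sum(w))
}

#' Draw calibration dates from warming-rate weights
#'
#' @param weights list from [warming_rate_weights()].
#' @param k number of dates (default 10000).
#' @param seed integer seed.
#' @return object of class `calibration_dates`: `dates` (years BP),
#'   `weights_source`, `seed`.
#' @export
sample_calibration_dates <- function(weights, k = 10000, seed = NULL) {
  if (k < 1) stop_invalid("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(weights$ages), k, replace = TRUE,
                    prob = weights$weights)
  structure(list(dates = weights$ages[idx],
                 weights_source = "positive warming rate",
                 seed = seed),
            class = "calibration_dates")
}

#' Cross transition-time posterior with calibration dates
#'
#' rate = TT / date (substitutions/site/year) for every (TT, date) pair
#' (`mode = "full"`) or for a seeded random pairing subsample
#' (`mode = "subsample"`, `n_sub` draws with replacement from each input).
#'
#' @param tt_posterior mutation-scaled transition-time samples (all > 0).
#' @param dates a `calibration_dates` object or numeric years BP (all > 0).
#' @param mode `"full"` or `"subsample"`.
#' @param n_sub subsample size (default 1e6) for `mode = "subsample"`.
#' @param seed integer seed for the subsample.
#' @return object of class `rate_samples`: `rates` (subst/site/year),
#'   `provenance`.
#' @export
cross_rate_samples <- function(tt_posterior, dates,
                               mode = c("full", "subsample"),
                               n_sub = 1e6, seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(dates, "calibration_dates")) dates <- dates$dates
  if (length(tt_posterior) < 1 || length(dates) < 1)
    stop_invalid("empty inputs")
  if (any(tt_posterior <= 0) || any(dates <= 0))
    stop_invalid("transition times and dates must be positive")
  if (mode == "full") {
    rates <- as.vector(outer(tt_posterior, dates, "/"))
  } else {
    if (!is.null(seed)) set.seed(seed)
    rates <- sample(tt_posterior, n_sub, replace = TRUE) /
      sample(dates, n_sub, replace = TRUE)
  }
  structure(list(rates = rates,
                 provenance = list(n_tt_samples = length(tt_posterior),
                                   n_dates = length(dates), mode = mode)),
            class = "rate_samples")
}

#' Fit and select the rate density (lognormal vs Gaussian)
#'
#' Closed-form maximum-likelihood fits of a lognormal and a Gaussian to the
#' rate sample, compared by AIC (2k - 2 lnL, k = 2 each). Fitting is done on
#' the substitutions/site/My scale so that the lognormal LogMean is directly
#' interpretable (exp(LogMean) in subst/site/My); the median rate is also
#' reported in %/My.
#'
#' @param rates a `rate_samples` object or numeric vector in
#'   substitutions/site/year (all > 0).
#' @return object of class `rate_distribution_fit`: `lognormal` (LogMean,
#'   LogSD, logLik, AIC), `gaussian` (mean, sd, logLik, AIC), `selected`,
#'   `median_rate_pct_per_my`, `units`.
#' @export
fit_rate_distribution <- function(rates) {
  if (inherits(rates, "rate_samples")) rates <- rates$rates
  if (length(rates) < 100) stop_invalid("need >= 100 rate samples")
  if (any(rates <= 0)) stop_invalid("non-positive rates present")
  if (stats::sd(rates) == 0)
    stop_invalid("degenerate all-equal rates: no density to fit")
  x <- rates * 1e6                     # subst/site/My
  n <- length(x)
  lx <- log(x)
  mu <- mean(lx); sdl <- sqrt(mean((lx - mu)^2))
  ll_ln <- sum(stats::dlnorm(x, mu, sdl, log = TRUE))
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  ll_no <- sum(stats::dnorm(x, m, s, log = TRUE))
  aic_ln <- 4 - 2 * ll_ln
  aic_no <- 4 - 2 * ll_no
  structure(list(lognormal = list(LogMean = mu, LogSD = sdl, logLik = ll_ln,
                                  AIC = aic_ln),
                 gaussian = list(mean = m, sd = s, logLik = ll_no,
                                 AIC = aic_no),
                 selected = if (aic_ln <= aic_no) "lognormal" else "gaussian",
                 median_rate_pct_per_my = stats::median(rates) * 1e8,
                 units = "fit on subst/site/My; input subst/site/year"),
            class = "rate_distribution_fit")
}

#' @export
print.rate_distribution_fit <- function(x, ...) {
  cat(sprintf("Rate density fit (selected: %s)\n", x$selected))
  cat(sprintf("  lognormal: LogMean %.3f, LogSD %.3f, AIC %.1f\n",
              x$lognormal$LogMean, x$lognormal$LogSD, x$lognormal$AIC))
  cat(sprintf("  gaussian : mean %.4f, sd %.4f, AIC %.1f\n",
              x$gaussian$mean, x$gaussian$sd, x$gaussian$AIC))
  cat(sprintf("  median rate: %.2f %%/My\n", x$median_rate_pct_per_my))
  invisible(x)
}

#' Convert substitution-rate units
#'
#' Exact linear conversions between `"subst/site/year"`, `"subst/site/My"`
#' and `"pct/My"` (%/My = subst/site/year x 1e8).
#'
#' @param value rate value(s).
#' @param from,to unit names.
#' @return converted value(s).
#' @export
convert_rate_units <- function(value, from, to) {
  units <- c("subst/site/year" = 1, "subst/site/My" = 1e-6, "pct/My" = 1e-8)
  if (!from %in% names(units)) stop_invalid("unknown unit '%s'", from)
  if (!to %in% names(units)) stop_invalid("unknown unit '%s'", to)
  value * units[[from]] / units[[to]]
}

#' Draw rates from a fitted CDT distribution
#'
#' @param fit a `rate_distribution_fit`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return rates in substitutions/site/year.
#' @export
sample_cdt_rates <- function(fit, n, seed = NULL) {
  stopifnot(inherits(fit, "rate_distribution_fit"))
  if (!is.null(seed)) set.seed(seed)
  if (fit$selected == "lognormal")
    stats::rlnorm(n, fit$lognormal$LogMean, fit$lognormal$LogSD) * 1e-6
  else
    pmax(stats::rnorm(n, fit$gaussian$mean, fit$gaussian$sd), 1e-12) * 1e-6
}
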