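test_that("synthetic temperature records have the designed warming", {
  rec <- synth_temperature(warming_onset = 12000, amplitude = 8,
                           noise_sd = 0, span = 25000, step = 100)
  expect_equal(rec$temperatures[1] - rec$temperatures[length(rec$ages)], 8,
               tolerance = 1e-6)
  ## maximum warming rate at the onset age
  dr <- -diff(rec$temperatures) / diff(rec$ages)
  mid_age <- (rec$ages[-1] + rec$ages[-length(rec$ages)]) / 2
  expect_equal(mid_age[which.max(dr)], 11950)
  r1 <- synth_temperature(noise_sd = 0.5, seed = 10)
  r2 <- synth_temperature(noise_sd = 0.5, seed = 10)
  expect_identical(r1$temperatures, r2$temperatures)
  expect_error(synth_temperature(warming_width = -1), "warming_width")
  expect_error(synth_temperature(warming_onset = 30000, span = 25000),
               "warming_onset")
})

test_that("warming-rate weights pick out warming intervals", {
  ## linear warming toward the present: uniform weights over positive ages
  ## (the present itself cannot serve as a calibration date)
  lin <- temperature_record(seq(0, 25000, 100), -seq(0, 25000, 100) / 5000)
  w <- warming_rate_weights(lin)
  pos <- w$ages > 0
  expect_equal(max(w$weights[pos]) - min(w$weights[pos]), 0,
               tolerance = 1e-12)
  expect_identical(w$weights[!pos], 0)
  expect_equal(sum(w$weights), 1)
  ## constant temperature: no admissible dates
  flat <- temperature_record(seq(0, 25000, 100), rep(1, 251))
  expect_error(warming_rate_weights(flat), "no warming")
  ## sigmoid warming centred at 12 kya: weight argmax at the onset
  rec <- synth_temperature(warming_onset = 12000, noise_sd = 0)
  w <- warming_rate_weights(rec)
  expect_equal(w$ages[which.max(w$weights)], 12000)
})

test_that("calibration dates follow the weights", {
  w <- list(ages = c(10000, 20000), weights = c(1, 0))
  d <- sample_calibration_dates(w, k = 50, seed = 1)
  expect_true(all(d$dates == 10000))
  w2 <- list(ages = c(10000, 20000), weights = c(0.5, 0.5))
  d2 <- sample_calibration_dates(w2, k = 10000, seed = 2)
  p <- mean(d2$dates == 10000)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(sample_calibration_dates(w2, 100, seed = 9)$dates,
                   sample_calibration_dates(w2, 100, seed = 9)$dates)
  expect_error(sample_calibration_dates(w2, 0), "k")
  ## default draw size matches the standard calibration sample
  expect_equal(length(sample_calibration_dates(w2, seed = 1)$dates), 10000)
})

test_that("rate crossing is the full quotient set", {
  r <- cross_rate_samples(2.0e-4, 10000)
  expect_equal(r$rates, 2.0e-8)
  expect_equal(convert_rate_units(r$rates, "subst/site/year", "pct/My"), 2.0)
  r2 <- cross_rate_samples(c(1e-4, 3e-4), c(10000, 30000))
  expect_setequal(round(r2$rates * 1e9, 6),
                  round(c(1e-8, 3e-8, 1e-8 / 3, 1e-8) * 1e9, 6))
  expect_equal(stats::median(r2$rates), 1e-8)
  expect_equal(length(r2$rates), 4L)
  ## median invariant to input order
  r3 <- cross_rate_samples(c(3e-4, 1e-4), c(30000, 10000))
  expect_equal(stats::median(r3$rates), stats::median(r2$rates))
  expect_error(cross_rate_samples(c(-1e-4), 1000), "positive")
})

test_that("subsampled crossing reproduces the full-product median", {
  set.seed(61)
  tt <- stats::rlnorm(2000, log(2.5e-4), 0.3)
  dates <- stats::runif(1000, 9000, 15000)
  full <- cross_rate_samples(tt, dates, mode = "full")
  sub <- cross_rate_samples(tt, dates, mode = "subsample", n_sub = 1e6,
                            seed = 5)
  expect_lt(abs(stats::median(sub$rates) / stats::median(full$rates) - 1),
            0.01)
  expect_equal(length(full$rates), 2e6)
})

test_that("rate-density fitting recovers lognormal parameters and prefers the right family", {
  set.seed(31)
  x_my <- stats::rlnorm(1e5, -3.89, 0.53)      # subst/site/My scale
  fit <- fit_rate_distribution(x_my * 1e-6)
  expect_lt(abs(fit$lognormal$LogMean - (-3.89)), 0.01)
  expect_lt(abs(fit$lognormal$LogSD - 0.53), 0.005)
  expect_equal(fit$selected, "lognormal")
  expect_lt(fit$lognormal$AIC, fit$gaussian$AIC)
  ## median identity: exp(LogMean) is the lognormal median
  expect_lt(abs(exp(fit$lognormal$LogMean) * 100 -
                  fit$median_rate_pct_per_my) /
              fit$median_rate_pct_per_my, 0.02)
  ## near-Gaussian positive data prefer the Gaussian
  set.seed(32)
  g_my <- stats::rnorm(1e5, 2, 0.1)
  g_my <- g_my[g_my > 0]
  fit_g <- fit_rate_distribution(g_my * 1e-6)
  expect_equal(fit_g$selected, "gaussian")
  expect_error(fit_rate_distribution(c(-1, rep(1e-8, 200))), "non-positive")
  expect_error(fit_rate_distribution(rep(1e-8, 200)), "degenerate")
  expect_error(fit_rate_distribution(rep(1e-8, 10)), "100")
})

test_that("rate unit conversions are exact and invertible", {
  expect_equal(convert_rate_units(2.2e-8, "subst/site/year", "pct/My"),
               2.2, tolerance = 1e-15)
  expect_equal(convert_rate_units(0.7, "pct/My", "subst/site/year"),
               7.0e-9, tolerance = 1e-15)
  expect_equal(convert_rate_units(1.5, "subst/site/My", "subst/site/year"),
               1.5e-6, tolerance = 1e-15)
  v <- 3.1e-8
  rt <- convert_rate_units(convert_rate_units(v, "subst/site/year", "pct/My"),
                           "pct/My", "subst/site/year")
  expect_lt(abs(rt / v - 1), 1e-15)
  expect_error(convert_rate_units(1, "furlongs", "pct/My"), "unknown unit")
})

test_that("temperature CSV round trips", {
  rec <- synth_temperature(noise_sd = 0.2, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_temperature_csv(rec, path)
  rec2 <- read_temperature_csv(path)
  expect_equal(rec2$ages, rec$ages)
  expect_equal(rec2$temperatures, rec$temperatures, tolerance = 1e-12)
})
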