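test_that("event counts convert to concentration by the volumetric rule", {
  expect_equal(events_to_concentration(16500, 66, 2), 5e5)
  expect_equal(events_to_concentration(0, 66, 2), 0)
  # homogeneity in the count
  expect_equal(events_to_concentration(33000, 66, 2),
               2 * events_to_concentration(16500, 66, 2))
  expect_error(events_to_concentration(10, 0, 2), "volume")
  expect_error(events_to_concentration(10, 66, 0.5), "Dilution")
})

test_that("conversion inverts the generator's Poisson construction", {
  sim <- simulate_sample(5e5, seed = 77)
  stainable <- sum(sim$truth$n_events[sim$truth$population != "NOISE"])
  est <- events_to_concentration(stainable, 66, 2)
  lambda <- 16500
  expect_lt(abs(stainable - lambda), 4 * sqrt(lambda))
  expect_equal(est, stainable / 66 * 2 * 1000)
})

test_that("day/night contrast reports medians, difference and Welch t-test", {
  ts <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC") + seq(0, 23.5, 0.5) * 3600
  hours <- as.numeric(format(ts, "%H", tz = "UTC"))
  day <- hours >= 6 & hours < 21
  # symmetric +/-1 jitter keeps the group medians exact
  conc <- ifelse(day, 5.2e5, 5.0e5) + rep(c(-1, 1), length.out = length(ts))
  res <- day_night_compare(tibble::tibble(timestamp = ts, concentration = conc))
  expect_equal(res$median_day, 5.2e5)
  expect_equal(res$median_night, 5.0e5)
  expect_equal(res$difference, 0.2e5)
  expect_equal(res$percent, 100 * 0.2 / 5.2, tolerance = 1e-10)
  expect_equal(res$n_day, sum(day))

  # identical distributions: difference 0, p ~= 1
  same <- tibble::tibble(
    timestamp = ts,
    concentration = rep(c(5e5, 5.1e5), length.out = length(ts))
  )
  res0 <- day_night_compare(same)
  expect_equal(res0$difference, 0)
  expect_gt(res0$p_value, 0.5)

  # pooled-variance Student variant differs only in its df handling
  resv <- day_night_compare(tibble::tibble(timestamp = ts,
                                           concentration = conc + rnorm(48)),
                            var_equal = TRUE)
  expect_true(is.finite(resv$t_statistic))
})

test_that("a 5% diel signal is detected in most synthetic days", {
  start <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC")
  hits <- vapply(1:100, function(s) {
    sc <- cruise_scenario(start, start + 85 * 15 * 60, n_tubes = 1,
                          diel_amplitude = 0.05, growth_rate = 0,
                          noise_cv = 0.02, env_coupling = 0, seed = s)
    tr <- cruise_truth(sc)
    res <- day_night_compare(
      tibble::tibble(timestamp = tr$timestamp,
                     concentration = tr$true_concentration))
    res$median_day > res$median_night && res$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("growth fits recover closed-form slopes", {
  # doubling every day: mu = ln 2, doubling time 1 day
  ts <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC") + (0:10) * 86400
  fit <- growth_rate(tibble::tibble(timestamp = ts,
                                    concentration = 1e5 * 2^(0:10)))
  expect_equal(fit$mu, log(2), tolerance = 1e-12)
  expect_equal(fit$doubling_time, 1, tolerance = 1e-12)

  flat <- growth_rate(tibble::tibble(timestamp = ts,
                                     concentration = rep(1e5, 11)))
  expect_equal(flat$mu, 0)
  expect_true(is.na(flat$doubling_time))

  expect_error(growth_rate(tibble::tibble(timestamp = ts[1:3],
                                          concentration = c(1, 0, 2))),
               "log undefined")

  # slope invariant under rescaling of all abundances
  f1 <- growth_rate(tibble::tibble(timestamp = ts,
                                   concentration = 1e5 * exp(0.3 * (0:10))))
  f2 <- growth_rate(tibble::tibble(timestamp = ts,
                                   concentration = 7e6 * exp(0.3 * (0:10))))
  expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
})

test_that("growth-rate estimation is unbiased at cruise noise levels", {
  start <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC")
  est <- vapply(1:200, function(s) {
    sc <- cruise_scenario(start, start + 85 * 15 * 60, n_tubes = 1,
                          diel_amplitude = 0, growth_rate = 0.04,
                          noise_cv = 0.03, env_coupling = 0, seed = s)
    tr <- cruise_truth(sc)
    growth_rate(tibble::tibble(timestamp = tr$timestamp,
                               concentration = tr$true_concentration))$mu
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.04), 0.005)
  # individual estimates stay within 3 standard errors most of the time
  expect_gt(mean(abs(est - 0.04) < 3 * 0.04), 0.95)
})

test_that("growth fits expose tidy() and glance() summaries", {
  ts <- as.POSIXct("2021-06-03 00:00:00", tz = "UTC") + (0:20) * 3600
  set.seed(2)
  fit <- growth_rate(tibble::tibble(
    timestamp = ts, concentration = 5e5 * exp(0.04 * (0:20) / 24 + rnorm(21, 0, 0.01))
  ))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "mu"))
  expect_equal(td$estimate[2], fit$mu)
  gl <- glance(fit)
  expect_equal(gl$n, 21)
  expect_equal(gl$doubling_time, log(2) / fit$mu)
})
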