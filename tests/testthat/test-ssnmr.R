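make_flat_spectrum <- function(y, ppm = seq(200, 0, by = -0.05),
                               experiment = "CP", t = 0)
  spectrum1d(ppm, y, experiment, t)

test_that("region integration is trapezoidal and sign-preserving", {
  ppm <- seq(200, 0, by = -0.05)
  # unit-height rectangle of width 2 ppm fully inside the window
  y <- as.numeric(ppm >= 54 & ppm <= 56)
  s <- make_flat_spectrum(y)
  expect_equal(integrate_region(s, 50, 65), 2.0, tolerance = 0.03)
  # all-zero spectrum
  expect_equal(integrate_region(make_flat_spectrum(0 * ppm), 50, 65), 0)
  # Lorentzian of known area integrated over +/- 20 linewidths
  area <- 3.7; hw <- 0.4
  y <- area * (hw / pi) / ((ppm - 120)^2 + hw^2)
  expect_equal(integrate_region(make_flat_spectrum(y), 120 - 20 * hw,
                                120 + 20 * hw), area, tolerance = 0.05)
  # disjoint window errors
  expect_error(integrate_region(s, 300, 310), "overlap")
})

test_that("integration is linear in the spectrum", {
  ppm <- seq(200, 0, by = -0.05)
  set.seed(5)
  y1 <- rnorm(length(ppm)); y2 <- rnorm(length(ppm))
  a <- 2.3; b <- -0.7
  lhs <- integrate_region(make_flat_spectrum(a * y1 + b * y2), 50, 65)
  rhs <- a * integrate_region(make_flat_spectrum(y1), 50, 65) +
    b * integrate_region(make_flat_spectrum(y2), 50, 65)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("both signal-to-noise definitions give their stated arithmetic", {
  ppm <- seq(200, 0, by = -0.05)
  y <- numeric(length(ppm))
  y[which.min(abs(ppm - 55))] <- 10            # peak height 10
  nsel <- ppm >= 0 & ppm <= 20
  y[nsel] <- rep(c(1, -1), length.out = sum(nsel))  # noise rms exactly 1
  s <- make_flat_spectrum(y)
  expect_equal(signal_to_noise(s, 55, c(0, 20), mode = "as_printed"), 10,
               tolerance = 1e-4)
  expect_equal(signal_to_noise(s, 55, c(0, 20), mode = "standard"), 5,
               tolerance = 1e-4)
  # "standard" is scale invariant; "as_printed" is not (halves on doubling)
  s2 <- make_flat_spectrum(2 * y)
  expect_equal(signal_to_noise(s2, 55, c(0, 20), mode = "standard"), 5,
               tolerance = 1e-4)
  expect_equal(signal_to_noise(s2, 55, c(0, 20), mode = "as_printed"), 5,
               tolerance = 1e-4)
  # overlapping windows are rejected
  expect_error(signal_to_noise(s, 10, c(0, 20)), "disjoint")
})

test_that("noise estimation tracks the injected noise level", {
  ppm <- seq(200, 0, by = -0.05)
  sigma <- 0.05
  set.seed(123)
  devs <- replicate(50, {
    y <- sigma * rnorm(length(ppm))
    y[which.min(abs(ppm - 55))] <- 1
    # standard mode back-solves to the noise rms estimate
    1 / (2 * signal_to_noise(make_flat_spectrum(y), 55, c(0, 40)))
  })
  expect_lt(abs(mean(devs) - sigma) / sigma, 0.1)
})

test_that("48-h normalization makes the reference value 1", {
  ser <- normalize_series(c(0.5, 1.0, 2.0), c(0, 48, 96))
  expect_equal(ser$values, c(0.5, 1.0, 2.0))
  expect_equal(ser$values[2], 1, tolerance = 1e-9)
  expect_equal(ser$times_days, c(0, 2, 4))
  # constant series normalizes to all ones
  expect_equal(normalize_series(rep(7, 4), c(0, 24, 48, 72))$values,
               rep(1, 4))
  # missing reference point errors and lists the available times
  expect_error(normalize_series(c(1, 2), c(0, 24)), "available times")
  # normalization preserves slope ratios of a linear series
  t_h <- c(0, 24, 48, 72)
  v <- 3 * (1 + 0.4 * t_h / 24)
  ser <- normalize_series(v, t_h)
  fit <- suppressWarnings(fit_linear_rate(ser))
  expect_equal(fit$slope, 0.4 / (1 + 0.4 * 2), tolerance = 1e-9)
})

test_that("linear rate fitting recovers exact and degenerate cases", {
  t_days <- c(0.2, 0.6, 1.0, 1.4, 2.0)
  ser <- list(times_days = t_days, values = 0.4 * t_days + 0.2)
  fit <- suppressWarnings(fit_linear_rate(ser))
  expect_equal(fit$slope, 0.4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-10)
  # constant series: zero slope
  flat <- suppressWarnings(
    fit_linear_rate(list(times_days = t_days, values = rep(1, 5))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(fit_linear_rate(list(times_days = c(1, 1, 1),
                                    values = 1:3)), "degenerate")
  expect_error(fit_linear_rate(list(times_days = c(1, 2), values = 1:2)),
               "3 time points")
})

test_that("slope recovery under 10% intensity noise is unbiased", {
  slopes <- vapply(1:60, function(s) {
    nm <- make_nmr_timeseries(mult_noise = 0.1, additive_noise = 0,
                              seed = 1000 + s)
    times <- vapply(nm$cp, function(x) x$time_stamp, numeric(1))
    vals <- vapply(nm$cp, integrate_region, numeric(1), 50, 65)
    fit_linear_rate(normalize_series(vals, times))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.25), 0.02)
})

test_that("rate comparison reproduces the measured slope ratios", {
  # biphasic vs monophasic CP slopes for Calpha and carbonyl carbons
  biphasic <- list(Calpha = 0.254, Cprime = 0.398)
  monophasic <- list(Calpha = 0.142, Cprime = 0.283)
  cmp <- compare_rates(biphasic, monophasic)
  expect_equal(cmp$ratio[cmp$label == "Calpha"], 1.789, tolerance = 1e-3)
  expect_equal(cmp$ratio[cmp$label == "Cprime"], 1.406, tolerance = 1e-3)
  expect_true(all(cmp$ratio > 1))  # droplet sample matures faster
  # identical inputs give unit ratios
  expect_equal(compare_rates(biphasic, biphasic)$ratio, c(1, 1))
  # antisymmetry under swapping the samples
  swapped <- compare_rates(monophasic, biphasic)
  expect_equal(swapped$ratio, 1 / cmp$ratio, tolerance = 1e-12)
  # zero denominator is flagged, ratio omitted
  z <- compare_rates(list(a = 1), list(a = 0))
  expect_true(z$zero_denominator)
  expect_true(is.na(z$ratio))
})
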