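test_that("generators are deterministic for a fixed seed and config", {
  a <- make_nmr_timeseries(seed = 4)
  b <- make_nmr_timeseries(seed = 4)
  expect_identical(a$cp[[1]]$intensity, b$cp[[1]]$intensity)
  expect_identical(a$inept[[3]]$intensity, b$inept[[3]]$intensity)
  c1 <- make_dosy_decays(seed = 4)$curves[[1]]$intensities
  c2 <- make_dosy_decays(seed = 4)$curves[[1]]$intensities
  expect_identical(c1, c2)
  k1 <- make_cars_cube(nx = 8, ny = 8, seed = 4)$cube$intensity
  k2 <- make_cars_cube(nx = 8, ny = 8, seed = 4)$cube$intensity
  expect_identical(k1, k2)
  o1 <- make_shift_observations(n_per_class = 10, seed = 4)
  o2 <- make_shift_observations(n_per_class = 10, seed = 4)
  expect_identical(o1, o2)
})

test_that("noiseless spectral series follow the linear construction", {
  nm <- make_nmr_timeseries(times_hours = c(4, 24, 48), mult_noise = 0,
                            additive_noise = 0, seed = 1)
  times <- vapply(nm$cp, function(s) s$time_stamp, numeric(1))
  vals <- vapply(nm$cp, integrate_region, numeric(1), 50, 65)
  ser <- normalize_series(vals, times)
  # 1 + 0.25*(t_days - 2): about half the 48-h signal is present at 4 h
  expect_equal(ser$values, c(0.5416667, 0.75, 1), tolerance = 1e-4)
  fit <- suppressWarnings(fit_linear_rate(ser))
  expect_equal(fit$slope, 0.25, tolerance = 1e-6)
  # INEPT decays at its configured rate
  iv <- vapply(nm$inept, integrate_region, numeric(1), 50, 65)
  ifit <- suppressWarnings(fit_linear_rate(normalize_series(iv, times)))
  expect_equal(ifit$slope, -0.06, tolerance = 1e-4)
})

test_that("single-population decays are exponential in g squared", {
  d <- make_dosy_decays(condensed_fraction = 0, snr = Inf, seed = 1)
  cv <- d$curves[[1]]
  fit <- lm(log(cv$intensities) ~ I(cv$gradients^2))
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-10)
  # gradient grid spans the printed 2-95% range
  acq <- dosy_acquisition()
  expect_equal(min(acq$gradient_fractions), 0.02)
  expect_equal(max(acq$gradient_fractions), 0.95)
  g <- cv$gradients
  expect_equal(min(g), 0.02 * acq$gmax)
  expect_equal(max(g), 0.95 * acq$gmax)
})

test_that("ground truth suffices to predict estimator outputs", {
  d <- make_dosy_decays(condensed_fraction = 0.6, snr = Inf, seed = 8)
  gt <- d$ground_truth
  # expected endpoint ratio from the stored clean curve
  expected <- gt$clean[length(gt$clean)] / gt$clean[1]
  expect_equal(endpoint_fractions(d$curves[[1]])$condensed, expected,
               tolerance = 1e-12)
  expect_equal(gt$d_fast / gt$d_slow, gt$ratio)
})

test_that("zero resonant amplitude gives a cube equal to its reference", {
  cc <- make_cars_cube(nx = 8, ny = 8,
                       core_lines = data.frame(center = numeric(0),
                                               gamma = numeric(0),
                                               amp = numeric(0)),
                       shell_extra = data.frame(center = numeric(0),
                                                gamma = numeric(0),
                                                amp = numeric(0)),
                       counts_scale = Inf, seed = 1)
  dev <- sweep(cc$cube$intensity, 3, cc$cube$nr_reference, "-")
  expect_lt(max(abs(dev)), 1e-12)
})

test_that("core-only droplets are homogeneous end to end", {
  cc <- make_cars_cube(mature = FALSE, counts_scale = Inf, seed = 3)
  m <- amide_map(cc$cube)
  seg <- segment_rings(m, n_rings = 5)
  cmp <- compare_core_shell(ring_spectra(cc$cube, seg,
                                         raman = attr(m, "raman")))
  expect_lt(max(abs(cmp$difference)), 1e-6)
})

test_that("zero-sd shift draws collapse onto the class means", {
  obs <- make_shift_observations("THR", n_per_class = 3, sd_scale = 0,
                                 seed = 1)
  stats <- load_shift_statistics()
  for (cls in unique(obs$true_class)) {
    row <- stats[stats$residue_type == "THR" & stats$ss_class == cls, ]
    expect_equal(unique(obs$ca[obs$true_class == cls]), row$mean_ca)
    expect_equal(unique(obs$cb[obs$true_class == cls]), row$mean_cb)
  }
})
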