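# Complex-Lorentzian helper: CARS intensity |chi_nr + sum A/((O-w)/G - i)|^2
cars_spectrum <- function(w, centers, gammas, amps, chi_nr = 1) {
  chi <- rep(chi_nr + 0i, length(w))
  for (k in seq_along(centers))
    chi <- chi + amps[k] / ((centers[k] - w) / gammas[k] - 1i)
  Mod(chi)^2
}

test_that("purely nonresonant input retrieves a null spectrum", {
  w <- seq(900, 1800, by = 2)
  nr <- rep(1.3, length(w))
  r <- kk_retrieve(nr, nr, w)
  expect_lt(max(abs(r$raman)), 1e-6)
  expect_error(kk_retrieve(nr, rep(0, length(w)), w), "positive")
})

test_that("retrieved lines sit at the injected centers", {
  w <- seq(900, 1800, by = 2)
  I <- cars_spectrum(w, 1618, 10, 0.05)
  r <- remove_error_phase(kk_retrieve(I, rep(1, length(w)), w))
  expect_lte(abs(w[which.max(r$raman)] - 1618), 2)  # within one bin

  # two well-separated lines: area ratio tracks the amplitude ratio
  I2 <- cars_spectrum(w, c(1100, 1618), c(10, 10), c(0.06, 0.03))
  r2 <- remove_error_phase(kk_retrieve(I2, rep(1, length(w)), w))
  area <- function(lo, hi) sum(r2$raman[w >= lo & w <= hi])
  expect_equal(area(1050, 1150) / area(1568, 1668), 2, tolerance = 0.1)
})

test_that("line centers and widths survive retrieval for random lines", {
  w <- seq(900, 1800, by = 2)
  set.seed(31)
  for (i in 1:10) {
    cen <- runif(1, 1100, 1600)
    gam <- runif(1, 8, 25)
    amp <- runif(1, 0.02, 0.08)
    I <- cars_spectrum(w, cen, gam, amp)
    # the reference is exact here, so the raw retrieval carries no error
    # phase and the line shape is preserved
    r <- kk_retrieve(I, rep(1, length(w)), w)
    ipk <- which.max(r$raman)
    expect_lte(abs(w[ipk] - cen), 2)
    # FWHM measured the same way on the retrieved line and on the exact
    # imaginary susceptibility sampled on the grid (width 2*gamma in the
    # continuum); they must agree to within one bin
    grid_fwhm <- function(y) {
      jpk <- which.max(y)
      above <- y >= y[jpk] / 2
      lo <- jpk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
      hi <- jpk; while (hi < length(w) && above[hi + 1]) hi <- hi + 1
      w[hi] - w[lo]
    }
    truth <- grid_fwhm(amp / (((cen - w) / gam)^2 + 1))   # Im chi_R
    expect_lte(abs(grid_fwhm(r$raman) - truth), 2)
    expect_lt(abs(truth - 2 * gam) / (2 * gam), 0.15)     # grid sanity
  }
})

test_that("error-phase removal reproduces smooth backgrounds", {
  w <- seq(900, 1800, by = 2)
  # zero phase in, zero out
  r0 <- list(wavenumber = w, phase = rep(0, length(w)),
             amplitude = rep(1, length(w)))
  expect_equal(max(abs(remove_error_phase(r0)$raman)), 0)
  # a pure quadratic phase is reproduced exactly by the 2nd-order filter
  quad <- 1e-3 * ((w - 1350) / 450)^2 + 5e-4 * (w - 1350) / 450
  rq <- list(wavenumber = w, phase = quad, amplitude = rep(1, length(w)))
  expect_lt(max(abs(remove_error_phase(rq)$raman)), 1e-3 * max(abs(quad)))
  # a line on top of a slow baseline keeps its position
  I <- cars_spectrum(w, 1618, 10, 0.05)
  r <- kk_retrieve(I, rep(1, length(w)), w)
  r$phase <- r$phase + quad * 50
  rc <- remove_error_phase(r)
  expect_lte(abs(w[which.max(rc$raman)] - 1618), 2)
  # window exceeding the spectral range errors
  expect_error(remove_error_phase(r, window_cm = 5000), "exceeds")
})

test_that("the amide map is a linear band integral localizing the droplet", {
  cc <- make_cars_cube(nx = 24, ny = 24, counts_scale = Inf, seed = 2)
  m <- amide_map(cc$cube)
  # the droplet indicator: threshold at the midpoint and compare masks
  th <- (max(m) + min(m)) / 2
  got <- m > th
  truth <- cc$ground_truth$droplet_mask
  dice <- 2 * sum(got & truth) / (sum(got) + sum(truth))
  expect_gt(dice, 0.95)
  # zero intensity in the band -> zero image
  cube0 <- cc$cube
  cube0$intensity <- array(rep(cc$cube$nr_reference,
                               each = 24 * 24), dim(cube0$intensity))
  expect_lt(max(abs(amide_map(cube0))), 1e-8)
  # doubling the Raman array doubles the map
  ram <- attr(m, "raman")
  m2 <- amide_map(cc$cube, raman = 2 * ram)
  expect_equal(m2[5, 5], 2 * m[5, 5], tolerance = 1e-12)
  expect_error(amide_map(cc$cube, band = c(100, 200)), "outside")
})

test_that("ring segmentation partitions a disk into equal-width annuli", {
  map <- matrix(0, 31, 31)
  rr <- sqrt(outer((1:31 - 16)^2, (1:31 - 16)^2, "+"))
  map[rr <= 10] <- 1
  seg <- segment_rings(map, n_rings = 5, mask = rr <= 10)
  expect_equal(seg$n_rings, 5L)
  # rings partition the mask exactly
  expect_equal(sum(!is.na(seg$ring_index)), sum(rr <= 10))
  counts <- tabulate(seg$ring_index[!is.na(seg$ring_index)], 5)
  expect_equal(sum(counts), sum(rr <= 10))
  # annulus areas increase outward for equal widths
  expect_true(all(diff(counts) > 0))
  # ring radial widths are equal within one pixel
  for (k in 1:5) {
    rk <- rr[!is.na(seg$ring_index) & seg$ring_index == k]
    expect_lt(diff(range(rk)), 10 / 5 + 1)
  }
  # degenerate single-pixel mask collapses with a warning
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_warning(s1 <- segment_rings(matrix(1, 5, 5), 4, mask = m1),
                 "collapsing")
  expect_equal(s1$n_rings, 1L)
  expect_error(segment_rings(map, mask = matrix(FALSE, 31, 31)), "empty")
})

test_that("the shell of a matured droplet lands in the border ring", {
  cc <- make_cars_cube(seed = 5)
  m <- amide_map(cc$cube)
  seg <- segment_rings(m, n_rings = 5)
  gt <- cc$ground_truth
  capture <- mean(seg$ring_index[gt$shell_mask] == seg$n_rings,
                  na.rm = TRUE)
  expect_gte(capture, 0.9)

  rs <- ring_spectra(cc$cube, seg, raman = attr(m, "raman"))
  expect_equal(sum(rs$n_pixels), sum(seg$mask))
  cmp <- compare_core_shell(rs)
  # the surface-localized narrow line dominates the difference spectrum
  expect_lte(abs(cmp$peak_position - 1665), 2)
  expect_gt(cmp$height_1665, 0)
  # swapping ring labels negates the difference
  cmp_sw <- compare_core_shell(rs, swap_labels = TRUE)
  expect_equal(cmp_sw$difference, -cmp$difference, tolerance = 1e-12)
  # normalization only scales the ring spectra; their peak centers stay put
  cmp_max <- compare_core_shell(rs, normalization = "max")
  band <- rs$wavenumber >= 1600 & rs$wavenumber <= 1700
  expect_equal(which.max(cmp$border[band]), which.max(cmp_max$border[band]))
  expect_equal(which.max(cmp$internal[band]),
               which.max(cmp_max$internal[band]))
})

test_that("homogeneous fresh droplets show no core-shell difference", {
  cc <- make_cars_cube(mature = FALSE, seed = 6)
  m <- amide_map(cc$cube)
  seg <- segment_rings(m, n_rings = 5)
  rs <- ring_spectra(cc$cube, seg, raman = attr(m, "raman"))
  cmp <- compare_core_shell(rs)
  w <- cmp$wavenumber
  # amide-band difference stays at the level of the line-free noise floor
  noise_floor <- 6 * sd(cmp$difference[w >= 1000 & w <= 1400])
  expect_lt(max(abs(cmp$difference[w >= 1600 & w <= 1700])), noise_floor)
})
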