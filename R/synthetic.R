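# Seeded generators for every input class the analysis modules consume.
# Each returns the dataset plus the generating parameters ("ground truth")
# so recovery tests can compute expected estimator outputs independently.

# Area-parametrized Lorentzian line: integrates to `area` over the real line.
.lorentz <- function(x, center, halfwidth, area)
  area * (halfwidth / pi) / ((x - center)^2 + halfwidth^2)

#' Synthetic CP/INEPT spectral time series
#'
#' Emulates a real-time MAS NMR maturation series: Lorentzian multiplets
#' in the conventional carbon regions whose areas change linearly in time
#' — CP (rigid-species) signal grows, INEPT (mobile-species) signal decays
#' slowly. Amplitudes are expressed in normalized units with the value at
#' the 48-h reference equal to 1, so the configured slopes are in
#' normalized intensity per day, matching how the measured series are
#' analysed. Noise is additive Gaussian on the spectrum plus a
#' multiplicative per-measurement-slot term (default 10%, the typical
#' slot-to-slot intensity uncertainty).
#'
#' @param times_hours acquisition times (>= 2), hours.
#' @param cp_slope,inept_slope normalized-intensity slopes, 1/day.
#' @param mult_noise s.d. of the multiplicative slot noise (0 disables).
#' @param additive_noise s.d. of the additive spectral noise.
#' @param seed integer seed (determinism contract: same seed + config,
#'   same spectra).
#' @return A list with `cp`, `inept` (lists of [spectrum1d()]) and
#'   `ground_truth` (slopes, region table, noise levels).
#' @export
make_nmr_timeseries <- function(times_hours = seq(4, 48, length.out = 6),
                                cp_slope = 0.25, inept_slope = -0.06,
                                mult_noise = 0.1, additive_noise = 0.002,
                                seed = 1) {
  stopifnot(length(times_hours) >= 2)
  set.seed(seed)
  ppm <- seq(200, 0, by = -0.05)
  regions <- default_regions()
  centers <- c(Cprime = 174, aromatic = 128, Calpha = 55,
               Calpha_gly = 45, Cbeta = 27, imino = 12.5)
  carbon <- setdiff(names(centers), "imino")
  t_days <- times_hours / 24
  build <- function(slope, experiment) {
    lapply(seq_along(t_days), function(i) {
      amp <- 1 + slope * (t_days[i] - 2)         # value 1 at 48 h
      y <- numeric(length(ppm))
      for (r in carbon) {
        a <- amp * (1 + mult_noise * stats::rnorm(1))
        y <- y + .lorentz(ppm, centers[[r]], 0.5, a)
      }
      y <- y + additive_noise * stats::rnorm(length(ppm))
      spectrum1d(ppm, y, experiment, times_hours[i])
    })
  }
  list(cp = build(cp_slope, "CP"),
       inept = build(inept_slope, "INEPT"),
       ground_truth = list(cp_slope = cp_slope, inept_slope = inept_slope,
                           centers = centers, regions = regions,
                           mult_noise = mult_noise,
                           additive_noise = additive_noise, seed = seed))
}

#' Synthetic two-population DOSY decays
#'
#' Two-component Stejskal-Tanner decay curves with a slowly diffusing
#' condensed pool and a fast dilute pool. Defaults reflect the measured
#' system: a dilute-pool diffusivity of 1e-10 m^2/s and a
#' condensed-to-dilute diffusivity ratio well beyond the 100x floor
#' (condensed protein diffuses at least 100 times more slowly), gradient
#' fractions spanning 2-95% of maximum, and Gaussian noise at a given
#' signal-to-noise ratio.
#'
#' @param condensed_fraction amplitude fraction of the slow pool.
#' @param d_fast dilute-pool diffusion coefficient, m^2/s.
#' @param ratio d_fast / d_slow (>= 100 by default).
#' @param snr signal-to-noise at zero gradient (Inf for noiseless).
#' @param acq a [dosy_acquisition()].
#' @param n_replicates number of curves.
#' @param seed integer seed.
#' @return A list with `curves` (list of [decay_curve()]) and
#'   `ground_truth`.
#' @export
make_dosy_decays <- function(condensed_fraction = 0.6, d_fast = 1e-10,
                             ratio = 500, snr = 100,
                             acq = dosy_acquisition(),
                             n_replicates = 1, seed = 1) {
  stopifnot(ratio >= 1, condensed_fraction >= 0, condensed_fraction <= 1)
  set.seed(seed)
  g <- dosy_gradients(acq)
  d_slow <- d_fast / ratio
  a_slow <- condensed_fraction; a_fast <- 1 - condensed_fraction
  clean <- stejskal_tanner(g, a_fast, d_fast, acq) +
    stejskal_tanner(g, a_slow, d_slow, acq)
  sigma <- if (is.finite(snr)) 1 / snr else 0
  curves <- lapply(seq_len(n_replicates), function(i)
    decay_curve(g, clean + sigma * stats::rnorm(length(g))))
  list(curves = curves,
       ground_truth = list(condensed_fraction = condensed_fraction,
                           d_fast = d_fast, d_slow = d_slow, ratio = ratio,
                           snr = snr, clean = clean, seed = seed))
}

#' Synthetic core-shell droplet CARS cube
#'
#' Builds a raster-scan BCARS cube of a disk-shaped droplet in a
#' nonresonant (agarose-like) background. Per pixel, the raw CARS
#' spectrum is |chi_NR + sum of complex Lorentzians|^2; the reference is
#' |chi_NR|^2. Core pixels carry the protein line set (amide I near 1,665
#' cm^-1 and the hydrogen-bond-sensitive tyrosine line at 1,618 cm^-1);
#' shell pixels (the outer `shell_fraction` of the droplet radius)
#' additionally carry a narrow 1,665 cm^-1 line and an enhanced 1,618
#' cm^-1 line, emulating the beta-sheet-rich surface crust of matured
#' droplets. `mature = FALSE` gives a homogeneous (fresh) droplet. Counts
#' are Poisson-distributed with additive Gaussian read noise.
#'
#' @param nx,ny image size in pixels.
#' @param wavenumber uniform grid, cm^-1.
#' @param radius_frac droplet radius as a fraction of `min(nx, ny)`.
#' @param shell_fraction shell thickness as a fraction of the radius,
#'   in (0, 0.5).
#' @param chi_nr nonresonant susceptibility (real).
#' @param core_lines,shell_extra data.frames with `center`, `gamma`,
#'   `amp` (shell pixels get core lines plus `shell_extra`).
#' @param counts_scale mean photon count at unit intensity (Poisson);
#'   `Inf` disables shot noise.
#' @param read_noise Gaussian read-noise s.d. in count units.
#' @param mature logical; FALSE drops the shell-specific lines.
#' @param seed integer seed.
#' @return A list with `cube` ([hyperspectral_cube()]) and `ground_truth`
#'   (`droplet_mask`, `shell_mask`, line tables, geometry).
#' @export
make_cars_cube <- function(nx = 32, ny = 32,
                           wavenumber = seq(900, 1800, by = 2),
                           radius_frac = 0.35, shell_fraction = 0.15,
                           chi_nr = 1,
                           core_lines = data.frame(
                             center = c(1618, 1665),
                             gamma = c(10, 18),
                             amp = c(0.03, 0.06)),
                           shell_extra = data.frame(
                             center = c(1618, 1665),
                             gamma = c(10, 5),
                             amp = c(0.03, 0.12)),
                           counts_scale = 1e5, read_noise = 0.5,
                           mature = TRUE, seed = 1) {
  stopifnot(shell_fraction > 0, shell_fraction < 0.5)
  set.seed(seed)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  R <- radius_frac * min(nx, ny)
  rr <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  droplet <- rr <= R
  shell <- droplet & rr > (1 - shell_fraction) * R

  chi_res <- function(lines) {
    if (is.null(lines) || nrow(lines) == 0)
      return(rep(0 + 0i, length(wavenumber)))
    Reduce(`+`, lapply(seq_len(nrow(lines)), function(k)
      lines$amp[k] / ((lines$center[k] - wavenumber) / lines$gamma[k] - 1i)))
  }
  spec_core <- Mod(chi_nr + chi_res(core_lines))^2
  shell_lines <- if (mature) rbind(core_lines, shell_extra) else core_lines
  spec_shell <- Mod(chi_nr + chi_res(shell_lines))^2
  spec_bg <- rep(chi_nr^2, length(wavenumber))

  nw <- length(wavenumber)
  intensity <- array(0, c(nx, ny, nw))
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    base <- if (!droplet[i, j]) spec_bg else
      if (shell[i, j]) spec_shell else spec_core
    if (is.finite(counts_scale)) {
      counts <- stats::rpois(nw, base * counts_scale) +
        read_noise * stats::rnorm(nw)
      intensity[i, j, ] <- counts / counts_scale
    } else intensity[i, j, ] <- base
  }
  cube <- hyperspectral_cube(intensity, wavenumber, spec_bg,
                             pixel_size_um = 0.25)
  list(cube = cube,
       ground_truth = list(droplet_mask = droplet, shell_mask = shell,
                           core_lines = core_lines,
                           shell_lines = shell_lines, chi_nr = chi_nr,
                           radius_px = R, shell_fraction = shell_fraction,
                           mature = mature, seed = seed))
}

#' Synthetic chemical-shift observations
#'
#' Draws Calpha/Cbeta observations from the per-class Gaussian statistics
#' for a residue type, labelled with the generating class, for
#' classification-accuracy tests.
#'
#' @param residue_type three-letter code present in `stats`.
#' @param n_per_class draws per secondary-structure class.
#' @param stats a [load_shift_statistics()] table.
#' @param sd_scale multiplies the tabulated s.d.s (0 collapses draws onto
#'   the class means).
#' @param seed integer seed.
#' @return A data.frame with `residue_type`, `true_class`, `ca`, `cb`.
#' @export
make_shift_observations <- function(residue_type = "THR", n_per_class = 500,
                                    stats = load_shift_statistics(),
                                    sd_scale = 1, seed = 1) {
  set.seed(seed)
  s <- .stats_for(stats, residue_type)
  out <- lapply(seq_len(nrow(s)), function(i) data.frame(
    residue_type = residue_type,
    true_class = s$ss_class[i],
    ca = stats::rnorm(n_per_class, s$mean_ca[i], sd_scale * s$sd_ca[i]),
    cb = if (is.na(s$mean_cb[i])) NA_real_ else
      stats::rnorm(n_per_class, s$mean_cb[i], sd_scale * s$sd_cb[i])))
  do.call(rbind, out)
}
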