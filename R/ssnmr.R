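#' A 1D NMR spectrum with time stamp
#'
#' @param ppm chemical-shift axis, stored descending (conventional NMR
#'   display order); any monotone input is accepted.
#' @param intensity intensities, same length.
#' @param experiment one of `"CP"`, `"INEPT"`, `"H1"`.
#' @param time_stamp hours since the start of maturation.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, experiment = c("CP", "INEPT", "H1"),
                       time_stamp = NA_real_) {
  experiment <- match.arg(experiment)
  stopifnot(length(ppm) == length(intensity), length(ppm) >= 2)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (d[1] > 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = ppm, intensity = intensity,
                 experiment = experiment, time_stamp = time_stamp),
            class = "spectrum1d")
}

#' Default integration windows
#'
#' Conventional 13C (and 1H imino) shift ranges for the spectral regions
#' tracked during maturation. The windows are configurable; these defaults
#' cover carbonyl, aromatic, Calpha, glycine Calpha and Cbeta carbons plus
#' the RNA imino proton region.
#'
#' @return A data.frame with columns `label`, `ppm_low`, `ppm_high`.
#' @export
default_regions <- function() {
  data.frame(
    label    = c("Cprime", "aromatic", "Calpha", "Calpha_gly", "Cbeta",
                 "imino"),
    ppm_low  = c(165, 105, 50, 42, 15, 10),
    ppm_high = c(182, 140, 65, 48, 40, 15))
}

#' Integrate a spectral region
#'
#' Sign-preserving trapezoidal integral of the intensity over a ppm window.
#'
#' @param spec a [spectrum1d()].
#' @param ppm_low,ppm_high window bounds (ppm_low < ppm_high).
#' @return The integral (intensity x ppm).
#' @export
integrate_region <- function(spec, ppm_low, ppm_high) {
  stopifnot(ppm_low < ppm_high)
  sel <- spec$ppm >= ppm_low & spec$ppm <= ppm_high
  if (sum(sel) < 2)
    stop("integration window [", ppm_low, ", ", ppm_high,
         "] does not overlap the spectrum axis", call. = FALSE)
  x <- rev(spec$ppm[sel])          # ascending for integration
  y <- rev(spec$intensity[sel])
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Signal-to-noise of a peak
#'
#' `mode = "standard"` is the conventional NMR definition, peak height
#' divided by twice the noise r.m.s. `mode = "as_printed"` divides the
#' peak height by the *square* of the noise r.m.s.; this matches the
#' vendor SiNo description used for the kinetics traces but is not scale
#' invariant (doubling all intensities halves it, while the standard
#' ratio is unchanged), so it is provided verbatim rather than as
#' default.
#'
#' @param spec a [spectrum1d()].
#' @param peak_ppm centre of the peak; the height is the maximum intensity
#'   within `peak_halfwidth` of it.
#' @param noise_window length-2 ppm range (disjoint from the peak) used to
#'   estimate the noise r.m.s. about its mean.
#' @param mode `"standard"` or `"as_printed"`.
#' @param peak_halfwidth ppm half-window for the peak height search.
#' @return Signal-to-noise value.
#' @export
signal_to_noise <- function(spec, peak_ppm, noise_window,
                            mode = c("standard", "as_printed"),
                            peak_halfwidth = 1) {
  mode <- match.arg(mode)
  nw <- sort(noise_window)
  if (peak_ppm >= nw[1] - peak_halfwidth && peak_ppm <= nw[2] + peak_halfwidth)
    stop("noise window must be disjoint from the peak region", call. = FALSE)
  peak_sel <- abs(spec$ppm - peak_ppm) <= peak_halfwidth
  noise_sel <- spec$ppm >= nw[1] & spec$ppm <= nw[2]
  if (!any(peak_sel) || sum(noise_sel) < 2)
    stop("peak or noise window outside the spectrum axis", call. = FALSE)
  height <- max(spec$intensity[peak_sel])
  x <- spec$intensity[noise_sel]
  noise_rms <- sqrt(mean((x - mean(x))^2))
  if (noise_rms <= 0) stop("zero noise estimate", call. = FALSE)
  switch(mode,
         standard  = height / (2 * noise_rms),
         as_printed = height / noise_rms^2)
}

#' Normalize a kinetics series to a reference time
#'
#' Divides all values by the value measured at (or near) the reference
#' time, conventionally 48 h, so the reference point becomes 1.
#'
#' @param values integrals or signal-to-noise values.
#' @param times_hours acquisition times, hours.
#' @param reference_hours reference time (default 48).
#' @param tolerance_hours how far from the reference a measurement may be.
#' @param label region label carried through.
#' @return A `kinetics_series`: list with `label`, `times_days`, `values`
#'   (normalized), `reference_hours`.
#' @export
normalize_series <- function(values, times_hours, reference_hours = 48,
                             tolerance_hours = 1, label = "") {
  stopifnot(length(values) == length(times_hours))
  i <- which(abs(times_hours - reference_hours) <= tolerance_hours)
  if (length(i) == 0)
    stop("no measurement within ", tolerance_hours, " h of the ",
         reference_hours, " h reference; available times (h): ",
         paste(signif(times_hours, 4), collapse = ", "), call. = FALSE)
  i <- i[which.min(abs(times_hours[i] - reference_hours))]
  if (values[i] == 0) stop("reference value is zero", call. = FALSE)
  structure(list(label = label, times_days = times_hours / 24,
                 values = values / values[i],
                 reference_hours = reference_hours),
            class = "kinetics_series")
}

#' Linear maturation-rate fit
#'
#' Ordinary least squares of normalized intensity against time in days;
#' the slope (1/days) is the maturation rate read off the CP build-up or
#' INEPT decay.
#'
#' @param series a `kinetics_series` (from [normalize_series()]), or a
#'   list with `times_days` and `values`.
#' @return A `slope_estimate`: `slope`, `intercept`, `se`, `r_squared`.
#' @export
fit_linear_rate <- function(series) {
  t <- series$times_days; y <- series$values
  if (length(t) < 3) stop("need at least 3 time points", call. = FALSE)
  if (diff(range(t)) == 0) stop("degenerate series: all times equal",
                                call. = FALSE)
  fit <- stats::lm(y ~ t)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se = unname(s$coefficients[2, 2]),
                 r_squared = s$r.squared,
                 label = if (!is.null(series$label)) series$label else ""),
            class = "slope_estimate")
}

#' Compare maturation rates between samples
#'
#' Per-region ratio of slopes (e.g. biphasic droplet sample over
#' monophasic bulk sample); a ratio above 1 means sample A matures faster.
#' Standard errors are propagated in quadrature on the relative scale.
#' Regions whose denominator slope is zero are flagged and their ratio
#' omitted (NA).
#'
#' @param slopes_a,slopes_b named lists of `slope_estimate`s (or of
#'   numeric slopes), sharing labels.
#' @return A data.frame with `label`, `slope_a`, `slope_b`, `ratio`,
#'   `ratio_se`, `zero_denominator`.
#' @export
compare_rates <- function(slopes_a, slopes_b) {
  labs <- intersect(names(slopes_a), names(slopes_b))
  if (length(labs) == 0) stop("no shared labels", call. = FALSE)
  take <- function(x) if (inherits(x, "slope_estimate"))
    c(x$slope, x$se) else c(as.numeric(x), NA_real_)
  rows <- lapply(labs, function(l) {
    a <- take(slopes_a[[l]]); b <- take(slopes_b[[l]])
    zero <- b[1] == 0
    ratio <- if (zero) NA_real_ else a[1] / b[1]
    se <- if (zero || anyNA(c(a[2], b[2]))) NA_real_ else
      abs(ratio) * sqrt((a[2] / a[1])^2 + (b[2] / b[1])^2)
    data.frame(label = l, slope_a = a[1], slope_b = b[1],
               ratio = ratio, ratio_se = se, zero_denominator = zero)
  })
  do.call(rbind, rows)
}

#' Region-integration kinetics over a spectral time series
#'
#' Convenience wrapper: integrates each region in every spectrum,
#' normalizes each region's series to the reference time and fits the
#' linear rate.
#'
#' @param spectra list of [spectrum1d()] with time stamps in hours.
#' @param regions data.frame like [default_regions()].
#' @param reference_hours normalization reference (default 48).
#' @return Named list of `slope_estimate`s, one per region label.
#' @export
region_kinetics <- function(spectra, regions = default_regions(),
                            reference_hours = 48) {
  times <- vapply(spectra, function(s) s$time_stamp, numeric(1))
  out <- list()
  for (i in seq_len(nrow(regions))) {
    vals <- vapply(spectra, integrate_region,
                   numeric(1), regions$ppm_low[i], regions$ppm_high[i])
    ser <- normalize_series(vals, times, reference_hours,
                            label = regions$label[i])
    out[[regions$label[i]]] <- fit_linear_rate(ser)
  }
  out
}
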