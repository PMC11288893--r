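#' Hyperspectral CARS cube
#'
#' Container for a raster-scanned broadband CARS measurement: an
#' `nx x ny x nw` intensity array on a strictly increasing wavenumber
#' grid, plus the nonresonant reference spectrum of the surrounding
#' medium (e.g. agarose) used for phase retrieval.
#'
#' @param intensity numeric array, dim (nx, ny, nw), counts.
#' @param wavenumber strictly increasing, cm^-1, length nw.
#' @param nr_reference nonresonant reference spectrum, length nw, strictly
#'   positive.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return An object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(intensity, wavenumber, nr_reference,
                               pixel_size_um = 1) {
  stopifnot(length(dim(intensity)) == 3,
            dim(intensity)[3] == length(wavenumber),
            length(nr_reference) == length(wavenumber),
            all(diff(wavenumber) > 0))
  if (any(nr_reference <= 0))
    stop("nonresonant reference must be strictly positive", call. = FALSE)
  structure(list(intensity = intensity, wavenumber = wavenumber,
                 nr_reference = nr_reference,
                 pixel_size_um = pixel_size_um),
            class = "hyperspectral_cube")
}

# Hilbert transform via FFT (imaginary part of the analytic signal).
.hilbert <- function(u) {
  n <- length(u)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Im(stats::fft(stats::fft(u) * h, inverse = TRUE) / n)
}

#' Kramers-Kronig phase retrieval for a CARS spectrum
#'
#' Retrieves the Raman-like spectrum from a measured CARS spectrum and a
#' nonresonant reference: the phase is the Hilbert transform of half the
#' log intensity ratio, phi = H{0.5 * ln(I_CARS / I_NR)} (mirror-image
#' edge padding suppresses wrap-around; the transform sign is fixed so
#' resonances come out positive), and the raw Raman-like amplitude is
#' sqrt(I_CARS / I_NR) * sin(phi). The slowly varying error phase left by
#' an imperfect reference is removed separately by
#' [remove_error_phase()].
#'
#' @param i_cars measured CARS intensities on the common grid.
#' @param nr_reference nonresonant reference intensities (> 0).
#' @param wavenumber the common, uniform wavenumber grid, cm^-1.
#' @return A list (class `kk_retrieval`) with `wavenumber`, `amplitude`
#'   (sqrt ratio), `phase`, and `raman` (raw Raman-like spectrum).
#' @export
kk_retrieve <- function(i_cars, nr_reference, wavenumber) {
  stopifnot(length(i_cars) == length(nr_reference),
            length(i_cars) == length(wavenumber))
  dg <- diff(wavenumber)
  if (any(nr_reference <= 0))
    stop("nonresonant reference must be strictly positive on the grid",
         call. = FALSE)
  if (max(abs(dg - dg[1])) > 1e-6 * dg[1])
    stop("wavenumber grid must be uniform", call. = FALSE)
  ratio <- pmax(i_cars, .Machine$double.eps) / nr_reference
  n <- length(ratio)
  padded <- c(rev(ratio), ratio, rev(ratio))     # mirror-image padding
  phase <- .hilbert(0.5 * log(padded))[(n + 1):(2 * n)]
  amplitude <- sqrt(ratio)
  structure(list(wavenumber = wavenumber, amplitude = amplitude,
                 phase = phase, raman = amplitude * sin(phase)),
            class = "kk_retrieval")
}

#' Remove the slowly varying error phase
#'
#' The retrieved phase carries a broad background (error phase) when the
#' reference is not perfectly nonresonant. It is estimated with a
#' Savitzky-Golay smoother (second-order polynomial, 400 cm^-1 window by
#' default, converted to the nearest odd sample count) and subtracted;
#' the corrected Raman-like spectrum is `amplitude * sin(phase - error)`.
#' A second-order filter reproduces quadratic phase backgrounds exactly.
#'
#' @param retrieval a [kk_retrieve()] result (or a list with `wavenumber`,
#'   `phase`, `amplitude`).
#' @param polynomial_order Savitzky-Golay polynomial order.
#' @param window_cm smoothing window in cm^-1.
#' @return The retrieval with added `error_phase`, `phase_corrected` and
#'   corrected `raman`.
#' @export
remove_error_phase <- function(retrieval, polynomial_order = 2,
                               window_cm = 400) {
  w <- retrieval$wavenumber
  dg <- mean(diff(w))
  n_win <- round(window_cm / dg)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win < 5)
    stop("window_cm must span at least 5 samples", call. = FALSE)
  if (n_win > length(w))
    stop("window_cm (", window_cm, " cm^-1) exceeds the spectral range",
         call. = FALSE)
  err <- signal::sgolayfilt(retrieval$phase, p = polynomial_order,
                            n = n_win)
  phase_c <- retrieval$phase - err
  retrieval$error_phase <- err
  retrieval$phase_corrected <- phase_c
  retrieval$raman <- retrieval$amplitude * sin(phase_c)
  retrieval
}

# Per-pixel corrected Raman-like spectra for a whole cube -> array
# (nx, ny, nw). Vectorized over pixels (mvfft for the Hilbert transform,
# one precomputed Savitzky-Golay design); numerically identical to
# kk_retrieve() + remove_error_phase() applied pixel by pixel.
.cube_raman <- function(cube, polynomial_order = 2, window_cm = 400) {
  d <- dim(cube$intensity)
  nw <- d[3]
  X <- t(matrix(cube$intensity, d[1] * d[2], nw))        # nw x npix
  ratio <- pmax(X, .Machine$double.eps) / cube$nr_reference
  padded <- rbind(ratio[nw:1, , drop = FALSE], ratio,
                  ratio[nw:1, , drop = FALSE])
  L <- 0.5 * log(padded)
  n <- nrow(L)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  H <- Im(stats::mvfft(stats::mvfft(L) * h, inverse = TRUE) / n)
  phase <- H[(nw + 1):(2 * nw), , drop = FALSE]

  dg <- mean(diff(cube$wavenumber))
  n_win <- round(window_cm / dg)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win > nw)
    stop("window_cm (", window_cm, " cm^-1) exceeds the spectral range",
         call. = FALSE)
  filt <- signal::sgolay(p = polynomial_order, n = n_win)
  err <- apply(phase, 2, function(col) signal::sgolayfilt(col, filt))
  ram <- sqrt(ratio) * sin(phase - err)
  array(t(ram), d)
}

#' Amide-I band map
#'
#' Per-pixel trapezoidal integral of the corrected Raman-like spectrum
#' over a wavenumber band (default the amide I band, 1600-1700 cm^-1,
#' the protein backbone marker used to image droplets).
#'
#' @param cube a [hyperspectral_cube()].
#' @param band length-2 band in cm^-1.
#' @param raman optional precomputed array from an earlier call (the
#'   per-pixel retrieval is the expensive step).
#' @return A numeric matrix (nx x ny) of band-integrated intensity, with
#'   the retrieved array attached as attribute `raman`.
#' @export
amide_map <- function(cube, band = c(1600, 1700), raman = NULL) {
  w <- cube$wavenumber
  if (band[1] < min(w) || band[2] > max(w))
    stop("band outside the wavenumber range", call. = FALSE)
  if (is.null(raman)) raman <- .cube_raman(cube)
  sel <- which(w >= band[1] & w <= band[2])
  if (length(sel) < 2) stop("band too narrow for the grid", call. = FALSE)
  ws <- w[sel]
  wts <- c(diff(ws) / 2, 0) + c(0, diff(ws) / 2)  # trapezoid weights
  d <- dim(raman)
  m <- matrix(raman[, , sel, drop = FALSE], nrow = d[1] * d[2]) %*% wts
  out <- matrix(m, d[1], d[2])
  attr(out, "raman") <- raman
  out
}

#' Segment a droplet into concentric rings
#'
#' Builds a droplet mask from the band map (Otsu threshold on the
#' normalized image, then largest connected component; or a supplied
#' mask), finds its centroid, and partitions the mask into `n_rings`
#' equal-width annuli from the centre to the boundary. The outermost ring
#' is the "border", the rest the "internal" region.
#'
#' @param map band-intensity matrix from [amide_map()].
#' @param n_rings number of annuli (default 5).
#' @param mask optional logical matrix overriding the threshold mask.
#' @return A list (class `ring_segmentation`) with `mask`, `center`,
#'   `ring_index` (matrix, NA outside the mask, 1 = innermost,
#'   `n_rings` = border) and `n_rings` (collapsed with a warning for
#'   degenerate masks).
#' @export
segment_rings <- function(map, n_rings = 5, mask = NULL) {
  if (is.null(mask)) {
    rng <- range(map)
    if (diff(rng) == 0) stop("empty mask: flat map", call. = FALSE)
    img <- (map - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(img))
    bw <- img > th
    lab <- EBImage::bwlabel(EBImage::Image(bw))
    lab <- EBImage::imageData(lab)
    if (max(lab) == 0) stop("empty mask after thresholding", call. = FALSE)
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
  }
  mask <- matrix(as.logical(mask), nrow(map), ncol(map))
  npix <- sum(mask)
  if (npix == 0) stop("empty mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  center <- colMeans(idx)
  r <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)
  rmax <- max(r)
  if (npix < n_rings || rmax == 0) {
    warning("mask too small for ", n_rings, " rings; collapsing to 1")
    n_rings <- 1L
  }
  ring <- if (rmax == 0) rep(1L, npix) else
    pmin(floor(r / (rmax * (1 + 1e-9)) * n_rings) + 1L, n_rings)
  ring_index <- matrix(NA_integer_, nrow(map), ncol(map))
  ring_index[mask] <- ring
  structure(list(mask = mask, center = center, ring_index = ring_index,
                 n_rings = as.integer(n_rings)),
            class = "ring_segmentation")
}

#' Per-ring mean Raman-like spectra
#'
#' Averages the corrected Raman-like spectrum over all pixels of each
#' ring, with per-wavenumber standard deviation. Empty rings are omitted
#' with a warning.
#'
#' @param cube a [hyperspectral_cube()].
#' @param seg a [segment_rings()] result.
#' @param raman optional precomputed per-pixel Raman array.
#' @return A list (class `ring_spectra`) with `wavenumber`, `mean`
#'   (n_rings x nw), `sd`, `n_pixels`, `n_rings`.
#' @export
ring_spectra <- function(cube, seg, raman = NULL) {
  if (!all(dim(seg$ring_index) == dim(cube$intensity)[1:2]))
    stop("segmentation does not match the cube dimensions", call. = FALSE)
  if (is.null(raman)) raman <- .cube_raman(cube)
  nw <- length(cube$wavenumber)
  mu <- matrix(NA_real_, seg$n_rings, nw)
  sdv <- matrix(NA_real_, seg$n_rings, nw)
  npx <- integer(seg$n_rings)
  flat <- matrix(raman, nrow = prod(dim(raman)[1:2]))
  for (k in seq_len(seg$n_rings)) {
    sel <- which(seg$ring_index == k)
    npx[k] <- length(sel)
    if (length(sel) == 0) { warning("ring ", k, " is empty; omitted"); next }
    block <- flat[sel, , drop = FALSE]
    mu[k, ] <- colMeans(block)
    sdv[k, ] <- if (length(sel) > 1) apply(block, 2, stats::sd) else 0
  }
  structure(list(wavenumber = cube$wavenumber, mean = mu, sd = sdv,
                 n_pixels = npx, n_rings = seg$n_rings),
            class = "ring_spectra")
}

# Area normalization over the fingerprint region (or max normalization).
.normalize_spectrum <- function(w, y, method = c("area", "max"),
                                region = c(900, 1800)) {
  method <- match.arg(method)
  sel <- w >= region[1] & w <= region[2]
  denom <- if (method == "area")
    sum(abs(y[sel])) * mean(diff(w)) else max(abs(y[sel]))
  if (denom == 0) return(y)
  y / denom
}

#' Border-versus-core spectral comparison
#'
#' Computes the difference between the normalized border (outermost ring)
#' spectrum and the normalized internal spectrum (pixel-weighted mean of
#' all inner rings), plus band metrics at the two maturation markers: the
#' hydrogen-bond-sensitive tyrosine line at 1,618 cm^-1 (height) and the
#' amide-I shoulder at 1,665 cm^-1 (height and FWHM of the difference
#' feature). In homogeneous (fresh) droplets the difference is flat at
#' the noise level; matured droplets develop surface-localized features.
#'
#' @param rings a [ring_spectra()] result.
#' @param normalization `"area"` (fingerprint 900-1800 cm^-1) or `"max"`.
#' @param swap_labels compare internal minus border instead (the
#'   difference spectrum negates).
#' @return A list (class `core_shell_comparison`) with `wavenumber`,
#'   `border`, `internal` (normalized spectra), `difference`,
#'   `peak_position` (cm^-1 of the absolute difference maximum inside the
#'   amide band), `height_1618`, `height_1665`, `fwhm_1665`.
#' @export
compare_core_shell <- function(rings, normalization = c("area", "max"),
                               swap_labels = FALSE) {
  normalization <- match.arg(normalization)
  w <- rings$wavenumber
  if (rings$n_rings < 2)
    stop("need at least two rings for a core-shell comparison",
         call. = FALSE)
  border <- rings$mean[rings$n_rings, ]
  inner_rows <- seq_len(rings$n_rings - 1)
  wts <- rings$n_pixels[inner_rows]
  internal <- colSums(rings$mean[inner_rows, , drop = FALSE] * wts) / sum(wts)
  border <- .normalize_spectrum(w, border, normalization)
  internal <- .normalize_spectrum(w, internal, normalization)
  if (swap_labels) { tmp <- border; border <- internal; internal <- tmp }
  diff_spec <- border - internal
  band <- w >= 1580 & w <= 1720
  ip <- which(band)[which.max(abs(diff_spec[band]))]
  height_at <- function(target) diff_spec[which.min(abs(w - target))]
  # FWHM of the difference feature around 1665
  h1665 <- height_at(1665)
  fwhm <- NA_real_
  i0 <- which.min(abs(w - 1665))
  if (is.finite(h1665) && h1665 != 0) {
    half <- abs(h1665) / 2
    s <- sign(h1665)
    above <- s * diff_spec >= half
    lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i0; while (hi < length(w) && above[hi + 1]) hi <- hi + 1
    if (above[i0]) fwhm <- w[hi] - w[lo]
  }
  structure(list(wavenumber = w, border = border, internal = internal,
                 difference = diff_spec, peak_position = w[ip],
                 height_1618 = height_at(1618), height_1665 = h1665,
                 fwhm_1665 = fwhm),
            class = "core_shell_comparison")
}
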