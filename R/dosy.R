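#' DOSY acquisition constants
#'
#' Pulsed-field-gradient acquisition parameters for the Stejskal-Tanner
#' attenuation model. Gradient strengths are handled as absolute T/m;
#' `gradient_fractions` are fractions of `gmax` (the experiment ramps the
#' gradient between about 2% and 95% of maximum).
#'
#' @param big_delta diffusion time Delta, s.
#' @param small_delta gradient pulse length delta, s (must be < big_delta).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1 (default 1H).
#' @param gmax maximum gradient strength, T/m.
#' @param gradient_fractions strictly increasing fractions of gmax in [0, 1].
#' @return An object of class `dosy_acquisition`.
#' @export
dosy_acquisition <- function(big_delta = 0.05, small_delta = 0.01,
                             gamma = 2.675e8, gmax = 0.5,
                             gradient_fractions = seq(0.02, 0.95,
                                                      length.out = 16)) {
  stopifnot(small_delta < big_delta, gmax > 0, gamma > 0,
            all(gradient_fractions >= 0), all(gradient_fractions <= 1),
            all(diff(gradient_fractions) > 0))
  structure(list(big_delta = big_delta, small_delta = small_delta,
                 gamma = gamma, gmax = gmax,
                 gradient_fractions = gradient_fractions),
            class = "dosy_acquisition")
}

#' @rdname dosy_acquisition
#' @param acq a `dosy_acquisition`.
#' @return `dosy_gradients` returns the absolute gradient strengths (T/m).
#' @export
dosy_gradients <- function(acq) acq$gmax * acq$gradient_fractions

#' Stejskal-Tanner signal attenuation
#'
#' Intensity of a freely diffusing species under a pulsed-gradient spin
#' echo: `A * exp(-D * gamma^2 * g^2 * delta^2 * (Delta - delta/3))`.
#'
#' @param g gradient strength(s), T/m.
#' @param A amplitude at zero gradient.
#' @param D diffusion coefficient, m^2/s.
#' @param acq [dosy_acquisition()].
#' @return Intensities, same length as `g`.
#' @export
stejskal_tanner <- function(g, A, D, acq) {
  stopifnot(all(g >= 0), D >= 0)
  b <- acq$gamma^2 * g^2 * acq$small_delta^2 *
    (acq$big_delta - acq$small_delta / 3)
  A * exp(-D * b)
}

#' A DOSY decay curve
#'
#' @param gradients gradient strengths, T/m.
#' @param intensities signal intensities (same length).
#' @param time_stamp hours since droplet formation (metadata).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(gradients, intensities, time_stamp = NA_real_) {
  stopifnot(length(gradients) == length(intensities),
            all(is.finite(gradients)), all(gradients >= 0))
  o <- order(gradients)
  structure(list(gradients = gradients[o], intensities = intensities[o],
                 time_stamp = time_stamp),
            class = "decay_curve")
}

.phase_fractions <- function(condensed, method) {
  condensed <- min(max(condensed, 0), 1)
  structure(list(condensed = condensed, dilute = 1 - condensed,
                 method = method),
            class = "phase_fractions")
}

#' Condensed/dilute fractions from the decay-curve endpoints
#'
#' At the weakest gradient the total protein pool contributes; at the
#' strongest gradient the fast-diffusing dilute pool is attenuated away and
#' only the slowly diffusing condensed (droplet) pool remains. The
#' condensed fraction is therefore the intensity ratio
#' `I(g_max) / I(g_min)`. The weakest measured gradient stands in for
#' "zero gradient", which is never measured directly.
#'
#' @param curve a [decay_curve()].
#' @return A `phase_fractions` object (`condensed`, `dilute`, `method`).
#' @export
endpoint_fractions <- function(curve) {
  i_min <- curve$intensities[1]
  i_max <- curve$intensities[length(curve$intensities)]
  if (!is.finite(i_min) || i_min <= 0)
    stop("invalid curve: intensity at the minimum gradient must be positive",
         call. = FALSE)
  .phase_fractions(i_max / i_min, "endpoint")
}

#' Two-population Stejskal-Tanner fit
#'
#' Nonlinear least squares of `A1 exp(-D1 b) + A2 exp(-D2 b)` against a
#' decay curve (b the gradient-dependent attenuation factor), with
#' component 1 the fast dilute pool and component 2 the slow condensed
#' pool, constrained to `D1/D2 >= ratio_floor` (condensed-phase protein
#' diffuses at least ~100x more slowly than dilute protein). Fractions are
#' the amplitudes normalized to their sum. Initialization is a log-linear
#' fit of the curve tail (slow D) and head (fast D).
#'
#' @param curve a [decay_curve()] with at least 6 points.
#' @param acq [dosy_acquisition()].
#' @param ratio_floor minimum D1/D2 ratio (default 100).
#' @return A list with `fit` (class `diffusion_fit`: `A1`, `A2`, `D1`,
#'   `D2`, `residual`, `ratio_constrained`) and `fractions`
#'   (`phase_fractions`).
#' @export
fit_two_populations <- function(curve, acq, ratio_floor = 100) {
  g <- curve$gradients
  if (length(g) < 6) stop("need at least 6 gradient points", call. = FALSE)
  scale <- max(abs(curve$intensities))
  if (scale <= 0) stop("curve has no signal", call. = FALSE)
  I <- curve$intensities / scale   # fit on unit scale: exact invariance
  b <- acq$gamma^2 * g^2 * acq$small_delta^2 *
    (acq$big_delta - acq$small_delta / 3)

  # log-linear start for the fast component from the curve head
  n <- length(g)
  pos <- I > 0
  slope_of <- function(idx) {
    idx <- idx[pos[idx]]
    if (length(idx) < 2) return(NA_real_)
    stats::coef(stats::lm(log(I[idx]) ~ b[idx]))[2]
  }
  D1_0 <- -slope_of(1:min(5, n))
  if (!is.finite(D1_0) || D1_0 <= 0) D1_0 <- 1 / b[n]

  # variable projection: for each candidate (D1, ratio), the amplitudes
  # solve a 2-column linear least-squares problem; a coarse grid picks a
  # start that a full Levenberg-Marquardt polish then refines.  This keeps
  # the two-exponential fit out of the local minima a single-start search
  # is prone to.
  proj_rss <- function(logD1, u) {
    D1 <- exp(logD1); ratio <- ratio_floor * (1 + exp(u))
    X <- cbind(exp(-D1 * b), exp(-(D1 / ratio) * b))
    cf <- tryCatch(qr.coef(qr(X), I), error = function(e) c(NA, NA))
    if (anyNA(cf)) return(list(rss = Inf, A = c(0, 0)))
    cf <- pmax(cf, 0)
    list(rss = sum((X %*% cf - I)^2), A = cf)
  }
  grid_logD1 <- log(D1_0) + seq(-2, 2, length.out = 13)
  grid_u <- seq(-8, 5, length.out = 14)
  best <- list(rss = Inf)
  for (ld in grid_logD1) for (u in grid_u) {
    cand <- proj_rss(ld, u)
    if (cand$rss < best$rss)
      best <- list(rss = cand$rss, logD1 = ld, u = u, A = cand$A)
  }

  # full polish: amplitudes via squares (>= 0), D2 = D1 / ratio with
  # ratio = ratio_floor * (1 + exp(u)) >= ratio_floor
  resid_fn <- function(p) {
    A1 <- p[1]^2; A2 <- p[2]^2
    D1 <- exp(p[3]); ratio <- ratio_floor * (1 + exp(p[4]))
    A1 * exp(-D1 * b) + A2 * exp(-(D1 / ratio) * b) - I
  }
  fit <- minpack.lm::nls.lm(
    par = c(sqrt(max(best$A[1], 1e-6)), sqrt(max(best$A[2], 1e-6)),
            best$logD1, best$u),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-15, ptol = 1e-15))
  if (fit$info %in% c(0, 9))
    stop("two-population fit did not converge; residual norm = ",
         sqrt(sum(fit$fvec^2)), call. = FALSE)
  p <- fit$par
  A1 <- p[1]^2 * scale; A2 <- p[2]^2 * scale
  D1 <- exp(p[3]); ratio <- ratio_floor * (1 + exp(p[4]))
  out <- structure(list(A1 = A1, A2 = A2, D1 = D1, D2 = D1 / ratio,
                        residual = scale * sqrt(sum(fit$fvec^2)),
                        ratio_constrained = exp(p[4]) < 1e-6),
                   class = "diffusion_fit")
  list(fit = out,
       fractions = .phase_fractions(A2 / (A1 + A2), "biexponential"))
}

#' Read a decay curve from CSV
#'
#' Expects columns `gradient_fraction` and `intensity`; gradients are
#' converted to absolute T/m using the acquisition `gmax`.
#'
#' @param path CSV path.
#' @param acq [dosy_acquisition()] supplying `gmax`.
#' @param time_stamp hours since droplet formation.
#' @return A [decay_curve()].
#' @export
read_decay_curve <- function(path, acq, time_stamp = NA_real_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("gradient_fraction", "intensity") %in% names(d)))
  decay_curve(acq$gmax * d$gradient_fraction, d$intensity, time_stamp)
}
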