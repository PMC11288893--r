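#' Flory-Huggins interaction parameters for a ternary mixture
#'
#' Parameter container for an incompressible ternary mixture of protein
#' monomers (1), aggregates (2) and solvent (s). Interaction strengths are
#' dimensionless Flory chi parameters; molecular volumes are expressed in
#' units of a reference volume, so the free energy comes out in kB*T per
#' reference volume.
#'
#' @param chi12 monomer-aggregate interaction parameter.
#' @param chi1s monomer-solvent interaction parameter.
#' @param chi2s aggregate-solvent interaction parameter.
#' @param v1,v2,vs molecular volumes (reference-volume units), all > 0.
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(chi12 = 0, chi1s = 0, chi2s = 0,
                               v1 = 1, v2 = 1, vs = 1) {
  stopifnot(is.finite(chi12), is.finite(chi1s), is.finite(chi2s))
  if (v1 <= 0 || v2 <= 0 || vs <= 0)
    stop("molecular volumes must be positive", call. = FALSE)
  structure(list(chi12 = chi12, chi1s = chi1s, chi2s = chi2s,
                 v1 = v1, v2 = v2, vs = vs),
            class = "interaction_params")
}

#' Ternary composition in volume fractions
#'
#' @param phi1 monomer volume fraction.
#' @param phi2 aggregate volume fraction.
#' @param phis solvent volume fraction; defaults to `1 - phi1 - phi2`.
#' @return An object of class `composition` (named numeric of length 3).
#' @export
composition <- function(phi1, phi2, phis = 1 - phi1 - phi2) {
  phi <- c(phi1 = phi1, phi2 = phi2, phis = phis)
  if (any(!is.finite(phi)))
    stop("volume fractions must be finite", call. = FALSE)
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12))
    stop("volume fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(phi) - 1) > 1e-12)
    stop("volume fractions must sum to 1", call. = FALSE)
  structure(pmin(pmax(phi, 0), 1), class = "composition")
}

# phi ln phi with the x -> 0+ limit 0; phis clamped only inside the log
.xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))

#' Flory-Huggins free-energy density
#'
#' Free-energy density of the ternary monomer/aggregate/solvent mixture,
#' f/kB*T = phi1/v1 ln(phi1) + phi2/v2 ln(phi2) + phis/vs ln(phis)
#'        + chi12 phi1 phi2 + (chi1s phi1 + chi2s phi2) phis,
#' in kB*T per reference volume (kB*T = 1 internally). Boundary fractions
#' are handled through the limit phi ln(phi) -> 0.
#'
#' @param comp a [composition()] (or any length-3 vector phi1, phi2, phis).
#' @param params an [interaction_params()].
#' @return Free-energy density (scalar).
#' @export
free_energy_density <- function(comp, params) {
  phi <- as.numeric(comp)
  if (any(phi < 0)) stop("negative volume fraction", call. = FALSE)
  p1 <- phi[1]; p2 <- phi[2]; ps <- phi[3]
  .xlogx(p1) / params$v1 + .xlogx(p2) / params$v2 + .xlogx(ps) / params$vs +
    params$chi12 * p1 * p2 + (params$chi1s * p1 + params$chi2s * p2) * ps
}

# Reduced free energy and partials in the independent variables (phi1, phi2)
# after eliminating phis = 1 - phi1 - phi2; logs are clamped for use inside
# root finding near the simplex boundary.
.f_reduced <- function(p1, p2, params, clamp = 1e-12) {
  ps <- 1 - p1 - p2
  l1 <- log(pmin(pmax(p1, clamp), 1 - clamp))
  l2 <- log(pmin(pmax(p2, clamp), 1 - clamp))
  ls <- log(pmin(pmax(ps, clamp), 1 - clamp))
  f  <- p1 * l1 / params$v1 + p2 * l2 / params$v2 + ps * ls / params$vs +
    params$chi12 * p1 * p2 + (params$chi1s * p1 + params$chi2s * p2) * ps
  df1 <- (l1 + 1) / params$v1 - (ls + 1) / params$vs +
    params$chi12 * p2 + params$chi1s * (ps - p1) - params$chi2s * p2
  df2 <- (l2 + 1) / params$v2 - (ls + 1) / params$vs +
    params$chi12 * p1 + params$chi2s * (ps - p2) - params$chi1s * p1
  list(f = f, df1 = df1, df2 = df2)
}

#' Chemical potentials and osmotic pressure
#'
#' Evaluates the exchange chemical potentials mu_i = vs * df/dphi_i and the
#' osmotic pressure Pi = -f + phi1 df/dphi1 + phi2 df/dphi2, with f treated
#' as a function of (phi1, phi2) after eliminating phis = 1 - phi1 - phi2.
#' These are the quantities equated between coexisting phases.
#'
#' @inheritParams free_energy_density
#' @param eps interior tolerance; compositions with any fraction below `eps`
#'   are rejected (the logarithmic terms diverge on the boundary).
#' @return A list with `f`, `mu1`, `mu2`, `Pi` (class `thermo_state`).
#' @export
thermo_state <- function(comp, params, eps = 1e-10) {
  phi <- as.numeric(comp)
  if (any(phi < eps))
    stop("boundary composition: all volume fractions must exceed ", eps,
         "; clamp or perturb the composition", call. = FALSE)
  d <- .f_reduced(phi[1], phi[2], params, clamp = 0)  # interior: no clamping
  structure(list(f   = d$f,
                 mu1 = params$vs * d$df1,
                 mu2 = params$vs * d$df2,
                 Pi  = -d$f + phi[1] * d$df1 + phi[2] * d$df2),
            class = "thermo_state")
}

# Hessian of the reduced f(phi1, phi2); used for spinodal / stability checks.
.f_hessian <- function(p1, p2, params) {
  ps <- 1 - p1 - p2
  h11 <- 1 / (params$v1 * p1) + 1 / (params$vs * ps) - 2 * params$chi1s
  h22 <- 1 / (params$v2 * p2) + 1 / (params$vs * ps) - 2 * params$chi2s
  h12 <- 1 / (params$vs * ps) + params$chi12 - params$chi1s - params$chi2s
  matrix(c(h11, h12, h12, h22), 2, 2)
}

# TRUE when the homogeneous state at (p1, p2) is locally stable
# (positive-definite Hessian of the reduced free energy).
.is_locally_stable <- function(p1, p2, params) {
  if (p1 <= 0 || p2 <= 0 || p1 + p2 >= 1) {
    # degenerate on an edge: test the surviving binary curvature
    if (p2 <= 0 && p1 > 0 && p1 < 1)
      return(1 / (params$v1 * p1) + 1 / (params$vs * (1 - p1)) -
               2 * params$chi1s > 0)
    if (p1 <= 0 && p2 > 0 && p2 < 1)
      return(1 / (params$v2 * p2) + 1 / (params$vs * (1 - p2)) -
               2 * params$chi2s > 0)
    return(TRUE)
  }
  h <- .f_hessian(p1, p2, params)
  h[1, 1] > 0 && det(h) > 0
}
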