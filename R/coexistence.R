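#' Phase-equilibrium container
#'
#' Result of a coexistence calculation: the dense (I) and dilute (II) phase
#' compositions, the dense-phase volume fraction `nu` = V^I/V from the lever
#' rule, and a `single_phase` flag for averages outside the two-phase region.
#'
#' @param dense,dilute [composition()] objects for phases I and II.
#' @param nu dense-phase volume fraction in [0, 1].
#' @param single_phase logical; TRUE when the mixture does not demix.
#' @param total_f total free energy nu*f(I) + (1-nu)*f(II).
#' @param residual residual norm of the coexistence equations at the solution.
#' @return An object of class `phase_equilibrium`.
#' @export
phase_equilibrium <- function(dense, dilute, nu, single_phase = FALSE,
                              total_f = NA_real_, residual = NA_real_) {
  stopifnot(nu >= -1e-9, nu <= 1 + 1e-9)
  structure(list(dense = dense, dilute = dilute,
                 nu = min(max(nu, 0), 1),
                 single_phase = isTRUE(single_phase),
                 total_f = total_f, residual = residual),
            class = "phase_equilibrium")
}

#' @export
print.phase_equilibrium <- function(x, ...) {
  if (x$single_phase) {
    cat("Single phase at composition:\n")
    print(round(unclass(x$dense), 6))
  } else {
    cat(sprintf("Two-phase equilibrium (nu = %.4f):\n", x$nu))
    m <- rbind(dense = as.numeric(x$dense), dilute = as.numeric(x$dilute))
    colnames(m) <- c("phi1", "phi2", "phis")
    print(round(m, 6))
  }
  invisible(x)
}

#' Symmetric binary binodal by bisection
#'
#' For a binary protein/solvent mixture with equal molecular volumes the
#' coexisting fractions are symmetric about 1/2 and solve
#' ln(phi/(1-phi)) = chi*(2*phi - 1). Demixing requires chi > 2 (the
#' critical point of the symmetric mixture).
#'
#' @param chi interaction parameter.
#' @param tol root tolerance.
#' @return Named vector `c(dense =, dilute =)`; both 0.5 (no demixing)
#'   when `chi <= 2`.
#' @export
binary_binodal <- function(chi, tol = 1e-12) {
  if (chi <= 2) return(c(dense = 0.5, dilute = 0.5))
  g <- function(p) log(p / (1 - p)) - chi * (2 * p - 1)
  r <- stats::uniroot(g, c(0.5 + 1e-9, 1 - 1e-12), tol = tol)$root
  c(dense = r, dilute = 1 - r)
}

# Simplex parametrization: two unconstrained reals per phase ->
# (phi1, phi2) strictly inside the simplex.
.to_simplex <- function(a, b) {
  ea <- exp(a); eb <- exp(b); z <- 1 + ea + eb
  c(ea / z, eb / z)
}
.from_simplex <- function(p1, p2, floor = 1e-4) {
  p1 <- max(p1, floor); p2 <- max(p2, floor)
  ps <- max(1 - p1 - p2, floor)
  c(log(p1 / ps), log(p2 / ps))
}

# Residuals of the five coexistence equations: equal chemical potentials,
# equal osmotic pressure, and the two lever-rule mass balances.
.coex_residuals <- function(x, avg, params) {
  pI  <- .to_simplex(x[1], x[2])
  pII <- .to_simplex(x[3], x[4])
  nu  <- stats::plogis(x[5])
  dI  <- .f_reduced(pI[1],  pI[2],  params)
  dII <- .f_reduced(pII[1], pII[2], params)
  c(params$vs * (dI$df1 - dII$df1),
    params$vs * (dI$df2 - dII$df2),
    (-dI$f  + pI[1]  * dI$df1  + pI[2]  * dI$df2) -
    (-dII$f + pII[1] * dII$df1 + pII[2] * dII$df2),
    nu * pI[1] + (1 - nu) * pII[1] - avg[1],
    nu * pI[2] + (1 - nu) * pII[2] - avg[2])
}

.single_phase_result <- function(avg, params) {
  comp <- composition(avg[1], avg[2])
  phase_equilibrium(comp, comp, nu = 1, single_phase = TRUE,
                    total_f = free_energy_density(comp, params), residual = 0)
}

# Solve the binary (phi2 ~ 0) coexistence problem; equal-volume case by
# bisection, which also seeds the general ternary continuation.
.solve_binary <- function(avg1, params) {
  bb <- binary_binodal(params$chi1s)
  if (bb["dense"] - bb["dilute"] < 1e-6) return(NULL)     # no demixing
  if (avg1 <= bb["dilute"] || avg1 >= bb["dense"]) return(NULL)  # outside binodal
  nu <- (avg1 - bb[["dilute"]]) / (bb[["dense"]] - bb[["dilute"]])
  list(dense = c(bb[["dense"]], 0), dilute = c(bb[["dilute"]], 0), nu = nu)
}

#' Solve ternary phase coexistence
#'
#' Finds the two coexisting compositions and phase volume fraction for a
#' given average composition by solving the five-equation system: equality
#' of both chemical potentials and of the osmotic pressure between phases,
#' plus the two lever-rule mass balances that pin the tie-line to the
#' average. Compositions are parametrized on the interior of the simplex so
#' the solver cannot leave the physical domain. When no two-phase solution
#' with lower total free energy than the homogeneous state exists (or the
#' solver collapses onto the trivial identical-phases root while the
#' homogeneous state is locally stable), a `single_phase` result is
#' returned.
#'
#' @param avg average [composition()].
#' @param params [interaction_params()].
#' @param guess optional `phase_equilibrium` used as warm start
#'   (continuation along a trajectory).
#' @param tol residual-norm convergence tolerance.
#' @param max_restarts randomized restarts after a failed solve.
#' @return A [phase_equilibrium()].
#' @export
solve_coexistence <- function(avg, params, guess = NULL,
                              tol = 1e-10, max_restarts = 5) {
  avg <- as.numeric(avg)[1:2]

  # pure binary average: handle on the binary edge directly
  if (avg[2] < 1e-10) {
    b <- .solve_binary(avg[1], params)
    if (is.null(b)) return(.single_phase_result(avg, params))
    return(phase_equilibrium(
      composition(b$dense[1], 0), composition(b$dilute[1], 0), b$nu,
      total_f = b$nu * free_energy_density(composition(b$dense[1], 0), params) +
        (1 - b$nu) * free_energy_density(composition(b$dilute[1], 0), params),
      residual = 0))
  }

  starts <- list()
  if (!is.null(guess) && !guess$single_phase) {
    g <- guess
    starts[[length(starts) + 1]] <-
      c(.from_simplex(g$dense[[1]], g$dense[[2]]),
        .from_simplex(g$dilute[[1]], g$dilute[[2]]),
        stats::qlogis(min(max(g$nu, 1e-6), 1 - 1e-6)))
  } else {
    cont <- .continuation_start(avg, params, tol)
    if (!is.null(cont)) starts[[length(starts) + 1]] <- cont
  }
  # heuristic corner start as a fallback
  prot <- avg[1] + avg[2]; ratio <- avg[1] / prot
  pd <- min(0.9, prot * 1.6); pl <- prot * 0.08
  starts[[length(starts) + 1]] <-
    c(.from_simplex(pd * ratio, pd * (1 - ratio)),
      .from_simplex(pl * ratio, pl * (1 - ratio)),
      stats::qlogis(0.5))
  if (!is.null(guess) && !guess$single_phase) {
    # continuation as a last resort when the warm start goes stale
    starts[[length(starts) + 1]] <- quote(.continuation_start(avg, params, tol))
  }

  # a converged, non-trivial solution is accepted; trivial (identical
  # phases) roots and unconverged attempts trigger the next start, a
  # brute-force-seeded refinement, and finally the stability verdict
  attempt <- function(x0) {
    fit <- try(minpack.lm::nls.lm(
      par = x0, fn = .coex_residuals, avg = avg, params = params,
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  solution <- NULL
  worst_res <- Inf
  for (s0 in starts) {
    if (is.language(s0)) s0 <- eval(s0)
    if (is.null(s0)) next
    for (r in 0:max_restarts) {
      x0 <- if (r == 0) s0 else s0 + stats::rnorm(5, sd = 0.5 * r)
      fit <- attempt(x0)
      if (is.null(fit)) next
      res <- sqrt(sum(fit$fvec^2))
      worst_res <- min(worst_res, res)
      if (res >= tol) next
      pI  <- .to_simplex(fit$par[1], fit$par[2])
      pII <- .to_simplex(fit$par[3], fit$par[4])
      if (sqrt(sum((pI - pII)^2)) < 1e-4) next     # trivial root
      solution <- fit
      break
    }
    if (!is.null(solution)) break
  }

  if (is.null(solution)) {
    # seed from the grid optimum of the exhaustive tie-line search
    bf <- try(brute_force_equilibrium(avg, params, grid_n = 120),
              silent = TRUE)
    if (!inherits(bf, "try-error") && !bf$single_phase) {
      x0 <- c(.from_simplex(bf$dense[[1]], bf$dense[[2]]),
              .from_simplex(bf$dilute[[1]], bf$dilute[[2]]),
              stats::qlogis(min(max(bf$nu, 1e-6), 1 - 1e-6)))
      fit <- attempt(x0)
      if (!is.null(fit) && sqrt(sum(fit$fvec^2)) < tol) {
        pI  <- .to_simplex(fit$par[1], fit$par[2])
        pII <- .to_simplex(fit$par[3], fit$par[4])
        if (sqrt(sum((pI - pII)^2)) >= 1e-4) solution <- fit
      }
    }
  }

  if (is.null(solution)) {
    if (.is_locally_stable(avg[1], avg[2], params))
      return(.single_phase_result(avg, params))
    stop("coexistence solver failed to converge; best residual norm = ",
         signif(worst_res, 6), call. = FALSE)
  }

  x <- solution$par
  pI  <- .to_simplex(x[1], x[2])
  pII <- .to_simplex(x[3], x[4])
  nu  <- stats::plogis(x[5])

  # orient: phase I is the protein-dense phase
  if (sum(pI) < sum(pII)) { tmp <- pI; pI <- pII; pII <- tmp; nu <- 1 - nu }

  dense  <- composition(pI[1], pI[2])
  dilute <- composition(pII[1], pII[2])
  total_f <- nu * free_energy_density(dense, params) +
    (1 - nu) * free_energy_density(dilute, params)
  f_hom <- free_energy_density(composition(avg[1], avg[2]), params)
  if (total_f > f_hom + 1e-12)
    return(.single_phase_result(avg, params))
  phase_equilibrium(dense, dilute, nu, total_f = total_f,
                    residual = sqrt(sum(solution$fvec^2)))
}

# Continuation start for a ternary average with no warm start: begin from
# the binary problem with all protein counted as monomer, then ramp the
# aggregate share of the average in small steps, re-solving each time.
.continuation_start <- function(avg, params, tol, n_steps = 20) {
  prot <- avg[1] + avg[2]
  b <- .solve_binary(prot, params)
  if (is.null(b)) {
    # monomer alone does not demix; try the aggregate-dominated edge
    p2 <- interaction_params(params$chi12, params$chi2s, params$chi1s,
                             params$v2, params$v1, params$vs)
    b2 <- .solve_binary(prot, p2)
    if (is.null(b2)) return(NULL)
    b <- list(dense = c(0, b2$dense[1]), dilute = c(0, b2$dilute[1]),
              nu = b2$nu)
    from_edge2 <- TRUE
  } else from_edge2 <- FALSE

  eps0 <- 1e-6
  x <- c(.from_simplex(max(b$dense[1], eps0),  max(b$dense[2], eps0)),
         .from_simplex(max(b$dilute[1], eps0), max(b$dilute[2], eps0)),
         stats::qlogis(min(max(b$nu, 1e-6), 1 - 1e-6)))
  lams <- seq(0, 1, length.out = n_steps + 1)[-1]
  for (lam in lams) {
    a_lam <- if (from_edge2)
      c(lam * avg[1], prot - lam * avg[1]) else
      c(prot - lam * avg[2], lam * avg[2])
    fit <- try(minpack.lm::nls.lm(
      par = x, fn = .coex_residuals, avg = a_lam, params = params,
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error") || sqrt(sum(fit$fvec^2)) > 1e-6)
      return(NULL)
    x <- fit$par
  }
  x
}

#' Brute-force coexistence by exhaustive tie-line search
#'
#' Independent oracle for [solve_coexistence()]. Any pair of coexisting
#' compositions satisfying the lever rule must be collinear with the
#' average, so the search enumerates tie-line directions through the
#' average and, along each, all grid pairs straddling the average with
#' lever-rule weights, minimizing the total free energy. Not meant for
#' production use; it validates the equation-based solver.
#'
#' @param avg average [composition()].
#' @param params [interaction_params()].
#' @param grid_n grid points per axis (directions and per-side samples);
#'   at least 50.
#' @return A [phase_equilibrium()] (grid-resolution accuracy).
#' @export
brute_force_equilibrium <- function(avg, params, grid_n = 200) {
  stopifnot(grid_n >= 50)
  if (grid_n > 2000) stop("grid_n too large", call. = FALSE)
  avg <- as.numeric(avg)[1:2]
  margin <- 1e-9
  f_hom <- free_energy_density(composition(avg[1], avg[2]), params)

  f_of <- function(p) {   # vectorized free energy over rows of (p1, p2)
    ps <- 1 - p[, 1] - p[, 2]
    .xlogx(p[, 1]) / params$v1 + .xlogx(p[, 2]) / params$v2 +
      .xlogx(ps) / params$vs + params$chi12 * p[, 1] * p[, 2] +
      (params$chi1s * p[, 1] + params$chi2s * p[, 2]) * ps
  }

  best <- list(F = f_hom, single = TRUE)
  thetas <- seq(0, pi, length.out = grid_n + 1)[-(grid_n + 1)]
  for (th in thetas) {
    u <- c(cos(th), sin(th))
    # max step sizes keeping avg +/- t*u inside the closed simplex
    tmax_dir <- function(sgn) {
      v <- sgn * u
      lims <- c(if (v[1] < 0) (margin - avg[1]) / v[1] else
                  if (v[1] > 0) (1 - margin - avg[1]) / v[1] else Inf,
                if (v[2] < 0) (margin - avg[2]) / v[2] else
                  if (v[2] > 0) (1 - margin - avg[2]) / v[2] else Inf,
                if (sum(v) > 0) (1 - margin - sum(avg)) / sum(v) else
                  if (sum(v) < 0) (margin - sum(avg)) / sum(v) else Inf)
      max(min(lims), 0)
    }
    tp <- tmax_dir(1); tm <- tmax_dir(-1)
    if (tp < 1e-6 || tm < 1e-6) next
    ta <- seq(tp / grid_n, tp, length.out = grid_n)   # + side
    tb <- seq(tm / grid_n, tm, length.out = grid_n)   # - side
    Pa <- cbind(avg[1] + ta * u[1], avg[2] + ta * u[2])
    Pb <- cbind(avg[1] - tb * u[1], avg[2] - tb * u[2])
    fa <- f_of(Pa); fb <- f_of(Pb)
    # lever: nu weights the + side; nu = tb_j / (ta_i + tb_j)
    Tsum <- outer(ta, tb, "+")
    Nu <- sweep(1 / Tsum, 2, tb, "*")
    Fb <- matrix(fb, nrow = length(ta), ncol = length(tb), byrow = TRUE)
    Ftot <- Nu * fa + (1 - Nu) * Fb
    idx <- arrayInd(which.min(Ftot), dim(Ftot))
    if (Ftot[idx] < best$F - 1e-12) {
      i <- idx[1]; j <- idx[2]
      best <- list(F = Ftot[idx], single = FALSE,
                   pa = Pa[i, ], pb = Pb[j, ], nu = Nu[i, j])
    }
  }

  if (best$single) return(.single_phase_result(avg, params))
  pa <- best$pa; pb <- best$pb; nu <- best$nu
  if (sum(pa) < sum(pb)) { tmp <- pa; pa <- pb; pb <- tmp; nu <- 1 - nu }
  phase_equilibrium(composition(pa[1], pa[2]), composition(pb[1], pb[2]),
                    nu, total_f = best$F, residual = NA_real_)
}
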