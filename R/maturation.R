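#' Aggregation kinetic parameters
#'
#' @param k1 forward (monomer -> aggregate) rate, 1/day.
#' @param k2 backward rate, 1/day.
#' @param phi_tot total protein volume fraction in (0, 1); the system starts
#'   fully monomeric, phi1(0) = phi_tot.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1, k2, phi_tot) {
  stopifnot(k1 >= 0, k2 >= 0, phi_tot > 0, phi_tot < 1)
  structure(list(k1 = k1, k2 = k2, phi_tot = phi_tot),
            class = "kinetic_params")
}

#' Closed-form aggregation kinetics of the average volume fractions
#'
#' First-order monomer <-> aggregate interconversion with phase-independent
#' rates gives, for a mixture starting fully monomeric,
#' \deqn{\bar\phi_1(t) = \frac{\phi_{tot}}{k_1+k_2}\,(k_2 + k_1 e^{-(k_1+k_2)t}),\quad
#'       \bar\phi_2(t) = \frac{\phi_{tot}}{k_1+k_2}\,(k_1 - k_1 e^{-(k_1+k_2)t}).}
#' Conservation \eqn{\bar\phi_1 + \bar\phi_2 = \phi_{tot}} holds exactly.
#'
#' @param kin [kinetic_params()].
#' @param times numeric vector of times in days, all >= 0.
#' @return A data.frame with columns `time_days`, `avg_phi1`, `avg_phi2`.
#' @export
aggregation_trajectory <- function(kin, times) {
  stopifnot(all(times >= 0))
  k <- kin$k1 + kin$k2
  if (k == 0) {
    phi1 <- rep(kin$phi_tot, length(times))
  } else {
    phi1 <- kin$phi_tot / k * (kin$k2 + kin$k1 * exp(-k * times))
  }
  data.frame(time_days = times, avg_phi1 = phi1,
             avg_phi2 = kin$phi_tot - phi1)
}

#' Simulate condensate maturation in coexisting phases
#'
#' Couples the aggregation kinetics to instantaneous phase equilibrium:
#' phase separation is assumed much faster than aggregation, so at every
#' kinetic time point the average monomer/aggregate composition from
#' [aggregation_trajectory()] is re-equilibrated with
#' [solve_coexistence()], warm-starting each solve from the previous time
#' point. This yields the time evolution of monomer, aggregate and solvent
#' fractions in the dense (I) and dilute (II) phases — in particular the
#' dense-phase solvent fraction, whose direction of change (solvent influx
#' vs efflux) is set by the sign of chi1s - chi2s.
#'
#' @param kin [kinetic_params()].
#' @param params [interaction_params()].
#' @param times strictly increasing times in days.
#' @return A `maturation_trajectory`: list with `table` (one row per time
#'   point: averages, both phase compositions, `nu`, `single_phase`) and
#'   `equilibria` (list of [phase_equilibrium()]).
#' @export
simulate_maturation <- function(kin, params, times) {
  stopifnot(length(times) >= 1, all(diff(times) > 0), all(times >= 0))
  traj <- aggregation_trajectory(kin, times)
  eqs <- vector("list", length(times))
  guess <- NULL
  for (i in seq_along(times)) {
    eq <- tryCatch(
      solve_coexistence(c(traj$avg_phi1[i], traj$avg_phi2[i]), params,
                        guess = guess),
      error = function(e)
        stop("coexistence solve failed at time index ", i, " (t = ",
             times[i], " d): ", conditionMessage(e), call. = FALSE))
    eqs[[i]] <- eq
    if (!eq$single_phase) guess <- eq
  }
  tab <- cbind(
    traj,
    do.call(rbind, lapply(eqs, function(eq) data.frame(
      phi1_I  = eq$dense[[1]],  phi2_I  = eq$dense[[2]],
      phis_I  = eq$dense[[3]],
      phi1_II = eq$dilute[[1]], phi2_II = eq$dilute[[2]],
      phis_II = eq$dilute[[3]],
      nu = eq$nu, single_phase = eq$single_phase))))
  structure(list(table = tab, equilibria = eqs, kin = kin, params = params),
            class = "maturation_trajectory")
}

#' @export
print.maturation_trajectory <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("Maturation trajectory: %d time points over %.3g days\n",
              n, max(x$table$time_days)))
  cat(sprintf("  dense-phase solvent fraction: %.4f -> %.4f\n",
              x$table$phis_I[1], x$table$phis_I[n]))
  invisible(x)
}

#' Bundled model scenarios
#'
#' The three parameter sets used for the maturation simulations:
#' `regimeA` (chi1s = 3 > chi2s = 2.1, k1 = 0.2/d, k2 = 0.1/d,
#' phi_tot = 0.55; aggregation weakens the dense phase's solvent repulsion,
#' so solvent flows into the droplet), `regimeB` (chi1s = 2.1 < chi2s = 3,
#' k1 = 0.1/d, k2 = 0.05/d; solvent is expelled), and `regimeA_high`
#' (regime A interactions at phi_tot = 0.8, the concentration variant).
#' All use equal molecular volumes and chi12 = 0.
#'
#' @param name one of `"regimeA"`, `"regimeB"`, `"regimeA_high"`, or
#'   `NULL` to return the full named list.
#' @return A list with elements `params` ([interaction_params()]) and
#'   `kin` ([kinetic_params()]) — or a named list of such scenarios.
#' @export
model_scenarios <- function(name = NULL) {
  sc <- list(
    regimeA = list(
      params = interaction_params(chi12 = 0, chi1s = 3, chi2s = 2.1),
      kin = kinetic_params(k1 = 0.2, k2 = 0.1, phi_tot = 0.55)),
    regimeB = list(
      params = interaction_params(chi12 = 0, chi1s = 2.1, chi2s = 3),
      kin = kinetic_params(k1 = 0.1, k2 = 0.05, phi_tot = 0.55)),
    regimeA_high = list(
      params = interaction_params(chi12 = 0, chi1s = 3, chi2s = 2.1),
      kin = kinetic_params(k1 = 0.2, k2 = 0.1, phi_tot = 0.8)))
  if (is.null(name)) return(sc)
  if (!name %in% names(sc))
    stop("unknown scenario: ", name, call. = FALSE)
  sc[[name]]
}

#' Write or read scenario presets as JSON
#'
#' Serializes [model_scenarios()] to the JSON parameter-file layout
#' (keys chi12, chi1s, chi2s, v1, v2, vs, k1_per_day, k2_per_day, phi_tot,
#' t_max_days, n_times) and reads such files back.
#'
#' @param path file path.
#' @param t_max_days,n_times time-grid fields stored alongside the model
#'   parameters.
#' @return `write_model_scenarios` returns `path` invisibly;
#'   `read_model_scenario` returns a scenario list plus a `times` vector.
#' @export
write_model_scenarios <- function(path, t_max_days = 20, n_times = 81) {
  sc <- model_scenarios()
  out <- lapply(sc, function(s) list(
    chi12 = s$params$chi12, chi1s = s$params$chi1s, chi2s = s$params$chi2s,
    v1 = s$params$v1, v2 = s$params$v2, vs = s$params$vs,
    k1_per_day = s$kin$k1, k2_per_day = s$kin$k2, phi_tot = s$kin$phi_tot,
    t_max_days = t_max_days, n_times = n_times))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_scenarios
#' @param name scenario name inside the file (for multi-scenario files).
#' @export
read_model_scenario <- function(path, name = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(name)) j <- j[[name]]
  list(params = interaction_params(j$chi12, j$chi1s, j$chi2s,
                                   j$v1, j$v2, j$vs),
       kin = kinetic_params(j$k1_per_day, j$k2_per_day, j$phi_tot),
       times = seq(0, j$t_max_days, length.out = j$n_times))
}
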