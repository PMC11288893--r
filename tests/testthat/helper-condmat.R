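# Shared fixtures for the test suite; everything is generated in code.

# default interaction set used throughout: monomer more solvophobic than
# aggregate, no direct monomer-aggregate interaction
regimeA_params <- function() interaction_params(chi12 = 0, chi1s = 3,
                                                chi2s = 2.1)

# independent binary-binodal oracle: bisection on the symmetric condition
oracle_binary_binodal <- function(chi) {
  stopifnot(chi > 2)
  g <- function(p) log(p / (1 - p)) - chi * (2 * p - 1)
  r <- uniroot(g, c(0.5 + 1e-9, 1 - 1e-12), tol = 1e-14)$root
  c(dense = r, dilute = 1 - r)
}

# maximum lever-rule mass-balance error of an equilibrium
mass_balance_error <- function(eq, avg) {
  avg3 <- c(avg[1], avg[2], 1 - avg[1] - avg[2])
  mix <- eq$nu * as.numeric(eq$dense) + (1 - eq$nu) * as.numeric(eq$dilute)
  max(abs(mix - avg3))
}

# noiseless two-component decay curve with known ground truth
clean_two_pop_curve <- function(a_slow = 0.6, d_fast = 1e-10, ratio = 500,
                                acq = dosy_acquisition()) {
  g <- dosy_gradients(acq)
  I <- stejskal_tanner(g, 1 - a_slow, d_fast, acq) +
    stejskal_tanner(g, a_slow, d_fast / ratio, acq)
  decay_curve(g, I)
}
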