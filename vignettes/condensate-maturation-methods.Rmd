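---
title: "Models and methods for quantifying condensate maturation"
author: "condmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying condensate maturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condmat)
```

Protein condensates formed by liquid–liquid phase separation (LLPS) — FUS
droplets being the canonical example — age from liquid droplets toward
solid, fibril-like states. `condmat` collects the computational machinery
for studying that maturation: a ternary phase-separation/aggregation
model, and the quantification procedures for the three spectroscopic
readouts that track it (solution-state DOSY NMR, real-time CP/INEPT
solid-state NMR, and hyperspectral coherent Raman imaging), plus
chemical-shift secondary-structure classification. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The ternary maturation model

The solution is treated as an incompressible ternary mixture of protein
monomers (volume fraction $\phi_1$), aggregates ($\phi_2$) and solvent
($\phi_s = 1-\phi_1-\phi_2$), with the Flory–Huggins free-energy density
(in units of $k_BT$ per reference volume)

$$
f = \frac{\phi_1}{v_1}\ln\phi_1 + \frac{\phi_2}{v_2}\ln\phi_2 +
    \frac{\phi_s}{v_s}\ln\phi_s + \chi_{12}\phi_1\phi_2 +
    (\chi_{1s}\phi_1 + \chi_{2s}\phi_2)\,\phi_s .
$$

Coexistence between the droplet phase (I) and the dilute phase (II)
requires equality of both exchange chemical potentials
$\mu_i = v_s\,\partial f/\partial\phi_i$ and of the osmotic pressure
$\Pi = -f + \phi_1\,\partial f/\partial\phi_1 +
\phi_2\,\partial f/\partial\phi_2$. Both are evaluated after eliminating
$\phi_s$, i.e. with $f$ treated as a function of $(\phi_1,\phi_2)$ only;
this makes the coexistence system well posed under the incompressibility
constraint. $\Pi$ is implemented exactly in this form, without adjusting
it to any other osmotic-pressure convention.

Aggregation is a first-order interconversion
$\phi_1 \rightleftharpoons \phi_2$ with phase-independent forward and
backward rates $k_1, k_2$ (units 1/day). For a mixture that starts fully
monomeric at total protein fraction $\phi_{tot}$, the average fractions
follow the closed form

$$
\bar\phi_1(t) = \frac{\phi_{tot}}{k_1+k_2}\left(k_2 + k_1
  e^{-(k_1+k_2)t}\right),\qquad
\bar\phi_2(t) = \phi_{tot} - \bar\phi_1(t),
$$

implemented in `aggregation_trajectory()`. Phase separation is assumed
much faster than aggregation, so `simulate_maturation()` re-solves the
coexistence problem at every kinetic time point for the current averages,
warm-starting from the previous solution. The interesting observable is
the dense-phase solvent fraction $\phi_s^I(t)$: when
$\chi_{1s} > \chi_{2s}$ (the aggregate repels solvent less than the
monomer), aggregation draws solvent *into* the droplet; when
$\chi_{1s} < \chi_{2s}$ it pushes solvent *out*. The two bundled
scenarios (`model_scenarios()`) encode exactly these two regimes —
regime A: $\chi_{1s}=3$, $\chi_{2s}=2.1$, $k_1=0.2$/d, $k_2=0.1$/d,
$\phi_{tot}=0.55$; regime B: $\chi_{1s}=2.1$, $\chi_{2s}=3$,
$k_1=0.1$/d, $k_2=0.05$/d — plus a $\phi_{tot}=0.8$ concentration
variant of regime A. All use equal molecular volumes and
$\chi_{12}=0$.

### Solving coexistence

`solve_coexistence()` solves five equations — the three equalities plus
the two lever-rule mass balances
$\nu\phi_i^I + (1-\nu)\phi_i^{II} = \bar\phi_i$ — for the five unknowns
$(\phi_1^I,\phi_2^I,\phi_1^{II},\phi_2^{II},\nu)$. The binodal alone is
a one-parameter family of tie-lines; the average composition selects the
tie-line, which is why the lever-rule equations are part of the system
rather than applied afterwards.

Numerical choices, all of which were genuinely open:

* **Domain control.** Each phase composition is parametrized on the open
  simplex through a two-variable softmax and $\nu$ through a logistic,
  so Levenberg–Marquardt iterations can never leave the physical domain;
  logs are additionally clamped to $[10^{-12}, 1-10^{-12}]$ during
  residual evaluation.
* **Convergence.** Residual-norm tolerance $10^{-10}$, at most 200
  iterations per attempt, up to 5 randomized restarts per start.
* **Starts.** A binary ($\phi_2=0$) bisection solution seeds the $t=0$
  problem; later time points warm-start from the previous equilibrium.
  Cold ternary calls run a short continuation that ramps the aggregate
  share of the average from zero. If every equation-based start fails,
  the grid optimum of the brute-force search seeds one final polish.
* **Trivial root.** The identical-phases root satisfies the equations at
  any composition; solutions with $\lVert$dense$-$dilute$\rVert <
  10^{-4}$ are rejected. A composition where nothing non-trivial is found
  is declared single-phase only after checking that the Hessian of $f$
  is positive definite there (i.e. the homogeneous state is at least
  metastable); otherwise the solver raises an error instead of returning
  a wrong answer. A converged two-phase solution whose total free energy
  exceeds the homogeneous value is likewise demoted to single-phase.

`brute_force_equilibrium()` is the independent oracle: any pair of
phases obeying the lever rule is collinear with the average, so it
enumerates tie-line directions through the average and, along each, all
grid pairs straddling the average with lever-rule weights, minimizing
total free energy. It validates the equation-based solver (the test
suite requires agreement to $10^{-3}\,k_BT$ and grid-resolution
composition agreement) but is itself too coarse for production use.

## DOSY phase quantification

Condensed-phase protein diffuses at least two orders of magnitude more
slowly than dilute protein, so a pulsed-gradient decay curve is a
two-population Stejskal–Tanner sum
$A_1 e^{-D_1 b(g)} + A_2 e^{-D_2 b(g)}$ with
$b(g) = \gamma^2 g^2\delta^2(\Delta-\delta/3)$. Two estimators are
provided because the original analysis could have used either:

* `endpoint_fractions()` takes the ratio $I(g_{max})/I(g_{min})$ — at
  the weakest gradient all protein contributes, at the strongest only
  the condensed pool survives. "Zero gradient" is operationalized as the
  weakest measured gradient (2% of maximum), since $I(0)$ is never
  measured.
* `fit_two_populations()` fits the two-exponential model with the
  constraint $D_1/D_2 \ge 100$ (the `ratio_floor`), normalizing
  amplitudes to fractions. Because two-exponential fits are prone to
  local minima, the fit uses variable projection — amplitudes solve a
  linear least-squares problem for each candidate $(D_1, D_1/D_2)$ on a
  coarse grid — to pick the start for a full Levenberg–Marquardt polish,
  and the curve is internally normalized to unit scale so the result is
  exactly invariant under intensity rescaling.

Default acquisition constants are $\Delta = 50$ ms, $\delta = 10$ ms,
$\gamma = 2.675\times10^8$ rad s$^{-1}$T$^{-1}$ (protons), and 16
gradient fractions spanning 2–95% of maximum. The hardware maximum
gradient is not part of the experimental record, so a typical 0.5 T/m is
the configurable default; gradients are stored in absolute T/m to keep
units safe. A diffusion time of 0.1 s is selectable for the longer-Δ
variant of the experiment.

## Solid-state NMR kinetics

CP spectra report immobilized protein and grow as maturation proceeds;
INEPT spectra report mobile protein and decay only slowly.
`integrate_region()` performs sign-preserving trapezoidal integration
over ppm windows; the bundled defaults (`default_regions()`: carbonyl
165–182, aromatic 105–140, Cα 50–65, Gly Cα 42–48, Cβ 15–40 ppm, plus
the $^1$H imino window 10–15 ppm used for RNA) are conventional ranges —
the published figures mark the windows only graphically, so the exact
boundaries are declared here, not inferred, and everything is
configurable. Series are normalized to the spectrum measured at 48 h
(`normalize_series()`), times are converted from hours to days, and
`fit_linear_rate()` performs ordinary least squares so slopes come out
in 1/days, the unit the measured slopes are reported in.
`compare_rates()` forms per-region slope ratios (droplet sample over
bulk sample) with errors propagated in quadrature on the relative
scale.

`signal_to_noise()` implements two definitions: the conventional peak
height over twice the noise r.m.s. (default), and the vendor SiNo
formula stated with the measured kinetics — peak height divided by the
*square* of the noise intensity. The printed definition is dimensionally
unusual (it is not invariant under intensity rescaling: doubling a
spectrum halves it), so both are exposed and neither intent is guessed.

## Chemical-shift secondary structure

`class_posterior()` treats each secondary-structure class (helix, sheet,
coil) as an independent Gaussian in Cα and Cβ and returns the normalized
posterior under configurable priors; a missing dimension simply drops
its factor. `classify_cb_band()` is the 1D Cβ-only variant used when
only the band position is known: it assigns the class with the highest
Gaussian density (equivalently the smallest width-penalized deviation
$z^2/2 + \ln\sigma$), reports all z-scores, and breaks exact ties
deterministically in the order helix < sheet < coil with a flag.

The per-class statistics live in an editable CSV
(`inst/extdata/shift_stats_synthetic.csv`), not in code, because such
statistics come from published compilations that users will want to
swap in. The bundled table holds synthetic, representative values on the
scale of those compilations (e.g. the threonine Cβ moves from ~68.5 ppm
in helices to ~71.3 ppm in sheets); under it, the matured-fibril
threonine fingerprint (Cα 61.2, Cβ 72.3 ppm) classifies as β-sheet, and
classes whose means are two pooled standard deviations apart are
recovered from sampled shifts with >80% accuracy. Replace the file with
a database-derived table for production analyses.

`predict_correlation_peaks()` back-predicts 2D peak lists from an
assignment table: NCA correlates N(i)–Cα(i), NCO correlates
N(i)–C'(i−1), and DARR at short mixing (~20 ms) yields all intra-residue
carbon–carbon pairs at both symmetric positions; a `sequential` option
adds Cα–Cα and C'–Cα sequential contacts for long mixing times, since
short-mixing spectra are dominated by one-bond transfers. Missing atoms
are skipped and counted, and output is sorted so the prediction is
invariant to assignment row order.

## Hyperspectral CARS processing

Raw broadband CARS spectra mix the resonant susceptibility with a
nonresonant background; `kk_retrieve()` recovers the Raman-like spectrum
by the Kramers–Kronig route, using the measured spectrum of the
surrounding nonresonant medium (agarose) as reference: the phase is the
Hilbert transform of $\tfrac12\ln(I_{CARS}/I_{NR})$ and the Raman-like
amplitude is $\sqrt{I_{CARS}/I_{NR}}\,\sin\varphi$. The Hilbert
transform is computed through the FFT analytic-signal construction with
mirror-image edge padding to suppress wrap-around; its sign is fixed so
that resonances retrieve positive. This measured-reference-normalized
formulation is a declared design choice — the reference implementation
behind the published processing chain is cited there, not restated — and
the generators' ground truth verifies it: retrieved line centers land
within one spectral bin and linewidths match the grid-sampled
$\mathrm{Im}\,\chi_R$ within a bin.

`remove_error_phase()` removes the slowly varying error phase left by an
imperfect reference with a Savitzky–Golay smoother (second-order
polynomial, 400 cm$^{-1}$ window converted to the nearest odd sample
count, since the filter needs odd windows); a second-order filter
reproduces quadratic phase backgrounds exactly. Note the smoothing also
absorbs part of very broad line wings, so quantitative lineshape work
should use the raw retrieval when the reference is trusted.

`amide_map()` integrates the corrected spectra over the amide I band
(1600–1700 cm$^{-1}$ default) per pixel; `segment_rings()` thresholds
the map (Otsu, then largest connected component — segmentation is not
specified by the source experiments, so the most standard choice is
used, with a manual mask override), finds the centroid and cuts the
droplet into `n_rings` equal-width annuli (default 5, matching the
several concentric rings shown in the published figure; equal-width
rather than equal-area is a declared choice). The outermost ring is the
"border". `ring_spectra()` averages per ring, and
`compare_core_shell()` forms border minus pixel-weighted internal after
normalization — area normalization over the 900–1800 cm$^{-1}$
fingerprint by default, max-normalization selectable, since the source
analysis says only "normalized" — and reports the two maturation
markers: height at the 1,618 cm$^{-1}$ tyrosine line and height plus
FWHM of the 1,665 cm$^{-1}$ feature.

Cube I/O is deliberately absent: cubes are in-memory arrays built by
the generator or by user code (no HDF5 reader is part of the package's
dependency set); spectra, maps and metrics export as plain CSV.

## What the generators emulate — and what they do not

`make_nmr_timeseries()` builds Lorentzian multiplets whose areas change
linearly: CP at +0.25/day and INEPT at −0.06/day in normalized units
(value 1 at the 48-h reference), so that roughly half the 48-h CP signal
is already present at 4 h, matching the observed build-up scale. Noise
is additive Gaussian plus a 10% multiplicative per-slot term — the
typical slot-to-slot intensity uncertainty of real-time MAS series.
`make_dosy_decays()` produces two-component decays with a dilute-pool
diffusivity of $10^{-10}$ m$^2$/s and a default contrast of 500 (well
beyond the 100× floor), at configurable SNR. `make_cars_cube()` builds a
disk droplet over an agarose-like background from complex Lorentzian
susceptibilities, with the shell (outer 15% of the radius) carrying a
narrow 1,665 cm$^{-1}$ line and an enhanced 1,618 cm$^{-1}$ line in the
matured state, and Poisson-plus-Gaussian count noise.
`make_shift_observations()` samples per-class Gaussians from the
statistics table. All generators take a single integer seed and echo
their generating parameters, so every estimator's expected output is
computable without re-running the generator.

These are statistical emulators, not physical simulators: no spin
dynamics, no exchange broadening, no baseline/phasing artifacts, no
convection in the DOSY dimension, no nonlinear-optical imaging
aberrations, no multi-droplet fields. Passing the recovery tests
therefore shows that the estimators are correct for data obeying their
stated models at realistic noise, not that they are robust to every
artifact of real instrument data.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by choice:
brute-force oracle grids of 150–200 points per axis and 10 random
parameter draws; 200 DOSY replicates at SNR 100 with 16 gradient
points; 100 CP series of 6 time points over 2 days; 32×32×451 CARS
cubes; 500 shift observations per class. Maturation trajectories use 21
to 81 time points over 20 days. All randomness flows from explicit
integer seeds; identical seed and configuration give byte-identical
synthetic data.

## Known limitations

* The thermodynamic solver targets the two-phase region of this ternary
  model family ($\chi_{12}=0$ scenarios and moderate asymmetries); it
  does not handle three-phase coexistence, which the model can in
  principle exhibit elsewhere in parameter space.
* Spatial dynamics (droplet size distributions, Cahn–Hilliard
  coarsening, surface tension, nucleation/elongation/fragmentation
  kinetics) are out of scope; the kinetic model is the two-rate
  interconversion above.
* `fit_two_populations()` returns an essentially unidentifiable slow
  diffusivity when the condensed pool barely attenuates over the
  gradient range (only the amplitude fraction is then meaningful —
  which is the quantity of interest).
* The bundled shift statistics are synthetic stand-ins; quantitative
  secondary-structure work should substitute a database-derived table.
* Interaction parameters and rate constants are taken as given; fitting
  them to experimental NMR series is not attempted.
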