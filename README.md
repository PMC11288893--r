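# condmat

Phase-separation thermodynamics and spectroscopic analysis of protein
condensate maturation.

Biomolecular condensates formed by liquid–liquid phase separation — FUS
droplets are the archetype — age over days to weeks from liquid droplets
into solid, β-sheet-rich states. `condmat` is for researchers studying
that liquid-to-solid transition who need, in one tested package:

* a **ternary phase-separation + aggregation model** that explains when
  maturation draws solvent into the droplet phase and when it expels it;
* **DOSY NMR quantification** of the condensed vs dilute protein
  fractions from gradient decay curves;
* **real-time solid-state NMR kinetics** — spectral region integration,
  48-h normalization, linear maturation rates, biphasic-vs-monophasic
  rate comparison;
* **chemical-shift secondary-structure classification** (per-class
  Gaussian statistics for Cα/Cβ) and back-prediction of NCA/NCO/DARR
  peak lists from assignment tables;
* **hyperspectral CARS processing** — Kramers–Kronig phase retrieval,
  Savitzky–Golay error-phase removal, amide-I mapping, concentric-ring
  droplet segmentation and core-vs-shell spectral comparison;
* **seeded synthetic-data generators** for every input class, with
  ground truth for parameter-recovery testing.

## The model at the core

An incompressible ternary mixture of monomer (φ₁), aggregate (φ₂) and
solvent (φ_s = 1 − φ₁ − φ₂) with Flory–Huggins free-energy density
(units of k_BT per reference volume)

    f = φ₁/v₁ ln φ₁ + φ₂/v₂ ln φ₂ + φ_s/v_s ln φ_s
        + χ₁₂ φ₁φ₂ + (χ₁ₛ φ₁ + χ₂ₛ φ₂) φ_s .

Droplet (I) and dilute (II) phases coexist when μ₁ᴵ = μ₁ᴵᴵ, μ₂ᴵ = μ₂ᴵᴵ
and Πᴵ = Πᴵᴵ, with μᵢ = v_s ∂f/∂φᵢ and Π = −f + φ₁∂f/∂φ₁ + φ₂∂f/∂φ₂.
Monomers convert to aggregates by first-order kinetics
dφ̄₁/dt = −k₁φ̄₁ + k₂φ̄₂ with the closed-form solution implemented in
`aggregation_trajectory()`; phase separation is fast compared with
aggregation, so `simulate_maturation()` re-solves coexistence at every
time point. The sign of χ₁ₛ − χ₂ₛ sets the direction of solvent flux
into or out of the droplet as aggregation proceeds.

## Worked example

Simulate droplet maturation in the solvent-influx regime (χ₁ₛ = 3,
χ₂ₛ = 2.1, k₁ = 0.2/d, k₂ = 0.1/d, φ_tot = 0.55):

```r
library(condmat)
sc  <- model_scenarios("regimeA")
sim <- simulate_maturation(sc$kin, sc$params, seq(0, 20, length.out = 41))
sim
#> Maturation trajectory: 41 time points over 20 days
#>   dense-phase solvent fraction: 0.0707 -> 0.1619
```

The droplet starts as the dense branch of the binary binodal
(φ_s = 0.0707 at χ = 3) and takes up solvent as the less
solvent-repelling aggregate accumulates — the hallmark of regime A. A
single coexistence solve shows the full tie-line:

```r
solve_coexistence(c(0.4, 0.15), sc$params)
#> Two-phase equilibrium (nu = 0.5565):
#>            phi1     phi2     phis
#> dense  0.669685 0.234319 0.095995
#> dilute 0.061565 0.044185 0.894250
```

`nu` is the dense-phase volume fraction from the lever rule; mass
balance ν·φᴵ + (1−ν)·φᴵᴵ reproduces the average composition to 1e−8.

Classify the threonine fingerprint of matured fibrils (Cα 61.2 ppm,
Cβ 72.3 ppm):

```r
post <- class_posterior("THR", ca = 61.2, cb = 72.3)
round(post, 4)
#>  helix  sheet   coil
#> 0.0000 0.9288 0.0712
attr(post, "map")
#> [1] "sheet"
```

The high-frequency Cβ shift puts the residue firmly in the β-sheet
class — β-structure formed during maturation.

The `analysis/` directory holds five numbered drivers that run the full
workflows (phase model and binodals, DOSY fractions, ssNMR kinetics,
shift classification, Raman core–shell analysis) and write their tables
under `results/`:

```sh
Rscript analysis/01_phase_separation_model.R
# regimeA       phi_s^I: 0.0707 -> 0.1619 (solvent influx)
# regimeB       phi_s^I: 0.3146 -> 0.1076 (solvent efflux)
# ...
```

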