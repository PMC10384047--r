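# ampchem

Physicochemical characterization of cationic amino-acid surfactants and
their phospholipid vesicles, as an R package.

Antimicrobial amphiphiles built from phenylalanine or tryptophan
(CnPC3NH3Cl, CnTC3NH3Cl) are characterized by a standard chain of
measurements: small-angle X-ray scattering (SAXS) of their micelles and of
mixed DPPC vesicles, conductivity and pyrene-fluorescence scans for the
critical micelle concentration (CMC), potentiometric titrations for the
apparent pKa, frontier-orbital reactivity descriptors, and MIC/MBC and
hemolysis assays. ampchem implements that chain end to end for people who
analyze such data: each stage is a tested function with explicit units,
error classes and seeded synthetic-data generators, so the whole pipeline
is reproducible without access to the original instruments.

## Models at the core

- **Core-shell cylinder micelles.** Orientation-averaged form factor
  `I(q) = (phi / V_t) ∫ |A(q, α)|² sin α dα + bkg` with
  `A = Δρ_core V_c Λ(q, R_c, L_c, α) + Δρ_shell V_t Λ(q, R_c+R_h, L_c+2R_h, α)`
  and `Λ = sinc(qL cos α / 2) · 2J₁(qR sin α)/(qR sin α)`. The hydrocarbon
  core density is fixed from Tanford volumes
  (`v = 0.0274 + 0.0269 n` nm³); derived quantities are the aggregation
  number `N_agg = πR_c²L_c / v_chain`, the area per molecule
  `A_m = 2πR_cL_c / N_agg`, and the headgroup hydration.
- **Gaussian bilayers.** Symmetric three-Gaussian electron-density
  contrast profile (headgroups at ±Z_h, methyl trough at the midplane);
  `I(q) = scale · F(q)²/q² + bkg` with `F` the analytic cosine transform
  and `1/q²` the Lorentz factor for randomly oriented sheets.
- **CMC estimators.** Two-line least-squares intersection for conductivity
  (degree of ionization `α = S₂/S₁`, counterion binding `β = 1 − α`);
  Boltzmann sigmoid on log-concentration for the pyrene I₁/I₃ ratio.
- **Apparent pKa.** Exact monoprotic charge-balance titration model;
  equivalence by maximum slope, pKa as the pH at semi-equivalence.
- **HSAB descriptors.** `η = (E_LUMO − E_HOMO)/2`,
  `χ = |E_LUMO + E_HOMO|/2`, interaction energy
  `E_int = E_complex − (E_partner + E_ligand)`.
- **Bioactivity.** Censoring-aware MBC/MIC and HC₅₀/MIC ratios over
  two-fold dilution grids.

Fitting is weighted Levenberg–Marquardt with log/logit parameter
transforms, a seeded multistart against local minima, and linearized 95%
confidence intervals.

## Worked example

```r
library(ampchem)

# CMC from a synthetic conductivity scan (breakpoint 1.72 mM, 0.5% noise)
ser <- gen_conductivity(cmc_mM = 1.72, slope_below = 80,
                        slope_ratio = 0.74, seed = 1)
cmc_from_conductivity(ser, seed = 1)
#> <cmc_result [conductivity]: CMC = 1.702 mM (ci 0.068), alpha = 0.742, beta = 0.258>

# HSAB descriptors of DPPC from its frontier orbitals
d <- compute_descriptors(orbital_energies(-7.4133, -0.6579, "DPPC"))
sprintf("gap %.4f eV, hardness %.4f eV, chi %.4f eV",
        d$gap, d$hardness, d$electronegativity)
#> "gap 6.7554 eV, hardness 3.3777 eV, chi 4.0356 eV"

# Apparent pKa of a 2 mM weak acid titrated with 20 mM NaOH
tc <- simulate_titration(acid_umol = 30, V0_mL = 15, pKa = 6.55,
                         titrant_mM = 20, volumes = seq(0, 3, length.out = 200))
pk <- estimate_pka(tc)
sprintf("equivalence at %.3f mL, apparent pKa %.2f", pk$v_equiv, pk$pka_apparent)
#> "equivalence at 1.500 mL, apparent pKa 6.55"

# Derived micelle structure from a fitted core-shell cylinder
m <- ref_micelle_truth("C12TC3NH3Cl")$model
der <- derive_micelle_params(m, surfactant_spec(12, concentration = 10))
sprintf("N_agg %.0f, A_m %.2f nm^2", der$N_agg, der$A_m)
#> "N_agg 62, A_m 0.62 nm^2"
```

The recovered CMC (1.702 mM) sits within 1% of the generating breakpoint,
with `beta = 1 - alpha` exact by construction; the titration recovers both
the stoichiometric equivalence volume (30 µmol / 20 mM = 1.5 mL) and the
generating pKa at the semi-equivalence pH; the cylinder geometry implies
about 62 molecules per micelle at 0.62 nm² each at the core-shell
interface.

## Package layout

- `R/` — curve containers and I/O, forward models, fitting engine, CMC /
  pKa / descriptor / bioactivity estimators, synthetic generators, replay
  batteries, pipeline orchestrator (`run_pipeline()`).
- `inst/extdata/` — transcribed MIC/MBC tables (CSV, with censored and
  missing cells).
- `vignettes/ampchem-methods.Rmd` — the models, assumptions, numerical
  choices and limitations in detail.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles for both form factors.
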