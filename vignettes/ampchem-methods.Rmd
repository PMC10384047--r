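---
title: "Models and methods behind ampchem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampchem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampchem)
```

ampchem implements the physicochemical analysis chain used to characterize
cationic amino-acid surfactants (N-acyl tryptophan and N-acyl phenylalanine
propylamine salts, CnTC3NH3Cl / CnPC3NH3Cl) and their mixed vesicles with
the phospholipid DPPC. This vignette describes the models, their
assumptions, the numerical choices, and what the synthetic-data validation
does and does not demonstrate.

## SAXS data model and reduction

Scattering curves are triples (q, I, sigma) with q in nm^-1 and intensities
in cm^-1 after absolute scaling. The momentum transfer follows
q = (4 pi / lambda) sin(theta / 2); the default wavelength is the Cu
K-alpha line (0.1542 nm). Reduction is deliberately minimal: pointwise
background subtraction (no transmission correction is modeled) and
absolute-intensity calibration against the flat scattering of water. The
water cross section is not a measured input but a literature constant,
0.01632 cm^-1 at 25 degC; it is configurable, and its use is flagged in the
output metadata. Curves on mismatched q grids are an error, never silently
resampled — calibration correctness is preferred over convenience.
A reader option accepts A^-1 files (q multiplied by 10 on input), since
both unit conventions are common in practice.

## Micelle form factor: core-shell cylinder

Micelles of single-chain surfactants with 12-14 carbon acyl tails are
modeled as core-shell cylinders: a hydrocarbon core (radius `Rc`, length
`Lc`, electron density `rho_c`) wrapped in a hydrated headgroup shell of
uniform thickness `Rh` (density `rho_h`) covering the lateral surface and
both end caps, in water (`rho_solv` = 334 e/nm^3). The single-orientation
amplitude is the classical product of a longitudinal sinc factor and a
radial Bessel factor; the intensity is the orientation average

I(q) = (phi / V_total) * P(q) + bkg,

with P(q) the average of the squared amplitude over the angle between the
cylinder axis and q. Conversion from electron units to cm^-1 uses the
Thomson radius squared. No structure factor is applied: at the 10 mM study
concentration no interference effect is observable, so S(q) = 1.

Numerics: the orientation average uses fixed-order Gauss-Legendre
quadrature on (0, pi/2). The order is at least 128 and grows with
`q_max * (Lc + 2 Rh)` so that the oscillating sinc factor of long cylinders
(up to the ~64 nm length seen for the C14 phenylalanine homolog) stays
resolved; the removable singularities of sinc and 2 J1(x)/x are handled by
series below |x| = 1e-5. Nodes are cached per order, and during fitting the
order is frozen from the start geometry so a wandering optimizer cannot
inflate the evaluation cost. Against brute-force trapezoid oracles with
1e5 nodes, the evaluator agrees to better than 1e-6 relative over
q in [0.2, 6] nm^-1 for all published parameter sets (the test suite
asserts 1e-4).

Tanford geometry closes the model: chain volume
v = 0.0274 + 0.0269 n nm^3 and maximum extended length
l_max = 0.154 + 0.1265 n nm. The carbon count convention matters: for an
acyl (amide-linked) tail the carbonyl carbon is counted with the headgroup,
so a C12 acyl tail contributes n = 11 methylene+methyl carbons to the
volume formula while the extended-length convention uses the methylene
count n = 10, which reproduces the conventional 1.4 / 1.7 nm maxima for
C12 / C14 tails. The core density is fixed from these volumes rather than
fitted, removing one strongly correlated parameter.

Derived quantities use the lateral-surface convention: the aggregation
number is the core volume over one chain volume; the area per molecule is
the lateral core area over the aggregation number; shell hydration
allocates the lateral shell volume only. This is the only convention that
reproduces the published area-per-molecule row (0.63, 0.68, 0.65,
0.67 nm^2) exactly after rounding, which is why it was adopted. Water is
taken as 0.0299 nm^3 and 10 electrons per molecule for the volumetric
headgroup-density check.

The hydrocarbon volume fraction is phi = c N_A v_chain. At 10 mM for a C12
homolog this gives 0.00195, about 4% above the published 0.00187; the
volume convention behind the published number is not recoverable, so the
replay fixtures carry the published phi verbatim and `volume_fraction()`
documents the Tanford-based definition.

## Bilayer form factor: three-Gaussian profile

DPPC and DPPC/surfactant vesicles scatter like randomly oriented flat
unilamellar sheets. The bilayer contrast profile is two positive headgroup
Gaussians at +/- `Zh` (width `sigma_h`, amplitude `drho_h`) plus a negative
central Gaussian (width `sigma_c`, amplitude `drho_c`) for the terminal
methyl trough. The amplitude is the analytic cosine transform of this
profile and the intensity carries the 1/q^2 Lorentz factor:
I(q) = scale * F(q)^2 / q^2 + bkg.

The published parameter sets report `sigma_h`, `drho_h`, `Zh`, `sigma_c`
but no trough amplitude; scattering data constrain it only weakly. The
package therefore couples `drho_c = -drho_h` by default (the ratio is
configurable) and records the coupling in fit metadata. `scale` and `bkg`
for replay fixtures are package choices (1e-4 each) — with multiplicative
noise they only set the overall magnitude, not the recovery problem.

## Fitting engine

Weighted least squares with Levenberg-Marquardt (minpack.lm) behind a
parameter transformation layer: positive-only parameters are fitted on the
log scale, box-bounded parameters through a scaled logit, so the LM core is
unconstrained and widths cannot stick at zero. Weights are 1/sigma^2 when
uncertainties are present; otherwise unit weights with a warning and an
"unscaled" chi-squared. Confidence half-widths are 1.96 times the
linearized standard errors (covariance from the Gauss-Newton Hessian,
scaled by the reduced chi-squared, delta-method mapped back from the
transformed scale). No bootstrap is attempted by default.

The bilayer model's cos(q Zh) factor creates genuine local minima, and
cylinder fits started with the shell density below the solvent density
(contrast sign flip) can stall in a long-cylinder minimum. Both are
handled by a seeded random multistart (default 8 starts; the first is the
user's, later ones perturb the free parameters with a magnitude that ramps
up to ~1.5x the nominal +/-20%). An optional early stop
(`stop_at_chi2`) skips remaining starts once a converged start reaches a
stated reduced chi-squared; the recovery batteries use 2, since with
correctly specified uncertainties any fit at chi2_red <= 2 is already of
global-minimum quality. The micelle battery additionally bounds the
cylinder length to [1, 60] nm — lengths beyond what q >= 0.2 nm^-1
resolves are unidentifiable — and the headgroup density to
[340, 500] e/nm^3, below which the shell contrast changes sign and above
which no hydrated headgroup is physical.

Geometry selection refits the same data with a core-shell sphere and
rejects families whose implied headgroup region is implausible (more than
100 waters per headgroup, or a volumetric headgroup density more than
50 e/nm^3 from the fitted one); ties fall back to the lower reduced
chi-squared with a warning when neither family is plausible.

## CMC estimation

Conductivity: below the CMC each added molecule contributes free ions;
above it, micelles with condensed counterions conduct less per monomer.
The estimator fits two independent lines over every admissible split (at
least 4 points per side), takes the split with minimal total SSE, and
reports the intersection abscissa — the geometric construction, not the
split knot. The degree of ionization alpha is the slope ratio
above/below; beta = 1 - alpha holds exactly by construction. Slopes closer
than twice their combined standard error raise a no-breakpoint error
rather than returning an arbitrary intersection. Confidence half-widths
come from a seeded residual bootstrap (default 500 resamples). No
pre-smoothing is applied; an option excludes points around the candidate
break if instrument rounding is suspected. Water conductivity is assumed
already subtracted.

Fluorescence: the pyrene I1/I3 ratio sits near 1.6 in water and drops into
micelle cores. A Boltzmann sigmoid is fitted on log10(concentration) — the
transition develops over orders of magnitude, so the midpoint is defined
on the log axis (a linear-axis option exists and the choice is recorded).
The CMC is the back-transformed midpoint. A transition smaller than 0.1 in
the ratio is rejected as no transition; a width consistent with zero warns
of a step-like change.

## Titration and apparent pKa

The forward model treats the protonated ammonium as a monoprotic weak acid
and solves the exact charge balance (water autoprotolysis Kw = 1e-14,
dilution by the titrant, unit activity coefficients) by bracketed
root-finding with a Newton polish to a residual below 1e-13 mol/L. The
default conditions mirror the study protocol: 30 umol analyte in 15 mL
(about 2 mM) titrated with 20 mM NaOH; back-titration of the free amine
with HCl uses the same balance.

The estimator finds the equivalence volume as the maximum of |dpH/dV|
(centred differences on a window-3 moving average, parabolic refinement of
the discrete maximum) and reports the pH at half that volume. Two
safeguards matter in practice. First, the steep initial rise out of the
unbuffered start can exceed the equivalence jump for weakly acidic species
(pKa above ~8 at 2 mM), so candidate maxima are restricted to the high-pH
side of the mid-pH (low-pH side for back-titrations). Second, a candidate
whose pH does not clear the semi-equivalence plateau by at least one unit
is the buffer's own mid-crossing in a truncated curve, and raises an
incomplete-titration error. A quarter-point Henderson span far from
2 log10(3) (deviation above 0.3 pH) warns that the semi-equivalence
plateau is undefined — the strong-acid regime. Round-trip validation:
simulated curves with pKa 5-9 under study conditions are recovered within
0.05 pH units; the residual bias (~0.03 at pKa 9) comes from partial
dissociation, which the semi-equivalence construction ignores by design.
Micellization-induced pKa shifts are deliberately not modeled: the
estimator returns the apparent pKa of the supplied curve. Ionic-strength
corrections are omitted (< 0.05 pH below 0.01 M). Forward and
back-titration estimates are reconciled by their mean, flagging
discrepancies beyond 0.3 pH units.

## HSAB descriptors

Pure data algebra on user-supplied energies — no electronic-structure
computation is ever performed. The gap is E_LUMO - E_HOMO in the positive
convention (the source material states both sign conventions in different
places; the positive one is adopted and the raw signed half-sum retained).
Electronegativity is reported as |E_LUMO + E_HOMO| / 2 because the
published tables print positive values while the defining half-sum is
negative for bound orbitals; the signed value stays available as
`chi_signed`. The identity gap = 2 * hardness is exact in every output.
Interaction energies are the bare total-energy difference
E_complex - (E_partner + E_ligand); ranking is by ascending interaction
energy with stable ties. A Hartree-to-eV converter (27.211386) is provided.

## Bioactivity summaries

MIC/MBC endpoints are interval data from two-fold serial dilution, so
censoring is a first-class state (exact, greater-than, less-than,
missing) and is never silently dropped: a censored MBC propagates to a
lower-bound ratio, a censored MIC makes the ratio undefined, and "-" table
cells parse as missing, distinct from censored. HC50 is the first upward
piecewise-linear crossing of 50% hemolysis (a logistic fit was considered
and interpolation chosen as the default because the published analysis is
not further specified); curves topping out below 50% return a
greater-than bound at the highest tested concentration. The dilution grid
uses the conventional rounding of the 500...2 uM series (31, 62, 125). The
bactericidal rule of thumb (MBC/MIC between 1 and 2) is reported, not
enforced: the transcribed tables contain ratios up to 4, and the summary
flags that rather than hiding it.

## Synthetic data and what the validation shows

Every generator is deterministic given a seed (drawn in an isolated RNG
stream) and persists its generating truth with the output; recovery
scoring is always against that truth. Noise models and defaults mirror the
published uncertainty magnitudes: 2% multiplicative noise on SAXS curves
(with the stored sigma equal to the noise level, so correctly specified
refits have reduced chi-squared near 1), 0.5% on conductivity, 0.01
additive on the fluorescence ratio, 0.02 pH on titrations. The replay
fixtures regenerate every published parameter column as generator truth.

Problem sizes used in validation: SAXS curves of 200 points over
q in [0.2, 6] nm^-1, 10-seed fit batteries; conductivity series of 25
points spanning 0.2-2x the breakpoint, 20 seeds; fluorescence series of 30
log-spaced points, 20 seeds; titrations of 200 points to twice the
equivalence volume. These sizes reproduce the published values well within
their printed uncertainties.

What passing does not show: the generators draw from the same model
families the estimators fit, so recovery demonstrates correctness and
calibration of the estimators, not robustness to real-data pathologies —
smearing and multilamellar contamination in SAXS, electrode drift and CO2
ingress in titrations, polydispersity, or micelle-coupled proton release.
Those effects are documented limitations, not simulated ones.

## Known limitations

- No smearing/desmearing, polydispersity, or multilamellarity in the
  scattering models; the sphere model exists only for geometry selection.
- Linearized confidence intervals; the bilayer amplitude-scale coupling
  means absolute amplitudes are only as good as the fixed trough coupling.
- The titration model is strictly monoprotic with unit activities.
- Bioactivity summaries are table-level; no growth-curve or dose-response
  modeling beyond interpolation.
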