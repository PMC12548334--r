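---
title: "Methods: anomalous SAXS analysis of lanthanide-peptide aggregates"
author: "asaxsfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anomalous SAXS analysis of lanthanide-peptide aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asaxsfit)
```

## The problem

Lanthanide-binding-tag (LBT) peptides chelate trivalent rare-earth
cations (Ln3+) in a selective loop. In concentrated solutions with excess
Ln3+, LBT:Ln3+ complexes self-assemble into micron-scale aggregates that
can be separated by sedimentation — an all-aqueous route to rare-earth
separation. The quantity that decides whether this works is the
*composition* of the aggregates: how many lanthanide ions ride along per
peptide, and how selective the aggregate is between two lanthanides
(e.g. Tb3+ vs Lu3+).

Anomalous small-angle X-ray scattering (ASAXS) answers this in situ.
SAXS profiles are collected at a set of photon energies just below the
resonant element's L3 absorption edge (Tb: 7.514 keV, Lu: 9.244 keV),
where the element's atomic scattering factor acquires energy-dependent
corrections f'(E) and f''(E). The energy dependence of the measured
intensity then isolates the spatial distribution of that one element.

`asaxsfit` implements the full analysis chain on reduced 1-D profiles:

1. **Stuhrmann decomposition** of `I(Q, E)` into three terms,
2. a **biphasic uniform-sphere model** that forward-computes those terms,
3. a **simultaneous weighted fit** with chi-squared-profile uncertainties
   and derived quantities (ions per peptide, separation factors),
4. **binding speciation** (single and competitive 1:1 equilibria) and
   small solution-observable conversions,
5. a **seeded synthetic-data generator**, so that every stage is testable
   against known ground truth without any deposited beamline data.

## Stuhrmann decomposition

At each Q the intensity across energies follows

$$I(Q, E) = S(Q) + 2 f'(E)\, C(Q) + \left(f'(E)^2 + f''(E)^2\right) R(Q),$$

where S is the ordinary (non-resonant) SAXS term, C the cross term and R
the resonant term. With `Ne >= 3` energies this is an overdetermined
linear system per Q; `decompose()` solves it by weighted least squares
(weights `1/sigma^2`) independently at every Q, and propagates the
weighted least-squares covariance into per-term uncertainties, which the
fit stage uses as weights. Design choices:

* No smoothness coupling across Q — each Q is an independent solve.
* The design matrix `[1, 2 f'(E), f'(E)^2 + f''(E)^2]` is checked for
  conditioning; a condition number above 1e8 (e.g. all energies sharing
  one f') raises a degeneracy error rather than returning garbage.
* Negative resonant-term estimates caused by noise are *kept* by default;
  clipping would bias the downstream fit. A `nonnegative = TRUE` mode
  exists for display purposes.

Any physical density pair must satisfy the Cauchy–Schwarz bound
`C(Q)^2 <= S(Q) R(Q)`. For the biphasic sphere both contrasts share one
spatial profile, so the bound holds with *equality* — a strong internal
consistency check that `validate_cauchy_schwarz()` applies. For exact
terms the check is deterministic; for noisy decompositions a point is
flagged only when the excess is both beyond the stated tolerance and
statistically significant (default 2 propagated standard errors),
because at high Q the estimated terms are noise-dominated and the raw
ratio `C^2/(S R)` is uninformative.

`linearity_diagnostic()` regresses `I(Q_fixed, E)` on f' and f'^2: over
a narrow below-edge window the intensity is nearly linear in f' (slope
`2C`), and the quadratic share quantifies the size of the resonant term.

## The biphasic uniform-sphere model

TEM of the condensed phase shows granular, roughly isotropic aggregates,
motivating a spherical model. A homogeneous sphere, however, over-counts
the lanthanide content (it forces all contrast to carry the resonant
label); the biphasic model instead mixes, within one sphere,

* **phase 1** — the peptide–cation network: peptide formula
  C103H149N23O36 plus `phase1_rmoles` lanthanide ions per peptide, at
  mass density `phase1_density` and volume fraction `phase1_volfrac`;
* **phase 2** — a LnCl3-rich aqueous phase (LnCl3·nH2O, default n = 6,
  configurable) at `phase2_density`, `phase2_volfrac`;
* **solvent** — water filling the remaining volume fraction and the
  exterior.

The two phases are treated as homogeneously interleaved (a single
effective interior density), matching the interpenetrating-network
picture; a core–shell variant is out of scope. Contrasts are computed in
electrons/Å³ from the chemical formulas and mass densities; the resonant
atom contributes its full Z to the non-resonant part and its (f', f'')
only at intensity assembly, which keeps S, C, R energy-independent:

$$S \propto (\Delta\rho_0)^2 \langle V^2\Phi^2\rangle,\quad
  C \propto \Delta\rho_0\,\rho_{res} \langle V^2\Phi^2\rangle,\quad
  R \propto \rho_{res}^2 \langle V^2\Phi^2\rangle,$$

with `Phi(x) = 3(sin x - x cos x)/x^3` the uniform-sphere shape factor.
Because all three terms share `<V^2 Phi^2>`, `C^2 = S R` exactly — the
property the decomposition validity check exploits.

**Polydispersity.** Radii follow a log-normal distribution:
`mean_radius` is the *median* and `rsig` the standard deviation of ln R
(the common small-angle-fitting convention; both conventions in the
literature are handled by treating the pair as a parameterisation, and
the monodisperse limit `rsig -> 0` is exact). Averaging uses
Gauss–Legendre quadrature on ±5 rsig in log space. The node count
defaults to 401: at the default Q maximum (0.3 1/Å) and radii of
hundreds of Å the form-factor fringes oscillate with a period of about
0.026 in ln R, and a coarser rule (e.g. ~100 nodes) under-resolves them,
which leaves artificial ripples in the chi-squared surface that trap the
optimiser; 401 nodes is converged (doubling it changes chi-squared by
< 1e-6 relative) while keeping a model evaluation under 10 ms.

**Units.** Q in 1/Å, energies in keV, intensities in 1/cm. The `norm`
parameter is the aggregate number density in units of 1e12 cm⁻³, so the
values encountered here are O(10); with the classical electron radius
applied at assembly the absolute scale comes out in 1/cm. The default
ground truth (`default_truth()`: norm 23 ≙ 2.3e13 aggregates/cm³) is
chosen so that the aggregate inventory is consistent with an 800 µM
peptide solution — the concentrated regime in which ASAXS has enough
signal-to-noise — and gives forward intensities of tens of 1/cm at low
Q, a realistic absolute scale.

**Structure factor.** S(Q) ≡ 1: the aggregates are dilute
(volume fraction < 1%), and only form-factor terms are modelled.

## Fitting and uncertainties

`fit_biphasic()` minimises the stacked weighted residuals of all three
decomposed terms simultaneously with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`). Identifiability drives the default free set:
since `C^2 = S R`, the three amplitudes carry only two independent
numbers (`norm * delta_rho0^2` and `rho_res / delta_rho0`), plus the two
shape parameters from the Q dependence. The default therefore frees
`norm`, `phase1_rmoles`, `mean_radius`, `rsig` and fixes densities and
volume fractions at their configured values; freeing more reintroduces
the norm/volume-fraction degeneracy, which is detected and reported via
the Hessian condition number.

**Staged start.** Even with a converged quadrature, the joint surface
has shallow secondary minima: an inflated `rsig` can mimic a wrong
radius by smearing the fringes into a power law. The fitter therefore
scans a log grid of radii (and of rsig values) around the initial point,
re-optimising the amplitude-like parameters in each cell with warm
starts, and launches the full fit from the best cell. The procedure is
fully deterministic; `n_starts = 1` disables it.

**Chi-squared mapping.** `chi2_map()` profiles one parameter: at each of
41 grid points spanning ±4 approximate standard errors the parameter is
fixed and the remaining free parameters re-optimised; the Δχ² = 1
crossings, interpolated linearly, give the 1-sigma confidence interval.
On an exactly quadratic surface this reproduces the analytic ±1 SE
interval; a grid that fails to bracket a crossing yields a one-sided
interval with a warning.

**Derived quantities.** `ions_per_peptide()` adds to `phase1_rmoles` the
phase-2 resonant ions expressed per phase-1 peptide (from the fitted
densities, formulas and volume fractions); `element_ratio()` divides the
totals of two single-edge fits of the same two-element sample (the
separation factor, e.g. Tb3+/Lu3+); the ratio's uncertainty, when
propagated from the two profiles, assumes the two fits are independent —
they come from disjoint energy scans. `phase_metal_concentrations()`
converts each phase's composition to mol/L.

## Speciation and solution observables

The titration behaviour of the free peptide and free metal behind the
aggregation-regime picture is a 1:1 equilibrium: `solve_binding_1to1()`
uses the numerically stable closed-form quadratic;
`titration_curve()` labels each added-metal/peptide ratio as
undersaturated (< 1) or oversaturated (> 1), the threshold above which
excess free cations neutralise and bridge the complexes. Aggregation
itself is *not* modelled thermodynamically — the regime label is a
classification, not a phase boundary.

`solve_competitive()` handles several metals competing for one peptide
by monotone root bracketing on the free-peptide concentration plus
Newton polishing; mass balances close to 1e-12 relative. In the
weak-binding dilute regime (complexation depleting neither metal), the
bound ratio of two competing metals tends to their association-constant
ratio — the basis for expecting a Tb/Lu selectivity near 1.6 and a
Tb/La selectivity near 35 from dilute-limit constants. That limit fails
once a noticeable fraction of either metal is bound (the bound ratio
then bends toward 1), which is why the package's checks of this property
use small `K × total` products; association constants are user inputs
throughout (the shipped examples are illustrative, not authoritative).
Concentrations are unit-agnostic: any unit consistent with 1/K works,
and mass-balance guarantees are relative, not absolute.

Three small conversions used around the measurements are included:
Stokes–Einstein diameter `d = k_B T/(3 pi eta D)`; the Henry equation
`zeta = 3 mu eta / (2 eps F(ka))` with the Smoluchowski thin-double-layer
value F(ka) = 1.5 as default; and Beer–Lambert `c = A/(eps l)` with the
peptide's 280 nm extinction coefficient 8250 1/(M cm) as default.

## The synthetic-data generator

No raw beamline data are deposited for this system, so the generator
*is* the study design, not a convenience:

* **Energies:** 20 points spanning the ~100 eV window below the edge
  (stopping 5 eV short of it), placed uniformly in f' — denser near the
  edge where f' moves fastest — by inverting the dispersion table;
  a uniform-in-energy mode exists.
* **Q grid:** logarithmic, 0.003–0.3 1/Å, 200 points, typical of a
  3.6 m sample–detector geometry at these energies.
* **Noise:** independent Gaussian with `sigma = rel * I + floor`,
  default 1% relative — the character of reduced, absolute-scaled
  profiles (counting statistics plus scale calibration), not raw Poisson
  counts. The sigma matrix is reported truthfully. If both noise terms
  are zero the data are exact and unit sigmas are reported (equal
  weights). All randomness flows through the single mandatory seed.
* **Dispersion tables:** the shipped Tb/Lu L3 tables are *synthetic*
  (Cromer–Liberman-style logarithmic approach of f' to the edge,
  f' ≈ −10 → −22 e over the last 100 eV, f'' ≈ 3.1–3.6 e); they have
  realistic magnitudes but are not beamline calibrations, and real
  analyses must supply measured or tabulated values.

Defaults of `default_truth()` emulate the concentrated aggregation
regime: 2.25 ions per peptide in the binding phase (inside the 2–2.5
band characteristic of these aggregates), a 25%-volume peptide phase at
1.35 g/cm³, a thin (1%) LnCl3-rich phase at 1.10 g/cm³, median radius
400 Å with rsig 0.25, which together give ≈ 2.48 total ions per peptide.

What the generator deliberately does **not** emulate: instrument
resolution smearing, detector artefacts, background-subtraction
residuals, inter-aggregate structure factor, and any non-spherical
(fibrillar) morphology. Passing the recovery studies therefore shows the
estimator chain is correct and well-calibrated under its own model
assumptions; it does not certify those assumptions for real beamline
data.

## Study sizes and numerical choices

The parameter-recovery study (`recovery_study()`) uses 50 replicates of
a 20-energy × 200-Q scan at 1% noise, with the fit started from a fixed
multiplicative perturbation of the truth (norm ×1.5, ions per peptide
×1.3, radius ×1.2, rsig ×1.2) so the optimiser never starts at the
answer; replicate r uses seed `base_seed + r`. These sizes resolve the
median errors and interval coverage while keeping a full study in a few
minutes on one core. Tie-breaks and degenerate inputs: zero-noise
configurations produce exact data with unit weights; `rsig = 0`
bypasses the quadrature exactly; a regime label at exactly ratio 1 is
"undersaturated" (the oversaturated regime is defined by ratio > 1).

## Known limitations

* The two phase densities and volume fractions are not identifiable
  from a single-edge scan alongside `norm`; they are inputs (or must be
  constrained externally) rather than free parameters by default.
* The Δχ² = 1 intervals are frequentist profile intervals; with 50
  replicates their empirical coverage has a binomial standard error of
  about 7 percentage points, so individual studies can land a few points
  away from the nominal 68%.
* The spherical form factor is an approximation to granular aggregates;
  fibrillar species seen at lower concentrations are outside the model.
* Linear interpolation of dispersion tables is only as good as the
  table's energy spacing; no extrapolation is permitted, and
  Kramers–Kronig reconstruction of f' is out of scope.
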