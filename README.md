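# asaxsfit

Quantitative analysis of anomalous small-angle X-ray scattering (ASAXS)
from self-assembling lanthanide-binding-tag (LBT) peptide aggregates.

LBT peptides chelate trivalent rare-earth cations (Ln³⁺) in a selective
binding loop; in concentrated solutions with excess Ln³⁺ the complexes
condense into separable, lanthanide-rich aggregates — a candidate
all-aqueous rare-earth separation process. ASAXS, measured at ~20 photon
energies just below the resonant element's L3 edge (Tb: 7.514 keV,
Lu: 9.244 keV), resolves *where the lanthanide sits*: how many ions per
peptide the aggregates carry and how selective they are between two
elements. This package is for scattering/structural-biophysics users who
have reduced 1-D profiles (or want fully synthetic studies) and need the
analysis chain behind those numbers.

## What it computes

Writing f′(E), f″(E) for the anomalous dispersion corrections of the
resonant element, the measured intensity decomposes per Q as

    I(Q,E) = S(Q) + 2 f′(E) C(Q) + (f′(E)² + f″(E)²) R(Q)

— the Stuhrmann decomposition into SAXS term S, cross term C and
resonant term R, solved by per-Q weighted least squares (`decompose()`).
A biphasic uniform-sphere model (`model_terms()`) forward-computes the
three terms for polydisperse spherical aggregates whose interior mixes a
peptide–cation phase (peptide C₁₀₃H₁₄₉N₂₃O₃₆ carrying `phase1_rmoles`
ions per peptide) and a LnCl₃-rich aqueous phase in solvent, with radii
log-normally distributed (median `mean_radius`, log-width `rsig`);
because both contrasts share one spatial profile, C² = S·R exactly, a
built-in consistency check (`validate_cauchy_schwarz()`).
`fit_biphasic()` fits all three terms simultaneously by bounded
Levenberg–Marquardt, `chi2_map()` profiles the chi-squared space for
Δχ² = 1 confidence intervals, and `ions_per_peptide()` /
`element_ratio()` turn fits into stoichiometry and separation factors.
A speciation module covers the 1:1 and competitive metal–peptide
equilibria plus Stokes–Einstein, Henry/Smoluchowski and Beer–Lambert
conversions, and `synthetic_config()` / `generate_asaxs()` produce fully
seeded synthetic scans with known ground truth.

## Worked example

Simulate a 20-energy Tb-edge scan of the concentrated aggregation
regime, decompose it, fit it and read off the stoichiometry:

```r
library(asaxsfit)

cfg   <- synthetic_config(noise_rel = 0.01, seed = 42)  # truth: default_truth()
ds    <- generate_asaxs(cfg)
terms <- decompose(ds)
validate_cauchy_schwarz(terms, tolerance = 0.1)$n_violations
#> [1] 0

init <- cfg$truth
init$phase1_rmoles <- 3; init$mean_radius <- 500
init$norm <- 35; init$rsig <- 0.3
class(init) <- "biphasic_params"

fit <- fit_biphasic(terms, phase_compositions("Tb"), init)
fit
#> <biphasic_fit> chi2 = 696.883 on 596 dof (chi2/dof = 1.169)
#>   status: Relative error in the sum of squares is at most `ftol'.
#>   norm            23.0172 +/- 0.2
#>   phase1_rmoles   2.28513 +/- 0.0418
#>   mean_radius     402.608 +/- 1.68
#>   rsig            0.242123 +/- 0.00318
#>   fixed: phase1_density, phase1_volfrac, phase2_density, phase2_volfrac

ions_per_peptide(fit)
#> [1] 2.516
chi2_map(fit, terms, "phase1_rmoles")$interval
#>    lower    upper
#> 2.243     2.327
```

The generating truth was 2.25 ions per peptide in the binding phase
(2.48 in total, inside the 2–2.5 band characteristic of these
aggregates), median radius 400 Å, rsig 0.25 and norm 23
(2.3 × 10¹³ aggregates/cm³): the fit recovers the stoichiometry within
its Δχ² = 1 interval and the geometry to better than 1%, with
χ²/dof ≈ 1 confirming the noise model. `run_pipeline()` wraps the same
chain (simulate-or-load → decompose → fit → profile → report) with
file outputs and a provenance log.

Speciation, e.g. the competitive bound ratio of two metals in the
dilute weak-binding regime:

```r
sys <- binding_system(1, data.frame(label = c("Tb", "Lu"),
                                    total = c(10, 10),
                                    K_assoc = c(1.6e-4, 1e-4)))
st <- solve_competitive(sys)
st$metals$complexed[1] / st$metals$complexed[2]
#> [1] 1.599957   # -> the association-constant ratio 1.6
```

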