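# Shared builders for test fixtures (all generated in code).

# Small hand-made dispersion table with simple round values.
toy_table <- function() {
  dispersion_table("Tb", edge_energy = 7.514,
                   energy = c(7.0, 7.1, 7.2, 7.3, 7.4),
                   f_prime = c(-10, -12, -14, -17, -20),
                   f_doubleprime = c(2, 2, 2, 2.5, 3))
}

# Dataset built directly from known terms via the Stuhrmann design,
# exact (no noise), unit sigmas.
dataset_from_terms <- function(s, c_, r, energies, table,
                               q = seq_along(s) / 100) {
  f <- dispersion_at(table, energies)
  design <- cbind(1, 2 * f$f_prime, f$f_prime^2 + f$f_doubleprime^2)
  intensity <- design %*% rbind(s, c_, r)
  energy_scan(q, energies, intensity,
              matrix(1, length(energies), length(q)), table$element, table)
}

# Exact model terms decorated with small proportional uncertainties so
# they can be fed to the fitter.
terms_with_sigma <- function(terms, rel = 0.01) {
  scattering_terms(terms$q_grid, terms$saxs_term, terms$cross_term,
                   terms$resonant_term,
                   sigma_saxs = rel * abs(terms$saxs_term),
                   sigma_cross = rel * abs(terms$cross_term),
                   sigma_resonant = rel * abs(terms$resonant_term))
}

small_truth <- function() default_truth()

.param_names_for_test <- function() {
  c("norm", "phase1_density", "phase1_volfrac", "phase1_rmoles",
    "phase2_density", "phase2_volfrac", "mean_radius", "rsig")
}
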