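# Biphasic uniform-sphere forward model: polydisperse spherical aggregates
# whose interior is a volume-fraction mixture of a peptide-cation phase and
# a cation-rich aqueous phase in solvent, with one resonant element.

.param_names <- c("norm", "phase1_density", "phase1_volfrac",
                  "phase1_rmoles", "phase2_density", "phase2_volfrac",
                  "mean_radius", "rsig")

#' Biphasic sphere model parameters
#'
#' The eight parameters of the biphasic uniform-sphere ASAXS model. Names
#' follow the conventional XModFit-style parameter set
#' (norm, Phase1_Density, Phase1_volFrac, Phase1_rmoles, Phase2_Density,
#' Phase2_volFrac, Phase1_R, Rsig) in snake_case.
#'
#' @param norm Aggregate number-density scale; one unit corresponds to
#'   1e12 aggregates/cm^3.
#' @param phase1_density Mass density of the peptide-cation phase, g/cm^3.
#' @param phase1_volfrac Volume fraction of phase 1 inside the sphere.
#' @param phase1_rmoles Lanthanide ions per peptide in phase 1 (>= 0,
#'   may be fractional).
#' @param phase2_density Mass density of the LnCl3-rich aqueous phase,
#'   g/cm^3.
#' @param phase2_volfrac Volume fraction of phase 2 inside the sphere.
#' @param mean_radius Median of the log-normal radius distribution, A.
#' @param rsig Standard deviation of ln(R) (log-normal width, >= 0).
#' @return Object of class `biphasic_params` (a validated named list).
#' @export
biphasic_params <- function(norm, phase1_density, phase1_volfrac,
                            phase1_rmoles, phase2_density, phase2_volfrac,
                            mean_radius, rsig) {
  p <- list(norm = norm, phase1_density = phase1_density,
            phase1_volfrac = phase1_volfrac, phase1_rmoles = phase1_rmoles,
            phase2_density = phase2_density, phase2_volfrac = phase2_volfrac,
            mean_radius = mean_radius, rsig = rsig)
  stopifnot(all(vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))))
  if (p$phase1_density <= 0 || p$phase2_density <= 0) {
    stop("phase densities must be > 0", call. = FALSE)
  }
  if (p$phase1_volfrac < 0 || p$phase2_volfrac < 0 ||
      p$phase1_volfrac + p$phase2_volfrac > 1 + 1e-12) {
    stop("phase volume fractions must be >= 0 and sum to <= 1",
         call. = FALSE)
  }
  if (p$phase1_rmoles < 0) stop("phase1_rmoles must be >= 0", call. = FALSE)
  if (p$mean_radius <= 0) stop("mean_radius must be > 0", call. = FALSE)
  if (p$rsig < 0) stop("rsig must be >= 0", call. = FALSE)
  structure(p, class = "biphasic_params")
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("<biphasic_params>\n")
  for (nm in .param_names) cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Phase compositions of the biphasic sphere
#'
#' Chemical context for the model: the peptide base formula (default the
#' 20-residue lanthanide-binding-tag peptide, C103H149N23O36), the
#' composition of the lanthanide-chloride-rich aqueous phase
#' (LnCl3 hydrated with `phase2_waters` waters), and the solvent. The
#' resonant-element count of phase 1 is not stored here: it is the fit
#' parameter `phase1_rmoles` and is injected by [effective_contrasts()].
#'
#' @param resonant_element Element symbol of the lanthanide (e.g. `"Tb"`).
#' @param peptide_formula Formula string of the metal-free peptide.
#' @param phase2_waters Hydration number n of the LnCl3.nH2O phase-2
#'   formula.
#' @param solvent_formula,solvent_density Solvent composition (no resonant
#'   element) and its mass density in g/cm^3.
#' @return Object of class `phase_compositions`.
#' @export
phase_compositions <- function(resonant_element,
                               peptide_formula = "C103H149N23O36",
                               phase2_waters = 6,
                               solvent_formula = "H2O",
                               solvent_density = 1.0) {
  .element_row(resonant_element)
  pep <- parse_formula(peptide_formula)
  if (resonant_element %in% names(pep)) {
    stop("peptide base formula must not already contain the resonant element",
         call. = FALSE)
  }
  solv <- parse_formula(solvent_formula)
  if (resonant_element %in% names(solv)) {
    stop("solvent must not contain the resonant element", call. = FALSE)
  }
  structure(
    list(resonant_element = resonant_element,
         peptide_formula = pep,
         phase2_waters = phase2_waters,
         solvent = material_composition(solv, solvent_density)),
    class = "phase_compositions"
  )
}

#' @export
print.phase_compositions <- function(x, ...) {
  cat("<phase_compositions> resonant ", x$resonant_element,
      ", phase2 = ", x$resonant_element, "Cl3.", x$phase2_waters,
      "H2O, solvent ", x$solvent$mass_density, " g/cm^3\n", sep = "")
  invisible(x)
}

## phase-1 material at a given rmoles and density
.phase1_material <- function(comps, rmoles, density) {
  f <- comps$peptide_formula
  f[comps$resonant_element] <- rmoles
  material_composition(f, density, comps$resonant_element)
}

## phase-2 material: LnCl3.nH2O at a given density
.phase2_material <- function(comps, density) {
  f <- parse_formula(paste0(comps$resonant_element, "Cl3(H2O)",
                            comps$phase2_waters))
  material_composition(f, density, comps$resonant_element)
}

#' Uniform-sphere scattering amplitude shape factor
#'
#' `Phi(x) = 3 (sin x - x cos x) / x^3` with `x = q * radius`; `Phi(0) = 1`.
#' A Taylor series is used for small x to avoid cancellation.
#'
#' @param q Scattering vector magnitude(s), 1/A (>= 0).
#' @param radius Sphere radius, A (> 0).
#' @return Dimensionless shape factor, same length as `q`.
#' @export
sphere_amplitude <- function(q, radius) {
  stopifnot(all(q >= 0), radius > 0)
  x <- q * radius
  out <- numeric(length(x))
  small <- x < 1e-3
  out[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

## cache of Gauss-Legendre rules on [-1, 1], keyed by node count
.gl_rules <- new.env(parent = emptyenv())

.gl_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  rule <- .gl_rules[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n_nodes, -1, 1)
    .gl_rules[[key]] <- rule
  }
  rule
}

## Log-normal quadrature over radii: Gauss-Legendre on ln R in
## [ln R_m - 5 rsig, ln R_m + 5 rsig], weights renormalised over the
## truncated support. Returns nodes (radii) and normalised weights.
.lognormal_nodes <- function(mean_radius, rsig, n_nodes = 401L) {
  if (rsig == 0) {
    return(list(radius = mean_radius, weight = 1))
  }
  rule <- .gl_rule(n_nodes)
  t <- log(mean_radius) + 5 * rsig * rule$x
  w <- rule$w * stats::dnorm(rule$x, sd = 1 / 5)  # ln R pdf up to scale
  list(radius = exp(t), weight = w / sum(w))
}

## <V^2 Phi(qR)^2> over the radius distribution, in A^6.
.mean_v2phi2 <- function(q, mean_radius, rsig, n_nodes = 401L) {
  nd <- .lognormal_nodes(mean_radius, rsig, n_nodes)
  if (length(nd$radius) == 1L) {
    v <- 4 / 3 * pi * nd$radius^3
    return((v * sphere_amplitude(q, nd$radius))^2)
  }
  x <- outer(nd$radius, q)          # nodes x q
  phi <- 3 * (sin(x) - x * cos(x)) / x^3
  small <- x < 1e-3
  if (any(small)) {
    phi[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  }
  v <- 4 / 3 * pi * nd$radius^3
  drop((nd$weight * v^2) %*% phi^2)
}

#' Effective interior contrasts of the biphasic sphere
#'
#' Volume-fraction-weighted non-resonant electron-density contrast of the
#' sphere interior against the solvent, and volume-fraction-weighted number
#' density of the resonant element. Both are energy independent: the
#' resonant atom contributes its full Z to the non-resonant part, while its
#' (f', f'') enter only at intensity assembly.
#'
#' @param params A [biphasic_params()].
#' @param comps A [phase_compositions()].
#' @return List with `delta_rho0` (electrons/A^3) and `rho_res` (atoms/A^3).
#' @export
effective_contrasts <- function(params, comps) {
  stopifnot(inherits(params, "biphasic_params"),
            inherits(comps, "phase_compositions"))
  rho_s <- electron_density(comps$solvent)
  vf1 <- params$phase1_volfrac
  vf2 <- params$phase2_volfrac
  delta <- 0
  nres <- 0
  if (vf1 > 0) {
    m1 <- .phase1_material(comps, params$phase1_rmoles,
                           params$phase1_density)
    delta <- delta + vf1 * (electron_density(m1) - rho_s)
    nres <- nres + vf1 * params$phase1_rmoles * formula_unit_density(m1)
  }
  if (vf2 > 0) {
    m2 <- .phase2_material(comps, params$phase2_density)
    delta <- delta + vf2 * (electron_density(m2) - rho_s)
    nres <- nres + vf2 * formula_unit_density(m2)
  }
  list(delta_rho0 = delta, rho_res = nres)
}

#' Forward-model the three Stuhrmann scattering terms
#'
#' Computes the SAXS term `S(Q)`, cross term `C(Q)` and resonant term
#' `R(Q)` of the biphasic sphere on a Q grid, each averaged over the
#' log-normal radius distribution with fixed Gauss-Legendre
#' quadrature. Because the non-resonant contrast and the resonant atoms
#' share the same spherical profile, `C^2 = S * R` holds exactly at every Q.
#'
#' @param params A [biphasic_params()].
#' @param comps A [phase_compositions()].
#' @param q_grid Ascending Q grid, 1/A.
#' @param table Optional [dispersion_table()]; if supplied, its element is
#'   checked against `comps` (the terms themselves are energy independent).
#' @param n_nodes Number of quadrature nodes for the radius average.
#' @return A [scattering_terms()] object, intensities in 1/cm.
#' @export
model_terms <- function(params, comps, q_grid, table = NULL,
                        n_nodes = 401L) {
  stopifnot(is.numeric(q_grid), all(diff(q_grid) > 0), all(q_grid > 0))
  if (!is.null(table) && table$element != comps$resonant_element) {
    stop("dispersion table element does not match compositions",
         call. = FALSE)
  }
  con <- effective_contrasts(params, comps)
  avg <- .mean_v2phi2(q_grid, params$mean_radius, params$rsig, n_nodes)
  ## [cm^-1] = norm * 1e12 cm^-3 * re[cm]^2 * (density[A^-3] * V[A^3])^2
  scale <- params$norm * .norm_unit * .re_cm^2
  scattering_terms(
    q_grid,
    saxs_term = scale * con$delta_rho0^2 * avg,
    cross_term = scale * con$delta_rho0 * con$rho_res * avg,
    resonant_term = scale * con$rho_res^2 * avg
  )
}

#' Forward-model the total ASAXS intensity at one energy
#'
#' Assembles `I(Q,E) = S + 2 f'(E) C + (f'(E)^2 + f''(E)^2) R` from
#' [model_terms()] and [dispersion_at()].
#'
#' @inheritParams model_terms
#' @param table A [dispersion_table()] covering `energy`.
#' @param energy Photon energy in keV.
#' @return Intensity vector in 1/cm over `q_grid`.
#' @export
model_intensity <- function(params, comps, q_grid, table, energy,
                            n_nodes = 401L) {
  terms <- model_terms(params, comps, q_grid, table, n_nodes)
  f <- dispersion_at(table, energy)
  assemble_intensity(terms, f$f_prime, f$f_doubleprime)
}

#' Assemble intensity from scattering terms and dispersion corrections
#'
#' @param terms A [scattering_terms()].
#' @param f_prime,f_doubleprime Dispersion corrections in electrons.
#' @return Intensity vector, 1/cm.
#' @export
assemble_intensity <- function(terms, f_prime, f_doubleprime) {
  terms$saxs_term + 2 * f_prime * terms$cross_term +
    (f_prime^2 + f_doubleprime^2) * terms$resonant_term
}

#' Radius of gyration of the model spheres
#'
#' Monodisperse limit `Rg = sqrt(3/5) R`; for `rsig > 0` the
#' intensity-weighted (Guinier-apparent) value
#' `Rg = sqrt(3/5 <R^8>/<R^6>)` over the log-normal distribution, since
#' forward scattering weights each radius by V^2 ~ R^6.
#'
#' @param params A [biphasic_params()].
#' @return Rg in A.
#' @export
guinier_radius <- function(params) {
  stopifnot(inherits(params, "biphasic_params"))
  if (params$rsig == 0) {
    return(sqrt(3 / 5) * params$mean_radius)
  }
  nd <- .lognormal_nodes(params$mean_radius, params$rsig)
  m8 <- sum(nd$weight * nd$radius^8)
  m6 <- sum(nd$weight * nd$radius^6)
  sqrt(3 / 5 * m8 / m6)
}
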