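# Equilibrium metal-peptide binding: single 1:1 association (closed form),
# titration curves with regime labels, competitive multi-metal speciation,
# and small solution-observable conversions (Stokes-Einstein, Henry /
# Smoluchowski, Beer-Lambert).

#' Binding system for competitive speciation
#'
#' Total concentrations and 1:1 association constants for one peptide and
#' one or more metals. Concentrations may be in any unit as long as the
#' association constants are in its reciprocal (e.g. mol/L and L/mol).
#'
#' @param peptide_total Total peptide concentration (>= 0).
#' @param metals `data.frame` with columns `label`, `total` (>= 0) and
#'   `K_assoc` (> 0).
#' @param temperature Temperature in K (metadata; the constants are taken
#'   as given at this temperature).
#' @return Object of class `binding_system`.
#' @export
binding_system <- function(peptide_total, metals, temperature = 298.15) {
  stopifnot(is.numeric(peptide_total), peptide_total >= 0,
            is.data.frame(metals),
            all(c("label", "total", "K_assoc") %in% names(metals)),
            nrow(metals) >= 1L)
  if (any(metals$total < 0)) stop("metal totals must be >= 0", call. = FALSE)
  if (any(metals$K_assoc <= 0)) {
    stop("association constants must be > 0", call. = FALSE)
  }
  structure(list(peptide_total = peptide_total, metals = metals,
                 temperature = temperature),
            class = "binding_system")
}

.speciation_state <- function(free_peptide, labels, free_metal, complexed) {
  structure(
    list(free_peptide = free_peptide,
         metals = data.frame(label = labels, free = free_metal,
                             complexed = complexed)),
    class = "speciation_state"
  )
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("<speciation_state> free peptide = ", format(x$free_peptide), "\n",
      sep = "")
  print(x$metals, row.names = FALSE)
  invisible(x)
}

#' Closed-form 1:1 binding equilibrium
#'
#' Solves `P + M <-> PM` with association constant K. The complex
#' concentration is the numerically stable root of
#' `x^2 - (P0 + M0 + 1/K) x + P0 M0 = 0`.
#'
#' @param peptide_total,metal_total Total concentrations (>= 0).
#' @param K_assoc Association constant (> 0, reciprocal concentration
#'   unit).
#' @return A `speciation_state` with free and complexed species.
#' @export
#' @examples
#' # 100 uM peptide + 100 uM metal at Kd = 1 uM
#' solve_binding_1to1(100, 100, 1)
solve_binding_1to1 <- function(peptide_total, metal_total, K_assoc) {
  if (peptide_total < 0 || metal_total < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (K_assoc <= 0) stop("K_assoc must be > 0", call. = FALSE)
  b <- peptide_total + metal_total + 1 / K_assoc
  x <- 2 * peptide_total * metal_total /
    (b + sqrt(b^2 - 4 * peptide_total * metal_total))
  .speciation_state(peptide_total - x, label = "M",
                    free_metal = metal_total - x, complexed = x)
}

#' Titration curve of a 1:1 binding equilibrium
#'
#' Speciation as metal is titrated into a fixed peptide concentration,
#' with each point labelled undersaturated (added-metal/peptide ratio
#' below 1) or oversaturated (ratio above 1) -- the regime classification
#' that separates monomeric complexes from the aggregation-prone excess-ion
#' regime.
#'
#' @param peptide_total Fixed total peptide concentration.
#' @param K_assoc Association constant.
#' @param ratios Vector of added metal / peptide molar ratios (>= 0).
#' @return `data.frame` with columns `ratio`, `metal_total`,
#'   `free_peptide`, `free_metal`, `complexed`, `regime`.
#' @export
titration_curve <- function(peptide_total, K_assoc, ratios) {
  stopifnot(all(ratios >= 0))
  rows <- lapply(ratios, function(r) {
    st <- solve_binding_1to1(peptide_total, r * peptide_total, K_assoc)
    data.frame(ratio = r, metal_total = r * peptide_total,
               free_peptide = st$free_peptide,
               free_metal = st$metals$free,
               complexed = st$metals$complexed,
               regime = if (r > 1) "oversaturated" else "undersaturated",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Competitive 1:1 speciation for several metals
#'
#' Solves the coupled equilibria `P + M_i <-> PM_i` by safeguarded root
#' bracketing on the free-peptide concentration (the mass-balance residual
#' is monotone in it), followed by Newton polishing. Mass balances hold to
#' 1e-12 relative.
#'
#' @param system A [binding_system()].
#' @param max_iter Maximum bracketing/Newton iterations.
#' @return A `speciation_state` with one metals row per metal.
#' @export
solve_competitive <- function(system, max_iter = 200L) {
  stopifnot(inherits(system, "binding_system"))
  p0 <- system$peptide_total
  m0 <- system$metals$total
  k <- system$metals$K_assoc
  if (p0 == 0) {
    return(.speciation_state(0, system$metals$label, m0, 0 * m0))
  }
  ## residual g(P) = P + sum_i K_i M0_i P / (1 + K_i P) - P0, increasing
  g <- function(p) p + sum(k * m0 * p / (1 + k * p)) - p0
  lo <- 0; hi <- p0
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= .Machine$double.eps * p0) break
  }
  p <- (lo + hi) / 2
  ## Newton polish
  for (it in 1:3) {
    gp <- 1 + sum(k * m0 / (1 + k * p)^2)
    p <- p - g(p) / gp
    if (p < 0) p <- 0
  }
  complexed <- k * m0 * p / (1 + k * p)
  res <- abs(p + sum(complexed) - p0)
  if (res > 1e-10 * max(p0, 1)) {
    stop(sprintf("competitive solver did not converge (residual %.3g)",
                 res), call. = FALSE)
  }
  .speciation_state(p, system$metals$label, m0 - complexed, complexed)
}

#' Hydrodynamic diameter from a diffusion coefficient
#'
#' Stokes-Einstein relation `d = k_B T / (3 pi eta D)`.
#'
#' @param diffusion_coeff Translational diffusion coefficient, m^2/s (> 0).
#' @param temperature Temperature, K (> 0).
#' @param viscosity Dynamic viscosity, Pa s (> 0).
#' @return Hydrodynamic diameter in nm.
#' @export
#' @examples
#' hydrodynamic_diameter(5.34e-10, 298.15, 8.9e-4)  # ~0.92 nm (monomer)
hydrodynamic_diameter <- function(diffusion_coeff, temperature = 298.15,
                                  viscosity = 8.9e-4) {
  if (any(c(diffusion_coeff, temperature, viscosity) <= 0)) {
    stop("all inputs must be > 0", call. = FALSE)
  }
  d_m <- .k_B * temperature / (3 * pi * viscosity * diffusion_coeff)
  d_m * 1e9
}

#' Zeta potential from electrophoretic mobility (Henry's equation)
#'
#' `zeta = 3 mu eta / (2 eps F(ka))`; with the Smoluchowski limit
#' `F(ka) = 1.5` (thin double layer) this reduces to
#' `zeta = mu eta / eps`.
#'
#' @param mobility Electrophoretic mobility, m^2/(V s) (any sign).
#' @param viscosity Dynamic viscosity, Pa s (> 0).
#' @param permittivity Absolute permittivity of the medium, F/m (> 0);
#'   default water at 25 C.
#' @param henry_factor Henry function value F(ka); default 1.5.
#' @return Zeta potential in mV, same sign as the mobility.
#' @export
zeta_from_mobility <- function(mobility, viscosity = 8.9e-4,
                               permittivity = 6.95e-10,
                               henry_factor = 1.5) {
  if (viscosity <= 0 || permittivity <= 0 || henry_factor <= 0) {
    stop("viscosity, permittivity and Henry factor must be > 0",
         call. = FALSE)
  }
  zeta_v <- 3 * mobility * viscosity / (2 * permittivity * henry_factor)
  zeta_v * 1e3
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon l)`. The default extinction coefficient is the
#' 280 nm value used for the tryptophan/tyrosine-bearing LBT peptide,
#' 8250 1/(M cm).
#'
#' @param absorbance Absorbance (>= 0).
#' @param path Path length in cm (> 0).
#' @param epsilon Molar extinction coefficient, 1/(M cm) (> 0).
#' @return Concentration in mol/L.
#' @export
#' @examples
#' concentration_from_absorbance(0.065) * 1e6  # ~7.9 uM
concentration_from_absorbance <- function(absorbance, path = 1,
                                          epsilon = 8250) {
  if (path <= 0 || epsilon <= 0) {
    stop("path and epsilon must be > 0", call. = FALSE)
  }
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  absorbance / (epsilon * path)
}

#' Illustrative default association constants
#'
#' A default K set for synthetic speciation work, shaped so that the
#' Tb/Lu constant ratio is 1.6 and the Tb/La ratio 35 — the selectivity
#' ordering of the LBT peptide across these lanthanides. The absolute
#' values are representative of a high-affinity LBT (Kd tens of nM) but
#' are NOT authoritative measurements; supply your own constants for any
#' quantitative use.
#'
#' @return `data.frame` with columns `label` and `K_assoc` (L/mol).
#' @export
default_association_constants <- function() {
  k_tb <- 1.75e7
  data.frame(label = c("Tb", "Lu", "La"),
             K_assoc = c(k_tb, k_tb / 1.6, k_tb / 35))
}

#' Write a titration table as delimited text
#'
#' @param path Output path.
#' @param curve A `data.frame` from [titration_curve()] (or the
#'   competitive analogue with one free/complexed column pair per metal).
#' @export
write_titration <- function(path, curve) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# titration table (concentration units as supplied)", con)
  utils::write.table(curve, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
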