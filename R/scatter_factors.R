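# Anomalous dispersion tables and composition -> scattering-density
# computations for chemical formulas with at most one resonant element.

#' Parse a chemical formula string
#'
#' Parses formulas such as `"C103H149N23O36"`, `"TbCl3(H2O)6"` or
#' `"Tb2.25"` into a named vector of stoichiometric counts. Counts may be
#' non-integer, which is how fitted fractional lanthanide stoichiometries
#' (ions per peptide) are expressed.
#'
#' @param formula Formula string. Parenthesised groups with a trailing
#'   multiplier are supported; nesting is not.
#' @return Named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("TbCl3(H2O)6")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) stop("empty formula", call. = FALSE)
  counts <- c()
  add <- function(sym, n) {
    counts[sym] <<- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  num_re <- "([0-9]*\\.?[0-9]*)"
  ## expand parenthesised groups first
  grp_re <- paste0("\\(([^()]*)\\)", num_re)
  rest <- formula
  while (grepl(grp_re, rest)) {
    m <- regmatches(rest, regexpr(grp_re, rest))[[1]]
    inner <- sub(grp_re, "\\1", m)
    mult <- sub(grp_re, "\\2", m)
    mult <- if (nzchar(mult)) as.numeric(mult) else 1
    sub_counts <- parse_formula(inner) * mult
    for (s in names(sub_counts)) add(s, sub_counts[[s]])
    rest <- sub(grp_re, "", rest, fixed = FALSE)
  }
  tok_re <- paste0("([A-Z][a-z]?)", num_re)
  consumed <- 0L
  for (m in regmatches(rest, gregexpr(tok_re, rest))[[1]]) {
    sym <- sub(tok_re, "\\1", m)
    n <- sub(tok_re, "\\2", m)
    n <- if (nzchar(n)) as.numeric(n) else 1
    .element_row(sym)  # validates the symbol
    add(sym, n)
    consumed <- consumed + nchar(m)
  }
  if (consumed != nchar(rest)) {
    stop("could not parse formula: '", formula, "'", call. = FALSE)
  }
  counts
}

#' Molar mass of a formula
#'
#' @param formula Formula string or named count vector from
#'   [parse_formula()].
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(vapply(names(counts), atomic_mass, numeric(1)) * counts)
}

#' Electrons per formula unit
#'
#' @inheritParams molar_mass
#' @return Total electron count (sum of atomic numbers times counts).
#' @export
formula_electrons <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(vapply(names(counts), atomic_number, numeric(1)) * counts)
}

#' Material composition
#'
#' Bundles a chemical formula, a mass density and (optionally) the resonant
#' element whose anomalous scattering near an absorption edge is exploited
#' by ASAXS.
#'
#' @param formula Formula string or named count vector.
#' @param mass_density Mass density in g/cm^3 (> 0).
#' @param resonant_element Element symbol of the resonant species, or `NULL`.
#' @return Object of class `material_composition`.
#' @export
#' @examples
#' material_composition("H2O", 1.0)
material_composition <- function(formula, mass_density,
                                 resonant_element = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  if (any(counts < 0)) stop("negative stoichiometric count", call. = FALSE)
  stopifnot(is.numeric(mass_density), length(mass_density) == 1L)
  if (!is.finite(mass_density) || mass_density <= 0) {
    stop("mass_density must be > 0", call. = FALSE)
  }
  if (!is.null(resonant_element)) {
    .element_row(resonant_element)
    if (!resonant_element %in% names(counts)) {
      counts[resonant_element] <- 0
    }
  }
  structure(
    list(formula = counts, mass_density = mass_density,
         resonant_element = resonant_element),
    class = "material_composition"
  )
}

#' @export
print.material_composition <- function(x, ...) {
  f <- paste0(names(x$formula),
              ifelse(x$formula == 1, "", format(x$formula, trim = TRUE)),
              collapse = "")
  cat("<material_composition> ", f, " @ ", x$mass_density, " g/cm^3",
      if (!is.null(x$resonant_element))
        paste0("  [resonant: ", x$resonant_element, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Anomalous dispersion table
#'
#' Tabulated real (f') and imaginary (f'') anomalous dispersion corrections
#' for one element near one absorption edge. Lookups interpolate linearly;
#' no extrapolation outside the tabulated range is allowed because the
#' corrections vary steeply near an edge.
#'
#' @param element Element symbol.
#' @param edge_energy Absorption edge energy in keV.
#' @param energy Vector of tabulated energies in keV, strictly increasing.
#' @param f_prime f'(E) in electrons.
#' @param f_doubleprime f''(E) in electrons, all >= 0.
#' @return Object of class `dispersion_table`.
#' @export
dispersion_table <- function(element, edge_energy, energy, f_prime,
                             f_doubleprime) {
  .element_row(element)
  stopifnot(length(energy) == length(f_prime),
            length(energy) == length(f_doubleprime))
  if (length(energy) < 2L) {
    stop("dispersion table needs at least 2 rows", call. = FALSE)
  }
  if (any(diff(energy) <= 0)) {
    stop("table energies must be strictly increasing", call. = FALSE)
  }
  if (any(f_doubleprime < 0)) {
    stop("f'' must be non-negative", call. = FALSE)
  }
  structure(
    list(element = element, edge_energy = edge_energy,
         energy = as.numeric(energy), f_prime = as.numeric(f_prime),
         f_doubleprime = as.numeric(f_doubleprime)),
    class = "dispersion_table"
  )
}

#' @export
print.dispersion_table <- function(x, ...) {
  cat("<dispersion_table> ", x$element, " edge ", x$edge_energy, " keV, ",
      length(x$energy), " rows over [", min(x$energy), ", ", max(x$energy),
      "] keV\n", sep = "")
  invisible(x)
}

#' Read a dispersion table from a text file
#'
#' Whitespace-delimited 3-column format (energy_keV, f_prime,
#' f_doubleprime); `#` starts a comment.
#'
#' @param path File path.
#' @param element Element symbol the table belongs to.
#' @param edge_energy Edge energy in keV.
#' @return A [dispersion_table()].
#' @export
read_dispersion_table <- function(path, element, edge_energy) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy", "f_prime", "f_doubleprime"))
  dispersion_table(element, edge_energy, tab$energy, tab$f_prime,
                   tab$f_doubleprime)
}

#' Built-in dispersion tables (synthetic)
#'
#' Representative f'/f'' tables for the Tb and Lu L3 edge regions
#' (7.514 and 9.244 keV) spanning roughly 100 eV below each edge. The values
#' follow the Cromer-Liberman-type logarithmic approach of f' to the edge
#' with magnitudes typical of lanthanide L3 edges; they are synthetic
#' stand-ins, not beamline calibrations, and real analyses should supply
#' their own table via [read_dispersion_table()].
#'
#' @param element `"Tb"` or `"Lu"`.
#' @return A [dispersion_table()].
#' @export
builtin_dispersion_table <- function(element = c("Tb", "Lu")) {
  element <- match.arg(element)
  edge <- c(Tb = 7.514, Lu = 9.244)[[element]]
  path <- system.file("extdata",
                      paste0("dispersion_", tolower(element),
                             "_l3_synthetic.txt"),
                      package = "asaxsfit", mustWork = TRUE)
  read_dispersion_table(path, element, edge)
}

#' Interpolate anomalous dispersion corrections at an energy
#'
#' Linear interpolation between tabulated rows; exact at tabulated points;
#' energies outside the table range raise an error (no extrapolation).
#'
#' @param table A [dispersion_table()].
#' @param energy Photon energy in keV (vectorised).
#' @return List with numeric `f_prime` and `f_doubleprime` (electrons).
#' @export
dispersion_at <- function(table, energy) {
  stopifnot(inherits(table, "dispersion_table"), is.numeric(energy))
  lo <- min(table$energy); hi <- max(table$energy)
  if (any(energy < lo | energy > hi)) {
    stop(sprintf("energy outside table range [%g, %g] keV", lo, hi),
         call. = FALSE)
  }
  list(
    f_prime = stats::approx(table$energy, table$f_prime, xout = energy)$y,
    f_doubleprime = stats::approx(table$energy, table$f_doubleprime,
                                  xout = energy)$y
  )
}

#' Electron density of a material
#'
#' Energy-independent electron number density from the formula and the mass
#' density: sum(count * Z) * rho * N_A / M, expressed in electrons/A^3.
#'
#' @param comp A [material_composition()].
#' @return Electron density in electrons/A^3.
#' @export
#' @examples
#' electron_density(material_composition("H2O", 1.0))  # ~0.334 e/A^3
electron_density <- function(comp) {
  stopifnot(inherits(comp, "material_composition"))
  ne <- formula_electrons(comp$formula)
  m <- molar_mass(comp$formula)
  ## e/cm^3 -> e/A^3 (1 cm^3 = 1e24 A^3)
  ne * comp$mass_density * .N_A / m / 1e24
}

#' Formula-unit number density
#'
#' @param comp A [material_composition()].
#' @return Formula units per A^3.
#' @export
formula_unit_density <- function(comp) {
  stopifnot(inherits(comp, "material_composition"))
  comp$mass_density * .N_A / molar_mass(comp$formula) / 1e24
}

#' Split a material's scattering density into non-resonant and resonant parts
#'
#' The non-resonant part uses the full atomic number Z of every atom
#' (including the resonant one); the resonant part carries the number
#' density of the resonant element together with its (f', f'') at the given
#' energy, so that the total effective density is
#' `nonresonant + resonant_number_density * (f' + i f'')`.
#'
#' @param comp A [material_composition()] with a resonant element matching
#'   `table$element` (or resonant count 0).
#' @param table A [dispersion_table()].
#' @param energy Photon energy in keV.
#' @return List with `nonresonant_density` (electrons/A^3),
#'   `resonant_number_density` (atoms/A^3), `f_prime`, `f_doubleprime`.
#' @export
resonant_split_density <- function(comp, table, energy) {
  stopifnot(inherits(comp, "material_composition"),
            inherits(table, "dispersion_table"))
  res <- comp$resonant_element
  n_res <- 0
  if (!is.null(res) && res %in% names(comp$formula) &&
      comp$formula[[res]] > 0) {
    if (res != table$element) {
      stop("resonant element '", res, "' does not match table element '",
           table$element, "'", call. = FALSE)
    }
    n_res <- comp$formula[[res]] * formula_unit_density(comp)
  }
  f <- dispersion_at(table, energy)
  list(nonresonant_density = electron_density(comp),
       resonant_number_density = n_res,
       f_prime = f$f_prime, f_doubleprime = f$f_doubleprime)
}
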