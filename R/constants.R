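# Physical constants (SI / CODATA 2018) and a small element table.

## classical electron radius [cm]
.re_cm <- 2.8179403262e-13
## Avogadro constant [1/mol]
.N_A <- 6.02214076e23
## Boltzmann constant [J/K]
.k_B <- 1.380649e-23
## `norm` unit: aggregate number density carried by one unit of the
## dimensionless `norm` parameter [1/cm^3]
.norm_unit <- 1e12

## Atomic number and standard atomic weight [g/mol] for the elements that
## occur in peptide/buffer/lanthanide-salt compositions.
.element_data <- data.frame(
  symbol = c("H", "He", "Li", "B", "C", "N", "O", "F", "Na", "Mg", "Al",
             "Si", "P", "S", "Cl", "K", "Ca", "Sc", "Mn", "Fe", "Cu", "Zn",
             "Br", "Y", "I", "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb",
             "Dy", "Ho", "Er", "Tm", "Yb", "Lu"),
  z = c(1, 2, 3, 5, 6, 7, 8, 9, 11, 12, 13,
        14, 15, 16, 17, 19, 20, 21, 25, 26, 29, 30,
        35, 39, 53, 57, 58, 59, 60, 62, 63, 64, 65,
        66, 67, 68, 69, 70, 71),
  mass = c(1.008, 4.0026, 6.94, 10.81, 12.011, 14.007, 15.999, 18.998,
           22.9898, 24.305, 26.9815, 28.085, 30.9738, 32.06, 35.45,
           39.0983, 40.078, 44.956, 54.938, 55.845, 63.546, 65.38,
           79.904, 88.906, 126.904, 138.9055, 140.116, 140.908, 144.242,
           150.36, 151.964, 157.25, 158.9254, 162.5, 164.930, 167.259,
           168.934, 173.045, 174.9668),
  stringsAsFactors = FALSE
)

.element_row <- function(symbol) {
  i <- match(symbol, .element_data$symbol)
  if (is.na(i)) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  .element_data[i, ]
}

#' Atomic number of an element
#'
#' @param symbol Element symbol (e.g. `"Tb"`).
#' @return Integer atomic number.
#' @export
atomic_number <- function(symbol) .element_row(symbol)$z

#' Standard atomic weight of an element
#'
#' @param symbol Element symbol.
#' @return Atomic weight in g/mol.
#' @export
atomic_mass <- function(symbol) .element_row(symbol)$mass
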