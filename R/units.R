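#' Physical constants and unit conversions
#'
#' All internal computation is done in Hartree atomic units (hartree, bohr,
#' electron mass, atomic time unit).  Files on disk use Angstrom for lengths
#' and electron-charge-based multipole units; femtoseconds and Kelvin appear
#' only at the user interface.  These constants are defined once, here.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{1.8897259886 bohr / Angstrom (CODATA)}
#'   \item{fs_per_atu}{femtoseconds per atomic time unit (0.02418884254)}
#'   \item{atu_per_fs}{atomic time units per femtosecond}
#'   \item{kboltz_hartree}{Boltzmann constant, hartree / K}
#'   \item{me_per_amu}{electron masses per unified atomic mass unit}
#' }
#' @export
units_au <- list(
  bohr_per_angstrom = 1.8897259886,
  fs_per_atu        = 2.418884254e-2,
  atu_per_fs        = 1 / 2.418884254e-2,
  kboltz_hartree    = 3.166811563e-6,
  me_per_amu        = 1822.888486209
)

#' Convert Angstrom to bohr
#' @param x numeric, lengths in Angstrom
#' @return lengths in bohr
#' @export
ang2bohr <- function(x) x * units_au$bohr_per_angstrom

#' Convert bohr to Angstrom
#' @param x numeric, lengths in bohr
#' @return lengths in Angstrom
#' @export
bohr2ang <- function(x) x / units_au$bohr_per_angstrom

# element data for the species the s-type Gaussian backend and the fixture
# systems use; masses in amu
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "C", "N", "O", "X"),
  z      = c(1, 2, 3, 6, 7, 8, 0),
  mass   = c(1.00782503, 4.002602, 7.016003, 12.0, 14.003074, 15.994915, 12.0),
  stringsAsFactors = FALSE
)

element_charge <- function(symbols) {
  i <- match(symbols, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(unique(symbols[is.na(i)]), collapse = ", "))
  }
  .element_table$z[i]
}

element_mass <- function(symbols) {
  i <- match(symbols, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(unique(symbols[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}
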