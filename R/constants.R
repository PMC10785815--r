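#' Physical constants used throughout the package
#'
#' All energies in the package are expressed in units of the thermal energy
#' k_BT; all lengths in nanometres.  These helpers expose the conversion
#' constants at the reference temperature of 298 K.
#'
#' @name constants
NULL

#' Thermal energy in kcal/mol
#'
#' @param temperature_K temperature in Kelvin (default 298).
#' @return k_B*T expressed in kcal/mol (0.592 at 298 K).
#' @examples
#' kBT_kcal_mol()  # ~0.59
#' @export
kBT_kcal_mol <- function(temperature_K = 298) {
  kB <- 1.380649e-23                      # J/K
  NA_avogadro <- 6.02214076e23
  kB * temperature_K * NA_avogadro / 4184 # J -> kcal/mol
}

#' Bjerrum length in water
#'
#' Distance at which two unit charges interact with exactly one k_BT.
#' The default is the standard value for water at 298 K.
#'
#' @param temperature_K temperature in Kelvin.
#' @return Bjerrum length in nm (0.71 at 298 K).
#' @export
bjerrum_length <- function(temperature_K = 298) {
  # eps_r(T) for water by the empirical Malmberg-Maryott form
  eps_r <- 87.740 - 0.40008 * (temperature_K - 273.15) +
    9.398e-4 * (temperature_K - 273.15)^2 -
    1.410e-6 * (temperature_K - 273.15)^3
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23
  1e9 * e^2 / (4 * pi * eps0 * eps_r * kB * temperature_K)
}

# Species codes shared between R and the compiled core.
SPECIES_LEVELS <- c("CORE", "SS_BEAD", "DS_BEAD", "PRECURSOR", "ION_MONO", "ION_DI")

species_code <- function(species) {
  i <- match(species, SPECIES_LEVELS)
  if (anyNA(i)) stop("unknown species: ", paste(species[is.na(i)], collapse = ", "))
  i
}
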