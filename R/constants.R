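#' Physical constants used throughout the package
#'
#' All energies in the package are in kcal/mol and all temperatures in kelvin.
#' `R_KCAL` is the molar gas constant in kcal/(mol K); `KB_J` and `H_J` are
#' the CODATA (exact, SI-2019) Boltzmann and Planck constants used for the
#' Eyring prefactor kB*T/h.
#'
#' @format Named numeric constants.
#' @name haloselect-constants
#' @keywords internal
NULL

# gas constant, kcal/(mol K)
R_KCAL <- 1.987204e-3
# Boltzmann constant, J/K (exact)
KB_J <- 1.380649e-23
# Planck constant, J s (exact)
H_J <- 6.62607015e-34

#' Default run temperature (kelvin)
#'
#' The reactivity experiments the energetics describe were run at 90 degrees
#' Celsius, so 363.15 K is the default throughout; 298.15 K can be passed
#' anywhere a temperature is accepted.
#' @return A numeric scalar, kelvin.
#' @export
default_temperature <- function() 363.15

#' Default simulation horizon (seconds)
#'
#' 12 h (43200 s), the duration of the rebound experiments.
#' @return A numeric scalar, seconds.
#' @export
default_horizon <- function() 43200

# ligand vocabulary shared by tables, landscapes and generators
LIGANDS <- c("OH", "Cl", "Br", "F", "OTf")
HALIDES <- c("Cl", "Br", "F")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
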