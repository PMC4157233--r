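#' Physical constants used throughout the package
#'
#' Single source of truth for every physical constant the package uses.
#' Energies are kept in kcal/mol and potentials in volts, so the Faraday
#' constant is expressed as 23.0605 kcal mol-1 V-1 (equivalent to
#' 96,485 C mol-1) and the gas constant as 1.9872e-3 kcal mol-1 K-1.
#'
#' Two default temperatures coexist deliberately: titration and
#' protonation-probability work uses 300 K (the temperature of the
#' continuum-electrostatics protocol), while Eyring kinetics and
#' vibrational thermochemistry use 298.15 K. Every function that depends on
#' temperature also accepts it explicitly.
#'
#' @return A named list of constants:
#' \describe{
#'   \item{faraday}{23.0605 kcal mol-1 V-1}
#'   \item{gas_constant}{1.9872e-3 kcal mol-1 K-1}
#'   \item{kb_over_h}{Boltzmann/Planck ratio, s-1 K-1}
#'   \item{hc_ev_nm}{photon energy factor h*c, 1239.84 eV nm}
#'   \item{proton_solvation}{solvation free energy of the proton,
#'     -265.9 kcal mol-1}
#'   \item{she_absolute}{absolute potential of the standard hydrogen
#'     electrode, 4.43 V}
#'   \item{temperature_titration}{300 K}
#'   \item{temperature_kinetics}{298.15 K}
#'   \item{coulomb}{332.0636 kcal A mol-1 e-2, the point-charge Coulomb
#'     prefactor at unit dielectric}
#' }
#' @examples
#' thermo_constants()$faraday
#' @export
thermo_constants <- function() {
  list(
    faraday = 23.0605,
    gas_constant = 1.9872e-3,
    kb_over_h = 1.380649e-23 / 6.62607015e-34,
    hc_ev_nm = 1239.84,
    proton_solvation = -265.9,
    she_absolute = 4.43,
    temperature_titration = 300,
    temperature_kinetics = 298.15,
    coulomb = 332.0636
  )
}

# internal shorthand; kept as functions so the exported list stays the
# single definition site
.FARADAY <- function() 23.0605
.RGAS <- function() 1.9872e-3
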