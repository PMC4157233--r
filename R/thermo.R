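#' Convert a reaction free energy to a reduction potential
#'
#' Applies the thermodynamic relation \eqn{\Delta G = -nF\Delta E}: the
#' potential is \code{-delta_g / (n_electrons * F)} with F = 23.0605
#' kcal mol-1 V-1. Potentials are "absolute" (vacuum-referenced); use
#' [potential_vs_she()] to re-reference to the standard hydrogen electrode.
#'
#' @param delta_g reaction free energy (products minus reactants), kcal/mol
#' @param n_electrons number of electrons transferred (integer >= 1)
#' @return potential in volts
#' @examples
#' potential_from_delta_g(-67.4, 1) # 2.92 V
#' @export
potential_from_delta_g <- function(delta_g, n_electrons) {
  stopifnot(is.numeric(delta_g), is.numeric(n_electrons))
  if (any(n_electrons < 1) || any(n_electrons != round(n_electrons))) {
    stop("n_electrons must be a positive integer")
  }
  -delta_g / (n_electrons * .FARADAY())
}

#' Re-reference an absolute potential to the standard hydrogen electrode
#'
#' Subtracts the absolute SHE potential (4.43 V) from a vacuum-referenced
#' potential.
#'
#' @param e_absolute absolute (vacuum-referenced) potential, volts
#' @return potential vs SHE, volts
#' @export
potential_vs_she <- function(e_absolute) {
  e_absolute - thermo_constants()$she_absolute
}

#' pH-effective free energy of a reaction consuming solvent protons
#'
#' For a reaction that takes up \code{n_protons} protons from solution, the
#' effective free energy at a given pH is
#' \eqn{\Delta G_{eff} = \Delta G - RT \ln [H^+]^n = \Delta G + n RT \ln(10) \cdot pH}.
#'
#' @param delta_g free energy at unit proton activity, kcal/mol
#' @param n_protons number of solvent protons consumed (integer >= 0)
#' @param ph solution pH
#' @param temperature kelvin; defaults to the kinetics temperature 298.15 K
#' @return effective free energy, kcal/mol
#' @examples
#' effective_delta_g(0, 1, ph = 7) # +9.55 kcal/mol at 298.15 K
#' @export
effective_delta_g <- function(delta_g, n_protons, ph,
                              temperature = thermo_constants()$temperature_kinetics) {
  stopifnot(is.finite(ph), n_protons >= 0, n_protons == round(n_protons))
  delta_g + n_protons * .RGAS() * temperature * log(10) * ph
}

#' Barrier increase from the probability of a required protonation state
#'
#' When a reaction step requires the proton donors to be found in a
#' particular protonation state of probability p, the effective barrier
#' rises by \eqn{\Delta\Delta G = -RT \ln p}.
#'
#' @param p probability in (0, 1]
#' @param temperature kelvin; defaults to 300 K (the titration temperature)
#' @return barrier increase, kcal/mol (0 when p = 1)
#' @examples
#' barrier_increase_from_probability(1e-5) # 6.9 kcal/mol at 300 K
#' @export
barrier_increase_from_probability <- function(p,
                                              temperature = thermo_constants()$temperature_titration) {
  stopifnot(is.numeric(p))
  if (any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]: an infinite penalty is out of domain")
  }
  -.RGAS() * temperature * log(p)
}

#' Eyring relation between a rate constant and an activation free energy
#'
#' Transition-state theory: \eqn{k = (k_B T / h) e^{-\Delta G^\ddagger / RT}}.
#' Supply exactly one of \code{rate} or \code{barrier}; the other is
#' returned. The pair is mutually inverse.
#'
#' @param rate first-order rate constant, s-1
#' @param barrier activation free energy, kcal/mol
#' @param temperature kelvin; defaults to 298.15 K
#' @return the missing member of the (rate, barrier) pair
#' @examples
#' eyring(barrier = 19.3)        # ~4.4e-2 s-1
#' eyring(rate = 6.2e12)         # ~0 kcal/mol
#' @export
eyring <- function(rate = NULL, barrier = NULL,
                   temperature = thermo_constants()$temperature_kinetics) {
  prefactor <- thermo_constants()$kb_over_h * temperature
  rt <- .RGAS() * temperature
  if (is.null(rate) == is.null(barrier)) {
    stop("supply exactly one of 'rate' or 'barrier'")
  }
  if (is.null(barrier)) {
    if (any(rate <= 0)) stop("rate must be positive")
    rt * log(prefactor / rate)
  } else {
    stopifnot(is.finite(barrier))
    prefactor * exp(-barrier / rt)
  }
}

#' Rate constant from a specific activity
#'
#' Converts an enzyme specific activity (nmol product min-1 mg-1) to a
#' turnover number k_cat (s-1). The molecular mass of the catalytic unit
#' must be supplied explicitly.
#'
#' @param activity_nmol_min_mg specific activity, nmol min-1 mg-1
#' @param mass_kda molecular mass of the catalytic unit, kDa
#' @return k_cat in s-1
#' @examples
#' # 50 nmol/min/mg for a ~53 kDa catalytic unit gives k_cat ~ 4.4e-2 s-1,
#' # i.e. an Eyring barrier near 19.3 kcal/mol at 298.15 K
#' eyring(rate = kcat_from_specific_activity(50, 53))
#' @export
kcat_from_specific_activity <- function(activity_nmol_min_mg, mass_kda) {
  stopifnot(activity_nmol_min_mg > 0, mass_kda > 0)
  # nmol/min/mg * (1 min / 60 s) * (mass g/mol) -> mol product per mol enzyme per s
  activity_nmol_min_mg * 1e-9 / 60 * (mass_kda * 1e3) * 1e3
}

#' Reduction-potential shift supplied by photon absorption
#'
#' A photon of wavelength lambda carries hc/lambda electron-volts; spread
#' over n transferred electrons this raises the effective reduction
#' potential by (hc/lambda)/n volts.
#'
#' @param wavelength_nm photon wavelength, nm (> 0)
#' @param n_electrons number of electrons the energy is shared over
#' @return potential shift, volts
#' @examples
#' photon_potential_shift(590, 2) # 1.05 V
#' @export
photon_potential_shift <- function(wavelength_nm, n_electrons) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (any(n_electrons < 1) || any(n_electrons != round(n_electrons))) {
    stop("n_electrons must be a positive integer")
  }
  (thermo_constants()$hc_ev_nm / wavelength_nm) / n_electrons
}
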