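# Marcus-theory electron-transfer activation energies from two (possibly
# unequal) reorganization energies and a driving force.
#
# Parametrization: reactant diabat E_R(x) = lambda_R * x^2 with minimum at
# x = 0; product diabat E_P(x) = dG + lambda_P * (1 - x)^2 with minimum at
# x = 1. The activation energy is E_R at the lowest-energy real crossing.
# With equal curvatures this reduces to the textbook
# (lambda + dG)^2 / (4 lambda).

#' Reorganization energy of an electronic state
#'
#' The energy needed to distort a state from its own equilibrium geometry
#' to the other state's geometry: energy of the state at the other
#' geometry minus its energy at its own minimum. A negative difference is
#' rejected (a state cannot be stabler away from its own minimum).
#'
#' @param e_at_other_geometry energy of the state at the partner state's
#'   equilibrium geometry, kcal/mol
#' @param e_at_own_geometry energy of the state at its own equilibrium
#'   geometry, kcal/mol
#' @return reorganization energy, kcal/mol (>= 0)
#' @examples
#' reorganization_energy(-100.0, -112.5) # 12.5
#' @export
reorganization_energy <- function(e_at_other_geometry, e_at_own_geometry) {
  lambda <- e_at_other_geometry - e_at_own_geometry
  if (any(lambda < 0)) {
    stop("negative reorganization energy: state stabler away from its own minimum")
  }
  lambda
}

#' Marcus activation energy from two parabolas
#'
#' Solves for the crossing of the reactant diabat
#' \eqn{E_R(x) = \lambda_R x^2} and the product diabat
#' \eqn{E_P(x) = \Delta G + \lambda_P (1-x)^2}. When two real crossings
#' exist, the one with the lower \eqn{E_R} (the physically traversed
#' barrier) is taken. When the parabolas do not intersect the result is a
#' reportable \code{NO_CROSSING} status, not an error.
#'
#' @param delta_g driving force (product minus reactant at their own
#'   equilibrium geometries), kcal/mol
#' @param lambda_reactant,lambda_product reorganization energies, kcal/mol
#'   (>= 0)
#' @return an object of class \code{marcus_result}: list with
#'   \code{status} ("CROSSING" or "NO_CROSSING"), \code{activation}
#'   (kcal/mol, NA when no crossing) and \code{x_star} (crossing
#'   coordinate, NA when no crossing)
#' @examples
#' marcus_activation(0, 20, 20)$activation    # symmetric case: lambda/4 = 5
#' marcus_activation(-20, 20, 20)$activation  # activationless point: 0
#' @export
marcus_activation <- function(delta_g, lambda_reactant, lambda_product) {
  stopifnot(is.finite(delta_g), lambda_reactant >= 0, lambda_product >= 0)
  lr <- lambda_reactant
  lp <- lambda_product
  # crossing: lr x^2 = dG + lp (1-x)^2
  a <- lr - lp
  b <- 2 * lp
  cc <- -(lp + delta_g)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) {
      # two flat lines: coincide iff dG = 0
      if (abs(delta_g) < 1e-12) 0 else numeric(0)
    } else {
      -cc / b
    }
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  if (length(roots) == 0) {
    return(structure(list(status = "NO_CROSSING", activation = NA_real_,
                          x_star = NA_real_), class = "marcus_result"))
  }
  e_r <- lr * roots^2
  k <- which.min(e_r)
  structure(list(status = "CROSSING", activation = e_r[k], x_star = roots[k]),
            class = "marcus_result")
}

#' @export
print.marcus_result <- function(x, ...) {
  if (x$status == "CROSSING") {
    cat(sprintf("<Marcus crossing: activation %.4f kcal/mol at x* = %.4f>\n",
                x$activation, x$x_star))
  } else {
    cat("<Marcus: parabolas do not intersect (NO_CROSSING)>\n")
  }
  invisible(x)
}
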