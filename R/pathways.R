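# Potential-energy-surface bookkeeping: step and pathway barriers per
# reduction state, redox potentials between surfaces, stereochemistry
# penalties and the two canonical mechanism pathways.

#' Forward barrier of a single proton-transfer step
#'
#' Transition-state energy minus reactant energy on the same reduction
#' surface. A negative value (transition state below its reactant,
#' indicating an inconsistent table) is returned with a warning.
#'
#' @param table an \code{energy_table}
#' @param eps dielectric constant
#' @param reactant,ts \code{mechanism_state}s with equal electron counts;
#'   \code{ts} must be a transition state
#' @return barrier in kcal/mol
#' @examples
#' tab <- read_energy_table(system.file("extdata", "table1.csv",
#'                                      package = "pcetr"))
#' step_barrier(tab, 10, mechanism_state(0, "Asp274", "Propionate"),
#'              mechanism_state(0, "Asp274", "Propionate...C18")) # 24.7
#' @export
step_barrier <- function(table, eps, reactant, ts) {
  stopifnot(inherits(reactant, "mechanism_state"),
            inherits(ts, "mechanism_state"))
  if (!ts$is_ts) stop("'ts' is not a transition state")
  if (ts$electrons != reactant$electrons) {
    stop("reactant and transition state must share the reduction state")
  }
  b <- state_energy(table, ts, eps) - state_energy(table, reactant, eps)
  if (b < 0) {
    warning("transition state below reactant (", format(ts), "): barrier ",
            format(b), " kcal/mol")
  }
  b
}

#' Build a proton-transfer pathway step
#'
#' @param reactant,ts,product \code{mechanism_state}s; the transition state
#'   must connect reactant and product on the same reduction surface
#' @return a pathway step object
#' @export
proton_step <- function(reactant, ts, product) {
  stopifnot(inherits(reactant, "mechanism_state"),
            inherits(ts, "mechanism_state"),
            inherits(product, "mechanism_state"))
  if (!ts$is_ts) stop("'ts' is not a transition state")
  if (length(unique(c(reactant$electrons, ts$electrons,
                      product$electrons))) != 1) {
    stop("a proton step stays on one reduction surface")
  }
  structure(list(kind = "proton", reactant = reactant, ts = ts,
                 product = product), class = "pathway_step")
}

#' Build an electron-uptake pathway step
#'
#' The protonation pattern is held fixed while the substrate gains one
#' electron. The activation energy of the transfer is supplied externally
#' (typically from Marcus theory); the surfaces before and after are not
#' energetically comparable, so pathway bookkeeping restarts its reference
#' minimum at the product.
#'
#' @param from_state \code{mechanism_state} before the transfer (not a TS)
#' @param activation activation energy of the transfer in kcal/mol
#' @return a pathway step object
#' @export
electron_step <- function(from_state, activation = 4) {
  stopifnot(inherits(from_state, "mechanism_state"), activation >= 0)
  if (from_state$is_ts) stop("electron uptake from a transition state")
  product <- mechanism_state(from_state$electrons + 1L, from_state$asp,
                             from_state$prop)
  structure(list(kind = "electron", reactant = from_state, product = product,
                 activation = activation), class = "pathway_step")
}

#' Assemble a pathway from chained steps
#'
#' @param ... pathway steps (from [proton_step()] / [electron_step()]);
#'   consecutive steps must chain (each reactant equals the previous
#'   product)
#' @return an object of class \code{pathway}
#' @export
pathway <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) &&
      !inherits(steps[[1]], "pathway_step")) {
    steps <- steps[[1]]
  }
  stopifnot(length(steps) >= 1,
            all(vapply(steps, inherits, logical(1), "pathway_step")))
  for (i in seq_along(steps)[-1]) {
    prev <- steps[[i - 1]]$product
    cur <- steps[[i]]$reactant
    if (format(prev) != format(cur)) {
      stop("pathway does not chain at step ", i, ": ", format(prev),
           " != ", format(cur))
    }
  }
  structure(list(steps = steps), class = "pathway")
}

#' Overall and per-step barriers of a pathway
#'
#' Each proton step's effective barrier is its transition-state energy
#' minus the lowest minimum visited earlier on the same reduction surface
#' (an energetic-span convention within a reduction state); electron steps
#' contribute their externally supplied activation and reset the reference
#' minimum, since relative enthalpies on different reduction surfaces are
#' not comparable. The overall barrier is the maximum effective barrier;
#' ties resolve to the earliest step.
#'
#' @param table an \code{energy_table}
#' @param eps dielectric constant
#' @param path a \code{pathway}
#' @return an object of class \code{barrier_report}: list with
#'   \code{step_barriers} (forward, vs own reactant),
#'   \code{span_barriers} (vs lowest preceding minimum),
#'   \code{overall}, \code{rate_limiting} (step index) and
#'   \code{reference_state}
#' @examples
#' tab <- read_energy_table(system.file("extdata", "table1.csv",
#'                                      package = "pcetr"))
#' p <- pathway(
#'   proton_step(mechanism_state(1, "Asp274", "Propionate"),
#'               mechanism_state(1, "Asp274...C17", "Propionate"),
#'               mechanism_state(1, "C17", "Propionate")),
#'   proton_step(mechanism_state(1, "C17", "Propionate"),
#'               mechanism_state(1, "C17", "Propionate...C18"),
#'               mechanism_state(1, "C17", "C18")))
#' pathway_overall_barrier(tab, 10, p)$overall # 13.6
#' @export
pathway_overall_barrier <- function(table, eps, path) {
  stopifnot(inherits(path, "pathway"))
  steps <- path$steps
  n <- length(steps)
  fwd <- span <- numeric(n)
  ref_state <- steps[[1]]$reactant
  running_min <- if (steps[[1]]$kind == "proton") {
    state_energy(table, steps[[1]]$reactant, eps)
  } else {
    NA_real_
  }
  for (i in seq_len(n)) {
    st <- steps[[i]]
    if (st$kind == "proton") {
      e_react <- state_energy(table, st$reactant, eps)
      e_ts <- state_energy(table, st$ts, eps)
      e_prod <- state_energy(table, st$product, eps)
      running_min <- min(running_min, e_react, na.rm = TRUE)
      fwd[i] <- e_ts - e_react
      span[i] <- e_ts - running_min
      running_min <- min(running_min, e_prod)
    } else {
      fwd[i] <- span[i] <- st$activation
      # new reduction surface: reference restarts at the electron product
      running_min <- state_energy(table, st$product, eps)
    }
  }
  overall <- max(span)
  structure(
    list(step_barriers = fwd, span_barriers = span, overall = overall,
         rate_limiting = which.max(span), reference_state = ref_state),
    class = "barrier_report"
  )
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf("<barrier report: overall %.1f kcal/mol, rate-limiting step %d>\n",
              x$overall, x$rate_limiting))
  cat("  forward barriers:", paste(sprintf("%.1f", x$step_barriers),
                                   collapse = ", "), "\n")
  cat("  span barriers:   ", paste(sprintf("%.1f", x$span_barriers),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' One-electron reduction potential of a protonation pattern
#'
#' Differences the energies of the (n+1)- and n-electron states sharing a
#' protonation pattern and converts via \eqn{\Delta G = -nF\Delta E} with
#' n = 1. Both states must be minima (not transition states).
#'
#' @param table an \code{energy_table}
#' @param eps dielectric constant
#' @param asp,prop proton-position labels of the fixed pattern
#' @param from_electrons reduction state before the transfer (0 or 1)
#' @return absolute reduction potential, volts
#' @examples
#' tab <- read_energy_table(system.file("extdata", "table1.csv",
#'                                      package = "pcetr"))
#' redox_potential(tab, 10, "Asp274", "Propionate", 0) # 2.92 V
#' @export
redox_potential <- function(table, eps, asp, prop, from_electrons) {
  s0 <- mechanism_state(from_electrons, asp, prop)
  s1 <- mechanism_state(from_electrons + 1L, asp, prop)
  if (s0$is_ts) stop("redox potentials are defined between minima")
  dg <- state_energy(table, s1, eps) - state_energy(table, s0, eps)
  potential_from_delta_g(dg, 1L)
}

#' Stereochemical penalty of wrong-face protonation
#'
#' For each ring carbon, the energy of the wrong-stereochemistry
#' singly-protonated state minus the energy of the correct-stereochemistry
#' state protonated at the same carbon, at a given reduction state.
#' Positive values mean the wrong face is disfavored.
#'
#' @param table an \code{energy_table}
#' @param eps dielectric constant
#' @param electrons reduction state (with wrong-stereo rows tabulated)
#' @return named numeric vector with elements \code{C17} and \code{C18},
#'   kcal/mol
#' @export
stereochemistry_penalty <- function(table, eps, electrons) {
  c(
    C17 = state_energy(table, mechanism_state(electrons, "Asp274", "C17*"),
                       eps) -
      state_energy(table, mechanism_state(electrons, "C17", "Propionate"),
                   eps),
    C18 = state_energy(table, mechanism_state(electrons, "C18*", "Propionate"),
                       eps) -
      state_energy(table, mechanism_state(electrons, "Asp274", "C18"), eps)
  )
}

#' The two canonical mechanism pathways
#'
#' Pathway A (slow cluster re-reduction): one-electron reduction, then both
#' proton transfers on the one-electron surface (Asp274 to C17 first, then
#' propionate to C18), then the second reduction. Pathway B (fast
#' re-reduction): reduction, propionate-to-C18 transfer, second reduction,
#' then the Asp274-to-C17 transfer on the two-electron surface.
#'
#' @param et_activation activation energy assigned to each electron-uptake
#'   step, kcal/mol (default 4, an upper bound for these transfers)
#' @return a named list of two \code{pathway}s, \code{A} and \code{B}
#' @export
canonical_pathways <- function(et_activation = 4) {
  A <- pathway(
    electron_step(mechanism_state(0, "Asp274", "Propionate"), et_activation),
    proton_step(mechanism_state(1, "Asp274", "Propionate"),
                mechanism_state(1, "Asp274...C17", "Propionate"),
                mechanism_state(1, "C17", "Propionate")),
    proton_step(mechanism_state(1, "C17", "Propionate"),
                mechanism_state(1, "C17", "Propionate...C18"),
                mechanism_state(1, "C17", "C18")),
    electron_step(mechanism_state(1, "C17", "C18"), et_activation)
  )
  B <- pathway(
    electron_step(mechanism_state(0, "Asp274", "Propionate"), et_activation),
    proton_step(mechanism_state(1, "Asp274", "Propionate"),
                mechanism_state(1, "Asp274", "Propionate...C18"),
                mechanism_state(1, "Asp274", "C18")),
    electron_step(mechanism_state(1, "Asp274", "C18"), et_activation),
    proton_step(mechanism_state(2, "Asp274", "C18"),
                mechanism_state(2, "Asp274...C17", "C18"),
                mechanism_state(2, "C17", "C18"))
  )
  list(A = A, B = B)
}

#' Compare the slow- and fast-re-reduction mechanisms
#'
#' Builds the two canonical pathways, reports their barrier breakdowns,
#' and classifies whether substrate chemistry or cluster re-reduction is
#' rate-limiting: if the better pathway's overall barrier lies below the
#' Eyring-derived limit, the chemistry is fast enough and the external
#' re-reduction of the cluster must be rate-limiting.
#'
#' @param table an \code{energy_table}
#' @param eps dielectric constant
#' @param et_activation electron-transfer activation energy, kcal/mol
#' @param eyring_limit experimental upper bound for the rate-determining
#'   barrier, kcal/mol (19.3 for this enzyme)
#' @return list with \code{A}, \code{B} (\code{barrier_report}s),
#'   \code{best_pathway} ("A" or "B"), \code{rate_limiting}
#'   ("substrate_chemistry" or "cluster_re_reduction")
#' @export
compare_mechanisms <- function(table, eps, et_activation = 4,
                               eyring_limit = 19.3) {
  stopifnot(et_activation >= 0)
  paths <- canonical_pathways(et_activation)
  suppressWarnings({
    rep_a <- pathway_overall_barrier(table, eps, paths$A)
    rep_b <- pathway_overall_barrier(table, eps, paths$B)
  })
  best <- if (rep_b$overall <= rep_a$overall) "B" else "A"
  best_overall <- min(rep_a$overall, rep_b$overall)
  list(
    A = rep_a, B = rep_b,
    best_pathway = best,
    best_overall = best_overall,
    rate_limiting = if (best_overall < eyring_limit) {
      "cluster_re_reduction"
    } else {
      "substrate_chemistry"
    }
  )
}
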