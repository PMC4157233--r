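# Protein electrostatic correction over protonation microstates:
# point-charge Coulomb evaluation, the total-minus-active-site
# decomposition, additive per-site contributions, Boltzmann averaging with
# correlated-site group factorization, and effective-dielectric screening.

.COULOMB_K <- 332.0636 # kcal A mol-1 e-2, vacuum (eps = 1)

#' Construct a point-charge set
#'
#' @param atoms data.frame with columns \code{x, y, z} (angstrom),
#'   \code{charge} (elementary units), \code{region} ("active" or
#'   "environment") and optionally \code{residue}
#' @return an object of class \code{charge_set}
#' @export
charge_set <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("x", "y", "z", "charge", "region") %in% names(atoms)))
  atoms$region <- match.arg(tolower(as.character(atoms$region)),
                            c("active", "environment"), several.ok = TRUE)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z", "charge")])))) {
    stop("coordinates and charges must be finite")
  }
  if (is.null(atoms$residue)) atoms$residue <- NA_character_
  structure(atoms, class = c("charge_set", "data.frame"))
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge set: %d atoms (%d active, %d environment), net charge %+.3f e>\n",
              nrow(x), sum(x$region == "active"),
              sum(x$region == "environment"), sum(x$charge)))
  invisible(x)
}

#' Read point charges from a PQR file
#'
#' Parses the whitespace-separated PQR dialect (ATOM/HETATM records with
#' charge and radius in place of occupancy/B-factor), tolerating the
#' optional chain identifier. Atoms are tagged "active" when their residue
#' name appears in \code{active_residues}, "environment" otherwise.
#'
#' @param path PQR file path
#' @param active_residues character vector of residue names forming the
#'   active region (default: none; everything is environment)
#' @return a \code{charge_set}
#' @export
read_pqr <- function(path, active_residues = character(0)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0) stop("no ATOM/HETATM records in ", path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    # ... name resName [chain] resSeq x y z q r : chain present iff 11 fields
    if (length(f) == 11) {
      list(residue = f[4], resseq = f[6], vals = as.numeric(f[7:10]))
    } else if (length(f) == 10) {
      list(residue = f[4], resseq = f[5], vals = as.numeric(f[6:9]))
    } else {
      stop("unparseable PQR record: ", paste(f, collapse = " "))
    }
  })
  vals <- do.call(rbind, lapply(rows, `[[`, "vals"))
  res <- vapply(rows, `[[`, character(1), "residue")
  charge_set(data.frame(
    x = vals[, 1], y = vals[, 2], z = vals[, 3], charge = vals[, 4],
    region = ifelse(res %in% active_residues, "active", "environment"),
    residue = res, stringsAsFactors = FALSE))
}

#' Electrostatic energy of a charge set
#'
#' Plain pairwise Coulomb sum \eqn{\sum_{i<j} 332.0636 q_i q_j / r_{ij}}
#' at unit dielectric, with no cutoff and no periodicity. The pair
#' selection restricts which interactions are counted.
#'
#' @param charges a \code{charge_set}
#' @param pairs which pairs to include: "all" (every pair), "active"
#'   (both atoms active), "environment" (both atoms environment) or
#'   "cross" (one atom in each region)
#' @return energy in kcal/mol
#' @examples
#' cs <- charge_set(data.frame(x = c(0, 3.320636), y = 0, z = 0,
#'                             charge = c(1, -1),
#'                             region = c("active", "environment")))
#' coulomb_energy(cs) # -100 kcal/mol
#' @export
coulomb_energy <- function(charges, pairs = c("all", "active", "environment",
                                              "cross")) {
  stopifnot(inherits(charges, "charge_set"))
  pairs <- match.arg(pairs)
  xyz <- as.matrix(charges[c("x", "y", "z")])
  q <- charges$charge
  act <- charges$region == "active"
  n <- nrow(xyz)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(xyz))
  qq <- tcrossprod(q)
  sel <- upper.tri(d)
  sel <- sel & switch(pairs,
    all = TRUE,
    active = outer(act, act, `&`),
    environment = outer(!act, !act, `&`),
    cross = outer(act, !act, `&`) | outer(!act, act, `&`)
  )
  if (!any(sel)) return(0)
  if (any(d[sel] == 0)) stop("coincident atoms at zero distance")
  .COULOMB_K * sum(qq[sel] / d[sel])
}

#' Protein electrostatic contribution to an active-site step
#'
#' The total-minus-active-site decomposition: total electrostatic energy of
#' the full system minus the internal electrostatic energy of the active
#' region. This equals the active/environment cross term plus the
#' environment self-energy; the latter is constant across intermediates
#' superimposed in a fixed environment and cancels in step differences.
#' \code{cross_only = TRUE} drops the environment self-energy for
#' diagnostics.
#'
#' @param charges a \code{charge_set}
#' @param cross_only if TRUE return only the active/environment cross term
#' @return energy in kcal/mol
#' @export
delta_prot <- function(charges, cross_only = FALSE) {
  cross <- coulomb_energy(charges, "cross")
  if (cross_only) cross else cross + coulomb_energy(charges, "environment")
}

#' Per-site contribution table for a set of reaction steps
#'
#' Holds, for each titratable site and each reaction step, the additive
#' contribution (kcal/mol) of that site being protonated to the step's
#' electrostatic energy.
#'
#' @param contributions numeric matrix, rows = sites (rownames = site ids),
#'   columns = reaction steps (colnames = step labels)
#' @return an object of class \code{site_contribution_table}
#' @export
site_contribution_table <- function(contributions) {
  contributions <- as.matrix(contributions)
  stopifnot(is.numeric(contributions), all(is.finite(contributions)),
            !is.null(rownames(contributions)), !is.null(colnames(contributions)))
  structure(contributions, class = c("site_contribution_table", "matrix"))
}

#' Read a site-contribution table from TSV
#'
#' Tab-separated: first column \code{site}, remaining columns one per
#' reaction step.
#'
#' @param path TSV file path
#' @return a \code{site_contribution_table}
#' @export
read_site_contributions <- function(path) {
  df <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  site_contribution_table(m)
}

#' Electrostatic energy of one protonation microstate for a step
#'
#' Additivity of per-site contributions: \code{fixed_part} plus the sum of
#' the contributions of the protonated sites.
#'
#' @param table a \code{site_contribution_table}
#' @param step step label (a column of the table)
#' @param state 0/1 protonation vector named or ordered as the table rows
#' @param fixed_part state-independent part of the step energy, kcal/mol
#' @return energy in kcal/mol
#' @export
microstate_step_energy <- function(table, step, state, fixed_part = 0) {
  stopifnot(inherits(table, "site_contribution_table"))
  if (!step %in% colnames(table)) stop("unknown step: ", step)
  if (!is.null(names(state))) {
    missing <- setdiff(names(state), rownames(table))
    if (length(missing)) stop("unknown site(s): ", paste(missing, collapse = ", "))
    contrib <- table[names(state), step]
  } else {
    if (length(state) != nrow(table)) {
      stop("state length must match the number of sites")
    }
    contrib <- table[, step]
  }
  stopifnot(all(state %in% c(0, 1)))
  fixed_part + sum(state * contrib)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Construct a grouped microstate population
#'
#' @param groups list of groups; each group is a list with \code{sites}
#'   (character vector of site ids), \code{states} (0/1 matrix, one row
#'   per sub-state, columns in site order) and \code{probs} (probabilities
#'   summing to 1 within 1e-9)
#' @return an object of class \code{microstate_population}
#' @export
microstate_population <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  for (g in groups) {
    stopifnot(all(c("sites", "states", "probs") %in% names(g)))
    st <- as.matrix(g$states)
    if (ncol(st) != length(g$sites)) stop("states/sites width mismatch")
    if (!all(st %in% c(0, 1))) stop("states must be 0/1")
    if (length(g$probs) != nrow(st)) stop("one probability per sub-state")
    if (any(g$probs < 0)) stop("negative probability")
    if (abs(sum(g$probs) - 1) > 1e-9) {
      stop("group probabilities must sum to 1 (tolerance 1e-9)")
    }
  }
  all_sites <- unlist(lapply(groups, `[[`, "sites"))
  if (anyDuplicated(all_sites)) stop("groups must partition the sites")
  structure(list(groups = groups), class = "microstate_population")
}

#' Convert a sampled trajectory into a grouped population
#'
#' Frequency-counts the distinct sub-states of each group over a 0/1
#' trajectory matrix (rows = samples, columns named by site id).
#'
#' @param trajectory 0/1 matrix with column names
#' @param site_groups list of character vectors partitioning the columns
#' @return a \code{microstate_population}
#' @export
population_from_trajectory <- function(trajectory, site_groups) {
  trajectory <- as.matrix(trajectory)
  stopifnot(!is.null(colnames(trajectory)))
  groups <- lapply(site_groups, function(sites) {
    sub <- trajectory[, sites, drop = FALSE]
    key <- apply(sub, 1, paste, collapse = "")
    tab <- table(key)
    states <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
    colnames(states) <- sites
    list(sites = sites, states = states,
         probs = as.numeric(tab) / nrow(sub))
  })
  microstate_population(groups)
}

#' Boltzmann-averaged electrostatic correction over protonation states
#'
#' Implements the phenomenological ensemble correction
#' \eqn{e^{-\Delta E_{avg}/RT} = \sum_i p_i e^{-\Delta E_i/RT}}, factorized
#' over the population's site groups (valid when inter-group correlations
#' are negligible): each group contributes
#' \eqn{\Delta E_g = -RT \ln \sum_i p_i e^{-\Delta E_i/RT}} over its own
#' sub-states and the total is the sum of group terms. Evaluation is in
#' log-sum-exp form, since contributions span tens of kcal/mol.
#'
#' @param table a \code{site_contribution_table}
#' @param step step label
#' @param population a \code{microstate_population} whose groups partition
#'   the table's sites
#' @param temperature kelvin (default 300)
#' @return Boltzmann-averaged correction, kcal/mol; lies within
#'   \code{[min, max]} of the per-microstate energies
#' @export
boltzmann_average_correction <- function(table, step, population,
                                         temperature = thermo_constants()$temperature_titration) {
  stopifnot(inherits(table, "site_contribution_table"),
            inherits(population, "microstate_population"))
  pop_sites <- unlist(lapply(population$groups, `[[`, "sites"))
  if (!setequal(pop_sites, rownames(table))) {
    stop("population groups must partition the table's sites")
  }
  rt <- .RGAS() * temperature
  total <- 0
  for (g in population$groups) {
    de <- drop(as.matrix(g$states) %*% table[g$sites, step])
    keep <- g$probs > 0
    lw <- log(g$probs[keep]) - de[keep] / rt
    total <- total - rt * .logsumexp(lw)
  }
  total
}

#' Group titratable sites by occupancy correlation
#'
#' Greedy agglomeration for the factorized ensemble average: site pairs
#' are visited in decreasing |correlation| and their groups merged while
#' the combined size stays within \code{max_group_size} (which bounds each
#' group's enumeration at 2^size sub-states). Reports the largest
#' |correlation| left between different groups, i.e. what the
#' factorization neglects.
#'
#' @param correlation symmetric correlation matrix with dimnames
#' @param max_group_size largest allowed group (default 10)
#' @return list with \code{groups} (list of character vectors) and
#'   \code{max_neglected} (largest inter-group |correlation|)
#' @export
group_sites <- function(correlation, max_group_size = 10) {
  correlation <- as.matrix(correlation)
  n <- nrow(correlation)
  stopifnot(n == ncol(correlation), max_group_size >= 1)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  ids <- rownames(correlation)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  member <- seq_len(n)
  prs <- which(upper.tri(correlation), arr.ind = TRUE)
  ord <- order(-abs(correlation[prs]))
  for (k in ord) {
    i <- prs[k, 1]; j <- prs[k, 2]
    if (abs(correlation[i, j]) == 0) break
    gi <- member[i]; gj <- member[j]
    if (gi == gj) next
    if (sum(member == gi) + sum(member == gj) <= max_group_size) {
      member[member == gj] <- gi
    }
  }
  groups <- unname(lapply(split(seq_len(n), member), function(ix) ids[ix]))
  max_neglected <- 0
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (a < b) {
        ia <- match(groups[[a]], ids); ib <- match(groups[[b]], ids)
        max_neglected <- max(max_neglected,
                             max(abs(correlation[ia, ib, drop = FALSE])))
      }
    }
  }
  list(groups = groups, max_neglected = max_neglected)
}

#' Screen an electrostatic correction by an effective dielectric
#'
#' Divides a unit-dielectric electrostatic stabilization by an effective
#' dielectric constant that stands in for protein/solvent relaxation
#' neglected in a fixed-geometry computation.
#'
#' @param correction electrostatic energy computed at unit dielectric,
#'   kcal/mol
#' @param epsilon_eff effective dielectric constant (>= 1)
#' @return screened energy, kcal/mol
#' @export
screen_by_effective_dielectric <- function(correction, epsilon_eff) {
  if (any(epsilon_eff < 1)) stop("effective dielectric must be >= 1")
  correction / epsilon_eff
}
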