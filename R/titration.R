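# Coupled protonation/reduction titration over a pH x potential grid:
# microstate energies, exact enumeration, Metropolis Monte Carlo sampling
# with scan-phase clamping, midpoint/slope estimation and site
# correlations.

#' Construct a system of interacting titratable sites
#'
#' A site is either a proton-binding site (intrinsic value in pKa units) or
#' an electron-binding site (intrinsic midpoint in volts, absolute scale of
#' the caller's choosing). The coupling matrix holds pairwise interaction
#' energies in kcal/mol, paid when both sites are occupied (proton bound /
#' electron bound, i.e. reduced); it must be symmetric with zero diagonal.
#' Intrinsic values and couplings are inputs (in practice from continuum
#' electrostatics); this module only samples them.
#'
#' @param sites data.frame with columns \code{id} (unique strings),
#'   \code{kind} ("proton" or "electron") and \code{intrinsic} (pKa for
#'   proton sites, volts for electron sites)
#' @param coupling symmetric numeric matrix (kcal/mol), zero diagonal,
#'   one row/column per site; defaults to no coupling
#' @param temperature kelvin (default 300)
#' @return an object of class \code{titration_system}
#' @examples
#' titration_system(data.frame(id = "his1", kind = "proton", intrinsic = 6.5))
#' @export
titration_system <- function(sites, coupling = NULL,
                             temperature = thermo_constants()$temperature_titration) {
  stopifnot(is.data.frame(sites),
            all(c("id", "kind", "intrinsic") %in% names(sites)))
  n <- nrow(sites)
  sites$id <- as.character(sites$id)
  sites$kind <- match.arg(tolower(as.character(sites$kind)),
                          c("proton", "electron"), several.ok = TRUE)
  if (anyDuplicated(sites$id)) stop("site ids must be unique")
  if (is.null(coupling)) coupling <- matrix(0, n, n)
  coupling <- unname(as.matrix(coupling))
  if (!all(dim(coupling) == n)) stop("coupling must be ", n, " x ", n)
  if (!isTRUE(all.equal(coupling, t(coupling), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("coupling matrix must be symmetric")
  }
  if (any(diag(coupling) != 0)) stop("coupling diagonal must be zero")
  dimnames(coupling) <- list(sites$id, sites$id)
  structure(list(sites = sites, coupling = coupling,
                 temperature = temperature),
            class = "titration_system")
}

#' @export
print.titration_system <- function(x, ...) {
  cat(sprintf("<titration system: %d sites (%d proton, %d electron), %d couplings, T = %g K>\n",
              nrow(x$sites), sum(x$sites$kind == "proton"),
              sum(x$sites$kind == "electron"),
              sum(x$coupling[upper.tri(x$coupling)] != 0), x$temperature))
  invisible(x)
}

# one-body site energies (kcal/mol) at a grid point; potential in volts
.site_g <- function(system, ph, potential_v) {
  st <- system$sites
  rt <- .RGAS() * system$temperature
  ifelse(st$kind == "proton",
         rt * log(10) * (ph - st$intrinsic),
         .FARADAY() * (potential_v - st$intrinsic))
}

#' Energy of one protonation/reduction microstate
#'
#' \eqn{E(s) = \sum_i s_i g_i + \sum_{i<j} W_{ij} s_i s_j}, with
#' \eqn{g_i = RT \ln 10 (pH - pKa_i)} for proton sites and
#' \eqn{g_i = F (E - E^\circ_i)} for electron sites: occupancy (bound /
#' reduced) is penalized above the site's midpoint. The all-unbound state
#' is the zero of energy.
#'
#' @param system a \code{titration_system}
#' @param state 0/1 occupancy vector, one entry per site
#' @param ph solution pH
#' @param potential solution redox potential, volts
#' @return microstate energy, kcal/mol
#' @export
microstate_energy <- function(system, state, ph, potential) {
  stopifnot(inherits(system, "titration_system"))
  n <- nrow(system$sites)
  if (length(state) != n || !all(state %in% c(0, 1))) {
    stop("state must be a 0/1 vector of length ", n)
  }
  g <- .site_g(system, ph, potential)
  sum(state * g) + 0.5 * drop(state %*% system$coupling %*% state)
}

#' Construct the sampling grid for a titration
#'
#' Defaults follow the standard protocol: pH 5 to 9 in 0.1 steps,
#' potential -750 to -200 mV in 20 mV steps, 2e5 scan steps, 1e6
#' production steps, and a 0.9 clamp threshold (sites at least 90%
#' protonated or deprotonated across the scan of the whole grid are frozen
#' for production).
#'
#' @param ph vector of pH values
#' @param potential_mv vector of potentials, millivolts
#' @param steps_scan,steps_production Monte Carlo steps per grid point in
#'   the scan and production phases
#' @param clamp_threshold occupancy threshold in (0.5, 1] deciding which
#'   sites are frozen after the scan; 1 disables clamping for all but
#'   strictly constant sites
#' @param seed integer seed controlling all sampling
#' @return a list of class \code{grid_spec}
#' @export
grid_spec <- function(ph = seq(5, 9, by = 0.1),
                      potential_mv = seq(-750, -200, by = 20),
                      steps_scan = 2e5, steps_production = 1e6,
                      clamp_threshold = 0.9, seed = 1) {
  stopifnot(steps_scan > 0, steps_production > 0,
            clamp_threshold > 0.5, clamp_threshold <= 1,
            length(ph) >= 1, length(potential_mv) >= 1)
  structure(list(ph = ph, potential_mv = potential_mv,
                 steps_scan = as.integer(steps_scan),
                 steps_production = as.integer(steps_production),
                 clamp_threshold = clamp_threshold,
                 seed = as.integer(seed)),
            class = "grid_spec")
}

.new_occupancy_map <- function(system, grid, theta, se, moments,
                               n_moment_samples, clamped, method,
                               state_counts = NULL, trajectories = NULL) {
  structure(list(sites = system$sites, ph = grid$ph,
                 potential_mv = grid$potential_mv, theta = theta, se = se,
                 moments = moments, n_moment_samples = n_moment_samples,
                 clamped = clamped, method = method,
                 temperature = system$temperature,
                 state_counts = state_counts, trajectories = trajectories),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy map (%s): %d sites on %d pH x %d potential grid>\n",
              x$method, nrow(x$sites), length(x$ph), length(x$potential_mv)))
  if (any(x$clamped != 0L)) {
    cat("  clamped:", paste0(x$sites$id[x$clamped != 0L], "=",
                             pmax(x$clamped[x$clamped != 0L], 0),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact (enumerated) titration of a small system
#'
#' Boltzmann-exact occupancies from the full 2^N partition function at
#' every grid point. Serves as the oracle for the Monte Carlo sampler;
#' limited to 20 sites.
#'
#' @param system a \code{titration_system}
#' @param grid a \code{grid_spec} (its step counts and seed are ignored)
#' @return an \code{occupancy_map} with zero sampling error
#' @examples
#' sys <- titration_system(
#'   data.frame(id = "a", kind = "proton", intrinsic = 7))
#' occ <- exact_titration(sys, grid_spec(ph = 7, potential_mv = -400))
#' occ$theta[1, 1, 1] # 0.5 at pH = pKa
#' @export
exact_titration <- function(system, grid) {
  stopifnot(inherits(system, "titration_system"),
            inherits(grid, "grid_spec"))
  n <- nrow(system$sites)
  if (n > 20) stop("exact enumeration limited to 20 sites (2^N states)")
  rt <- .RGAS() * system$temperature
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, seq_len(n), drop = FALSE]
  colnames(states) <- system$sites$id
  pair_e <- 0.5 * rowSums((states %*% system$coupling) * states)

  np <- length(grid$ph); nv <- length(grid$potential_mv)
  theta <- array(NA_real_, c(n, np, nv),
                 dimnames = list(system$sites$id, NULL, NULL))
  moments <- array(NA_real_, c(n, n, np, nv))
  for (i in seq_len(np)) {
    for (j in seq_len(nv)) {
      g <- .site_g(system, grid$ph[i], grid$potential_mv[j] / 1000)
      e <- drop(states %*% g) + pair_e
      w <- exp(-(e - min(e)) / rt)
      w <- w / sum(w)
      theta[, i, j] <- drop(crossprod(states, w))
      moments[, , i, j] <- crossprod(states, states * w)
    }
  }
  .new_occupancy_map(system, grid, theta, se = array(0, dim(theta)),
                     moments = moments, n_moment_samples = Inf,
                     clamped = integer(n), method = "exact")
}

# strong-coupling threshold for pair moves: 2 pKa units at the system
# temperature
.pair_move_threshold <- function(temperature) {
  2 * .RGAS() * temperature * log(10)
}

.mc_one_phase <- function(system, grid, free, fixed_state, n_steps,
                          point_seeds, track_states, trajectory_points) {
  n <- nrow(system$sites)
  np <- length(grid$ph); nv <- length(grid$potential_mv)
  rt <- .RGAS() * system$temperature
  w_free <- system$coupling[free, free, drop = FALSE]
  thr <- .pair_move_threshold(system$temperature)
  pm <- which(abs(w_free) > thr & upper.tri(w_free), arr.ind = TRUE)
  pm <- matrix(as.integer(pm - 1L), ncol = 2) # 0-based for C++
  nf <- length(free)
  # thin at ~one sweep, but keep the interval odd: with degenerate sites
  # every flip is accepted and state parity alternates each step, which an
  # even sampling interval would alias
  thin <- max(1L, nf + (nf %% 2L == 0L))
  n_equil <- as.integer(min(max(1000, n_steps %/% 10), n_steps))

  theta <- array(NA_real_, c(n, np, nv),
                 dimnames = list(system$sites$id, NULL, NULL))
  se <- array(0, c(n, np, nv))
  moments <- array(NA_real_, c(n, n, np, nv))
  n_mom <- array(0, c(np, nv))
  counts <- if (track_states) vector("list", np * nv) else NULL
  trajs <- if (length(trajectory_points)) list() else NULL

  g_all <- matrix(NA_real_, n, np * nv)
  k <- 0
  for (j in seq_len(nv)) {
    for (i in seq_len(np)) {
      k <- k + 1
      g_all[, k] <- .site_g(system, grid$ph[i], grid$potential_mv[j] / 1000)
    }
  }

  k <- 0
  for (j in seq_len(nv)) {
    for (i in seq_len(np)) {
      k <- k + 1
      g <- g_all[, k]
      # fold clamped occupancies into the free sites' one-body terms
      g_free <- g[free] + drop(system$coupling[free, , drop = FALSE] %*%
                                 fixed_state)
      set.seed(point_seeds[k])
      init <- as.integer(runif(nf) < 0.5)
      keep_traj <- k %in% trajectory_points
      res <- .mc_sample_point(g_free, w_free, rt, init, as.integer(n_steps),
                              n_equil, pm, as.integer(min(20, n_steps)), thin,
                              track_states, keep_traj)
      th <- fixed_state
      th[free] <- res$theta
      theta[, i, j] <- th
      se_ij <- numeric(n)
      # batch estimates collapse for near-deterministic sites, where the
      # error is Poisson episode noise: a site is attempted every ~n_free
      # steps, so a minority spell lasts ~n_free steps and the occupancy
      # variance is at least (episodes + 2) * (n_free/n_steps)^2
      minority <- pmin(res$theta, 1 - res$theta) * n_steps
      floor_se <- sqrt((minority + 2 * nf) * nf) / n_steps
      se_ij[free] <- pmax(res$se, floor_se)
      se[, i, j] <- se_ij
      # clamped sites are constants: E[s_i s_j] factorizes through them
      mom <- outer(th, th)
      mom[free, free] <- res$moments
      moments[, , i, j] <- mom
      n_mom[i, j] <- res$n_moment_samples
      if (track_states) counts[[k]] <- res$state_counts
      if (keep_traj) trajs[[as.character(k)]] <- res$trajectory
    }
  }
  list(theta = theta, se = se, moments = moments, n_mom = n_mom,
       counts = counts, trajs = trajs)
}

#' Metropolis Monte Carlo titration
#'
#' Samples the coupled protonation/reduction microstates at every grid
#' point with single-site Metropolis flips, plus two-site flips for
#' strongly coupled pairs (|W| above 2 pKa units, which fixes mixing for
#' locked pairs). A scan phase over the whole grid first identifies sites
#' that stay at least \code{clamp_threshold} protonated (or deprotonated)
#' at every grid point; those are frozen at that state for the production
#' phase and excluded from moves, as in the standard protocol. Standard
#' errors come from 20 batch means, floored at 1/steps.
#'
#' Reproducibility: all randomness derives from \code{grid$seed}; each
#' grid point samples with its own derived seed, so results are identical
#' under any evaluation order.
#'
#' @param system a \code{titration_system}
#' @param grid a \code{grid_spec}
#' @param track_states if TRUE (and 20 sites or fewer), accumulate
#'   per-microstate visit counts for each grid point (production phase)
#' @param trajectory_points integer indices of grid points (column-major
#'   over pH then potential) for which a thinned 0/1 trajectory of the
#'   free sites is returned
#' @return an \code{occupancy_map}; clamped sites have \code{clamped}
#'   entries +1 (bound) or -1 (unbound) and zero standard error
#' @export
mc_titration <- function(system, grid, track_states = FALSE,
                         trajectory_points = integer(0)) {
  stopifnot(inherits(system, "titration_system"),
            inherits(grid, "grid_spec"))
  n <- nrow(system$sites)
  npts <- length(grid$ph) * length(grid$potential_mv)
  set.seed(grid$seed)
  scan_seeds <- sample.int(.Machine$integer.max - 1L, npts)
  prod_seeds <- sample.int(.Machine$integer.max - 1L, npts)

  scan <- .mc_one_phase(system, grid, free = seq_len(n),
                        fixed_state = numeric(n),
                        n_steps = grid$steps_scan,
                        point_seeds = scan_seeds,
                        track_states = FALSE,
                        trajectory_points = integer(0))

  # clamp decision over the full grid
  mins <- apply(scan$theta, 1, min)
  maxs <- apply(scan$theta, 1, max)
  clamped <- integer(n)
  clamped[mins >= grid$clamp_threshold] <- 1L
  clamped[maxs <= 1 - grid$clamp_threshold] <- -1L
  free <- which(clamped == 0L)
  fixed_state <- as.numeric(clamped == 1L)

  if (length(free) == 0) {
    # fully clamped system: occupancies are the clamped pattern everywhere
    np <- length(grid$ph); nv <- length(grid$potential_mv)
    theta <- array(fixed_state, c(n, np, nv),
                   dimnames = list(system$sites$id, NULL, NULL))
    mom <- tcrossprod(fixed_state)
    moments <- array(mom, c(n, n, np, nv))
    return(.new_occupancy_map(system, grid, theta,
                              se = array(0, c(n, np, nv)),
                              moments = moments, n_moment_samples = Inf,
                              clamped = clamped, method = "mc"))
  }

  prod <- .mc_one_phase(system, grid, free = free,
                        fixed_state = fixed_state,
                        n_steps = grid$steps_production,
                        point_seeds = prod_seeds,
                        track_states = track_states && length(free) <= 20,
                        trajectory_points = trajectory_points)

  .new_occupancy_map(system, grid, prod$theta, prod$se, prod$moments,
                     prod$n_mom, clamped, method = "mc",
                     state_counts = prod$counts,
                     trajectories = prod$trajs)
}

#' Midpoint potential, Nernst slope and proton uptake of an electron site
#'
#' For each requested pH (matched to the nearest evaluated grid pH), the
#' half-reduction potential is found by monotone linear interpolation of
#' the site's occupancy at 0.5; the slope of midpoint vs pH comes from a
#' least-squares fit over those pH values, and the implied proton uptake
#' per electron is \code{-slope / (1000 RT ln10 / F)} (one fully coupled
#' proton gives about -59.5 mV/pH at 300 K).
#'
#' @param occ an \code{occupancy_map}
#' @param site id of an electron site
#' @param ph_values pH values at which to evaluate midpoints
#'   (default 5, 7, 9)
#' @return list with \code{e_half} (named mV vector), \code{slope_mv_per_ph}
#'   and \code{protons_per_electron}
#' @export
midpoint_and_slope <- function(occ, site, ph_values = c(5, 7, 9)) {
  stopifnot(inherits(occ, "occupancy_map"))
  k <- match(site, occ$sites$id)
  if (is.na(k)) stop("unknown site: ", site)
  if (occ$sites$kind[k] != "electron") {
    stop("midpoints are defined for electron sites")
  }
  e_half <- vapply(ph_values, function(p) {
    i <- which.min(abs(occ$ph - p))
    th <- occ$theta[k, i, ]
    v <- occ$potential_mv
    # reduced fraction decreases with potential
    below <- which(th >= 0.5)
    above <- which(th < 0.5)
    if (length(below) == 0 || length(above) == 0) {
      stop("midpoint out of window for site '", site, "' at pH ", p)
    }
    a <- max(below); b <- min(above)
    if (b != a + 1) { # non-monotone sampling noise: use closest crossing
      ord <- order(v)
      th <- th[ord]; v <- v[ord]
      cross <- which(diff(th >= 0.5) != 0)[1]
      a <- cross; b <- cross + 1
    }
    v[a] + (0.5 - th[a]) * (v[b] - v[a]) / (th[b] - th[a])
  }, numeric(1))
  names(e_half) <- ph_values
  slope <- if (length(ph_values) > 1) {
    unname(coef(lm(e_half ~ ph_values))[2])
  } else {
    0
  }
  nernst <- 1000 * .RGAS() * occ$temperature * log(10) / .FARADAY()
  list(e_half = e_half, slope_mv_per_ph = slope,
       protons_per_electron = -slope / nernst)
}

#' Pearson correlation between two sites' occupancies
#'
#' Computed from the sampled (or exact) second moments at one grid point:
#' \eqn{r = (E[s_i s_j] - \theta_i\theta_j) /
#' \sqrt{\theta_i(1-\theta_i)\theta_j(1-\theta_j)}}. Correlation with a
#' clamped (frozen) site is undefined and returned as NA with a warning.
#'
#' @param occ an \code{occupancy_map}
#' @param pair character vector of two site ids (a site with itself gives 1)
#' @param ph,potential_mv grid point at which to evaluate (nearest match)
#' @return correlation coefficient in [-1, 1], or NA for clamped sites
#' @export
site_correlation <- function(occ, pair, ph, potential_mv) {
  stopifnot(inherits(occ, "occupancy_map"), length(pair) == 2)
  ij <- match(pair, occ$sites$id)
  if (anyNA(ij)) stop("unknown site id in pair")
  if (any(occ$clamped[ij] != 0L)) {
    warning("correlation undefined for clamped site(s): ",
            paste(pair[occ$clamped[ij] != 0L], collapse = ", "))
    return(NA_real_)
  }
  i <- which.min(abs(occ$ph - ph))
  j <- which.min(abs(occ$potential_mv - potential_mv))
  if (ij[1] == ij[2]) return(1)
  m <- occ$moments[, , i, j]
  th <- occ$theta[, i, j]
  cov_ij <- m[ij[1], ij[2]] - th[ij[1]] * th[ij[2]]
  den <- sqrt(th[ij[1]] * (1 - th[ij[1]]) * th[ij[2]] * (1 - th[ij[2]]))
  if (den == 0) return(NA_real_)
  # moments are thinned while means use every step; clip the tiny
  # inconsistency that can push |r| past 1
  max(-1, min(1, cov_ij / den))
}
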