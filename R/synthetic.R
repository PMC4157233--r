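# Seeded generators for every input the pipeline consumes, each carrying
# planted ground truth for recovery tests. All generators are pure
# functions of their arguments: the seed pins R's default Mersenne-Twister
# stream locally and the previous RNG state is restored on exit.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random titration system with planted truth
#'
#' Sites receive intrinsic values drawn uniformly from the given ranges
#' (defaults straddle the standard sampling windows of pH 5-9 and -750 to
#' -200 mV so that midpoints are observable); a sparse symmetric coupling
#' matrix is drawn with the given density and magnitude scale.
#'
#' @param n_sites number of sites (>= 1)
#' @param seed integer seed
#' @param n_electron how many of the sites are electron sites (default 1
#'   when \code{n_sites} > 1, else 0)
#' @param pka_range range of proton-site pKa values (default 3-10)
#' @param midpoint_range range of electron-site midpoints, volts
#'   (default -0.6 to -0.2)
#' @param coupling_density fraction of site pairs coupled (default 0.3)
#' @param coupling_scale magnitude scale of couplings, kcal/mol; each
#'   coupling is uniform on ±scale (default 2)
#' @param temperature kelvin (default 300)
#' @return list with \code{system} (a \code{titration_system}) and
#'   \code{truth} (planted intrinsic values and coupling matrix)
#' @export
gen_titration_system <- function(n_sites, seed, n_electron = NULL,
                                 pka_range = c(3, 10),
                                 midpoint_range = c(-0.6, -0.2),
                                 coupling_density = 0.3,
                                 coupling_scale = 2,
                                 temperature = 300) {
  stopifnot(n_sites >= 1, diff(pka_range) >= 0, diff(midpoint_range) >= 0,
            coupling_density >= 0, coupling_density <= 1)
  if (is.null(n_electron)) n_electron <- if (n_sites > 1) 1L else 0L
  stopifnot(n_electron <= n_sites)
  .with_seed(seed, {
    kind <- c(rep("electron", n_electron),
              rep("proton", n_sites - n_electron))
    intrinsic <- ifelse(kind == "electron",
                        runif(n_sites, midpoint_range[1], midpoint_range[2]),
                        runif(n_sites, pka_range[1], pka_range[2]))
    w <- matrix(0, n_sites, n_sites)
    if (n_sites > 1) {
      up <- which(upper.tri(w))
      on <- runif(length(up)) < coupling_density
      w[up[on]] <- runif(sum(on), -coupling_scale, coupling_scale)
      w <- w + t(w)
    }
    sites <- data.frame(id = sprintf("site%02d", seq_len(n_sites)),
                        kind = kind, intrinsic = intrinsic,
                        stringsAsFactors = FALSE)
    system <- titration_system(sites, w, temperature)
    list(system = system,
         truth = list(intrinsic = setNames(intrinsic, sites$id),
                      kind = setNames(kind, sites$id), coupling = w))
  })
}

#' Generate a mechanism energy table with planted barriers
#'
#' Builds a table shaped like the packaged 25-state fixture: three
#' reduction surfaces, each with its resting state, singly/doubly
#' protonated minima, the four proton-transfer transition states of the
#' two canonical pathways and the wrong-stereochemistry rows. The four
#' pathway barriers (A1: Asp274-to-C17 at 1 e-; A2: propionate-to-C18 at
#' 1 e-; B1: propionate-to-C18 at 1 e-; B2: Asp274-to-C17 at 2 e-) are
#' planted exactly as energetic-span barriers, so pathway analysis must
#' recover the planted rate-limiting step.
#'
#' @param seed integer seed
#' @param barrier_range range the four planted barriers are drawn from,
#'   kcal/mol (default 5-20)
#' @param electron_drop energy released per added electron, kcal/mol
#'   (sets the spacing of the reduction surfaces; default 70)
#' @return list with \code{table} (an \code{energy_table}) and
#'   \code{truth} (the planted barriers, per-pathway rate-limiting step
#'   index among proton steps, and the overall planted barrier)
#' @export
gen_energy_table <- function(seed, barrier_range = c(5, 20),
                             electron_drop = 70) {
  stopifnot(diff(barrier_range) >= 0, barrier_range[1] > 0)
  .with_seed(seed, {
    b <- runif(4, barrier_range[1], barrier_range[2])
    names(b) <- c("A1", "A2", "B1", "B2")
    # surface resting energies and within-surface minima (products lie at
    # or below the resting state so span barriers equal the planted values)
    base <- c(0, -electron_drop, -2 * electron_drop)
    drop1 <- runif(3, 0, 5)   # singly-protonated product below resting
    drop2 <- runif(3, 0, 5)   # doubly-protonated product below that
    rows <- list()
    add <- function(e, asp, prop, energy) {
      rows[[length(rows) + 1]] <<- data.frame(
        electrons = e, asp_proton = asp, prop_proton = prop,
        is_ts = grepl("\\.\\.\\.", paste(asp, prop)), energy = energy,
        stringsAsFactors = FALSE)
    }
    for (n in 0:2) {
      e0 <- base[n + 1]
      eC17 <- e0 - drop1[n + 1]
      eC18 <- e0 - drop1[n + 1] - 0.5
      eBoth <- min(eC17, eC18) - drop2[n + 1]
      add(n, "Asp274", "Propionate", e0)
      add(n, "C17", "Propionate", eC17)
      add(n, "Asp274", "C18", eC18)
      if (n > 0) add(n, "C17", "C18", eBoth)
      add(n, "C18*", "Propionate", eC18 + 6)
      add(n, "Asp274", "C17*", eC17 + 6)
      if (n == 1) {
        add(n, "Asp274...C17", "Propionate", e0 + b["A1"])
        add(n, "C17", "Propionate...C18", min(e0, eC17) + b["A2"])
        add(n, "Asp274", "Propionate...C18", e0 + b["B1"])
      }
      if (n == 2) {
        add(n, "Asp274...C17", "C18", eC18 + b["B2"])
      }
    }
    df <- do.call(rbind, rows)
    path <- tempfile(fileext = ".csv")
    on.exit(unlink(path), add = TRUE)
    df_out <- df
    names(df_out)[names(df_out) == "energy"] <- "eps10"
    write.csv(df_out, path, row.names = FALSE, quote = FALSE)
    table <- read_energy_table(path)
    truth <- list(
      barriers = b,
      rate_limiting_A = unname(which.max(b[c("A1", "A2")])),
      rate_limiting_B = unname(which.max(b[c("B1", "B2")])),
      overall_A = max(b[c("A1", "A2")]),
      overall_B = max(b[c("B1", "B2")])
    )
    list(table = table, truth = truth)
  })
}

#' Generate a random point-charge fixture
#'
#' Non-overlapping point charges in a cubic box with region tags and a
#' minimum pair separation, for exercising the Coulomb evaluator.
#'
#' @param n_atoms number of atoms
#' @param seed integer seed
#' @param box box edge, angstrom (default 20)
#' @param min_separation smallest allowed interatomic distance, angstrom
#'   (default 1)
#' @param charge_range charges drawn uniformly from this range (default
#'   ±1)
#' @param frac_active fraction of atoms tagged active (default 0.3)
#' @return a \code{charge_set}
#' @export
gen_charge_fixture <- function(n_atoms, seed, box = 20, min_separation = 1,
                               charge_range = c(-1, 1), frac_active = 0.3) {
  stopifnot(n_atoms >= 1, box > 0, min_separation >= 0)
  .with_seed(seed, {
    xyz <- matrix(NA_real_, n_atoms, 3)
    placed <- 0
    tries <- 0
    while (placed < n_atoms) {
      tries <- tries + 1
      if (tries > 1e5) stop("cannot place atoms at this density")
      p <- runif(3, 0, box)
      if (placed == 0 ||
          min(sqrt(colSums((t(xyz[seq_len(placed), , drop = FALSE]) - p)^2))) >=
            min_separation) {
        placed <- placed + 1
        xyz[placed, ] <- p
      }
    }
    n_active <- max(1, round(frac_active * n_atoms))
    charge_set(data.frame(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = runif(n_atoms, charge_range[1], charge_range[2]),
      region = c(rep("active", n_active),
                 rep("environment", n_atoms - n_active)),
      residue = sprintf("RES%d", seq_len(n_atoms)),
      stringsAsFactors = FALSE))
  })
}

#' Generate a microstate population with tunable inter-group correlation
#'
#' Draws a joint distribution over all 2^N protonation states from a
#' two-component latent mixture: given a latent toggle (probability 1/2
#' each way), site i is protonated with probability shifted up or down
#' from its base value by the correlation strength. At strength 0 the
#' joint is an exact product over sites (hence over any grouping); as the
#' strength grows, all sites (and therefore the groups) become
#' positively correlated.
#'
#' @param n_sites number of sites (<= 16; the full joint is enumerated)
#' @param seed integer seed
#' @param correlation correlation strength in [0, 1]
#' @return list with \code{sites} (ids), \code{states} (2^N x N matrix),
#'   \code{probs} (joint probabilities summing to 1), \code{base}
#'   (per-site base protonation probabilities)
#' @export
gen_population <- function(n_sites, seed, correlation = 0) {
  stopifnot(n_sites >= 1, n_sites <= 16, correlation >= 0, correlation <= 1)
  .with_seed(seed, {
    base <- runif(n_sites, 0.2, 0.8)
    up <- base + correlation * (1 - base)
    down <- base * (1 - correlation)
    states <- as.matrix(expand.grid(rep(list(0:1), n_sites)))
    colnames(states) <- sprintf("site%02d", seq_len(n_sites))
    p_of <- function(prob) {
      apply(states, 1, function(s) prod(ifelse(s == 1, prob, 1 - prob)))
    }
    probs <- 0.5 * p_of(up) + 0.5 * p_of(down)
    probs <- probs / sum(probs)
    list(sites = colnames(states), states = states, probs = probs,
         base = base)
  })
}

#' Marginalize a joint population onto site groups
#'
#' Produces the grouped population (a product approximation across
#' groups) from a full joint distribution, by summing the joint
#' probability over the complement of each group.
#'
#' @param population output of [gen_population()]
#' @param site_groups list of character vectors partitioning the sites
#' @return a \code{microstate_population}
#' @export
population_marginals <- function(population, site_groups) {
  stopifnot(setequal(unlist(site_groups), population$sites))
  groups <- lapply(site_groups, function(sites) {
    ix <- match(sites, population$sites)
    sub <- population$states[, ix, drop = FALSE]
    key <- apply(sub, 1, paste, collapse = "")
    agg <- tapply(population$probs, key, sum)
    states <- do.call(rbind, lapply(strsplit(names(agg), ""), as.integer))
    colnames(states) <- sites
    list(sites = sites, states = states, probs = as.numeric(agg))
  })
  microstate_population(groups)
}
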