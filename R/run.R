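# Configuration-driven front end: one entry point dispatching the
# package's analyses from a serializable config, echoing the config next
# to deterministic TSV/JSON reports.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file ending in .yml/.yaml (requires the yaml package) or
#'   .json
#' @return a named list
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
}

#' Run one configured analysis and write its reports
#'
#' Dispatches on \code{config$analysis}:
#' \describe{
#'   \item{redox}{one-electron reduction potentials of every minimum
#'     protonation pattern present at consecutive reduction states of an
#'     energy table (\code{table}, \code{eps})}
#'   \item{barriers}{barrier report of canonical pathway \code{pathway}
#'     ("A" or "B"); \code{et_activation} optional}
#'   \item{stereo}{stereochemistry penalties at each reduction state}
#'   \item{marcus}{activation energy for \code{delta_g},
#'     \code{lambda_reactant}, \code{lambda_product}}
#'   \item{titrate}{Monte Carlo titration of a site/coupling input
#'     (\code{sites}, \code{coupling} TSV paths; grid parameters and
#'     \code{seed} optional) plus midpoint/slope for electron sites}
#'   \item{simulate}{write generator outputs (\code{generator} =
#'     "titration_system", "energy_table" or "charges"; \code{seed})}
#' }
#' The config is echoed to \code{config.json} in \code{out_dir}; re-running
#' with the echoed config reproduces the numeric reports byte-identically.
#'
#' @param config named list (see details) or a path readable by
#'   [read_run_config()]
#' @param out_dir output directory, created if missing
#' @return named list of result objects, invisibly; reports are written
#'   as TSV and JSON files under \code{out_dir}
#' @export
run_analysis <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config), !is.null(config$analysis))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- switch(config$analysis,
    redox = .run_redox(config),
    barriers = .run_barriers(config),
    stereo = .run_stereo(config),
    marcus = .run_marcus(config),
    titrate = .run_titrate(config),
    simulate = .run_simulate(config, out_dir),
    stop("unknown analysis: ", config$analysis)
  )
  for (nm in names(out$tables)) {
    .write_tsv(out$tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(out$json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

.load_table <- function(config) {
  if (is.null(config$table)) stop("config$table (energy table CSV) required")
  if (!file.exists(config$table)) stop("input file not found: ", config$table)
  read_energy_table(config$table)
}

.run_redox <- function(config) {
  tab <- .load_table(config)
  eps <- config$eps %||% 10
  res <- list()
  for (n in 0:1) {
    here <- tab[tab$electrons == n & !tab$is_ts, ]
    nxt <- tab[tab$electrons == n + 1 & !tab$is_ts, ]
    shared <- merge(here[c("asp_proton", "prop_proton")],
                    nxt[c("asp_proton", "prop_proton")])
    if (nrow(shared) == 0) next
    pot <- vapply(seq_len(nrow(shared)), function(i) {
      redox_potential(tab, eps, shared$asp_proton[i], shared$prop_proton[i], n)
    }, numeric(1))
    res[[length(res) + 1]] <- data.frame(
      from_electrons = n, asp_proton = shared$asp_proton,
      prop_proton = shared$prop_proton, potential_v = round(pot, 2))
  }
  df <- do.call(rbind, res)
  list(tables = list(redox = df),
       json = list(analysis = "redox", eps = eps,
                   potentials_v = setNames(
                     df$potential_v,
                     paste0(df$from_electrons, "/", df$asp_proton, "/",
                            df$prop_proton))))
}

.run_barriers <- function(config) {
  tab <- .load_table(config)
  eps <- config$eps %||% 10
  et <- config$et_activation %||% 4
  cmp <- compare_mechanisms(tab, eps, et,
                            eyring_limit = config$eyring_limit %||% 19.3)
  pick <- config$pathway %||% "both"
  mk <- function(rep, nm) data.frame(
    pathway = nm, step = seq_along(rep$step_barriers),
    forward_kcal = round(rep$step_barriers, 1),
    span_kcal = round(rep$span_barriers, 1))
  tabs <- switch(pick,
    A = mk(cmp$A, "A"), B = mk(cmp$B, "B"),
    both = rbind(mk(cmp$A, "A"), mk(cmp$B, "B")))
  list(tables = list(barriers = tabs),
       json = list(analysis = "barriers", eps = eps,
                   overall_A = cmp$A$overall, overall_B = cmp$B$overall,
                   best_pathway = cmp$best_pathway,
                   rate_limiting = cmp$rate_limiting))
}

.run_stereo <- function(config) {
  tab <- .load_table(config)
  eps <- config$eps %||% 10
  ns <- sort(unique(tab$electrons[tab$asp_proton == "C18*" |
                                    tab$prop_proton == "C17*"]))
  rows <- do.call(rbind, lapply(ns, function(n) {
    p <- stereochemistry_penalty(tab, eps, n)
    data.frame(electrons = n, carbon = names(p), penalty_kcal = round(p, 1),
               row.names = NULL)
  }))
  list(tables = list(stereo = rows),
       json = list(analysis = "stereo", eps = eps,
                   penalties = split(rows$penalty_kcal, rows$electrons)))
}

.run_marcus <- function(config) {
  res <- marcus_activation(config$delta_g, config$lambda_reactant,
                           config$lambda_product)
  list(tables = list(),
       json = list(analysis = "marcus", status = res$status,
                   activation = res$activation, x_star = res$x_star))
}

.run_titrate <- function(config) {
  sites <- read.csv(config$sites, sep = "\t", stringsAsFactors = FALSE)
  w <- if (!is.null(config$coupling)) {
    as.matrix(read.csv(config$coupling, sep = "\t", header = FALSE))
  } else {
    NULL
  }
  sys <- titration_system(sites, w,
                          temperature = config$temperature %||% 300)
  grid <- grid_spec(
    ph = config$ph %||% seq(5, 9, 0.1),
    potential_mv = config$potential_mv %||% seq(-750, -200, 20),
    steps_scan = config$steps_scan %||% 2e5,
    steps_production = config$steps_production %||% 1e6,
    clamp_threshold = config$clamp_threshold %||% 0.9,
    seed = config$seed %||% 1)
  occ <- mc_titration(sys, grid)
  flat <- expand.grid(site = sys$sites$id, ph = grid$ph,
                      potential_mv = grid$potential_mv)
  flat$occupancy <- as.vector(occ$theta)
  flat$se <- as.vector(occ$se)
  mids <- list()
  for (id in sys$sites$id[sys$sites$kind == "electron"]) {
    mids[[id]] <- tryCatch(
      midpoint_and_slope(occ, id,
                         ph_values = config$slope_ph %||% c(5, 7, 9)),
      error = function(e) list(error = conditionMessage(e)))
  }
  list(tables = list(occupancy = flat),
       json = list(analysis = "titrate", seed = grid$seed,
                   clamped = setNames(as.list(occ$clamped), sys$sites$id),
                   midpoints = mids))
}

.run_simulate <- function(config, out_dir) {
  gen <- config$generator %||% "titration_system"
  seed <- config$seed %||% 1
  if (gen == "titration_system") {
    g <- gen_titration_system(config$n_sites %||% 10, seed)
    .write_tsv(g$system$sites, file.path(out_dir, "sites.tsv"))
    utils::write.table(g$system$coupling, file.path(out_dir, "coupling.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    list(tables = list(), json = list(analysis = "simulate", generator = gen,
                                      seed = seed, n_sites = nrow(g$system$sites)))
  } else if (gen == "energy_table") {
    g <- gen_energy_table(seed)
    write_energy_table(g$table, file.path(out_dir, "energy_table.csv"))
    list(tables = list(), json = list(analysis = "simulate", generator = gen,
                                      seed = seed,
                                      planted = as.list(g$truth$barriers)))
  } else if (gen == "charges") {
    cs <- gen_charge_fixture(config$n_atoms %||% 50, seed)
    .write_tsv(as.data.frame(cs), file.path(out_dir, "charges.tsv"))
    list(tables = list(), json = list(analysis = "simulate", generator = gen,
                                      seed = seed, n_atoms = nrow(cs)))
  } else {
    stop("unknown generator: ", gen)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
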