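# Mechanism-state bookkeeping for the substrate--Asp274 proton system.
#
# Proton positions are named by the field's labels: the Asp274-origin proton
# sits on "Asp274" (donor), "C17" (correct delivery), "C18*" (wrong
# stereochemistry) or in flight ("Asp274...C17" / "Asp274...C18"); the
# propionate-origin proton on "Propionate", "C18", "C17*",
# "Propionate...C18" / "Propionate...C17". An in-flight label marks a
# proton-transfer transition state.

.ASP_LABELS <- c("Asp274", "C17", "C18*", "Asp274...C17", "Asp274...C18")
.PROP_LABELS <- c("Propionate", "C18", "C17*", "Propionate...C18",
                  "Propionate...C17")
.EPS_COLUMNS <- c(eps4 = 4, eps10 = 10, eps20 = 20, eps78 = 78.36)

# typographic -> ASCII: minus sign, bullets/ellipsis in transfer labels
.normalize_label <- function(x) {
  x <- gsub("−", "-", x)
  x <- gsub("•{3}|…", "...", x)
  gsub("\\s+", "", x)
}

.is_in_flight <- function(label) grepl("\\.\\.\\.", label)

#' Construct a mechanism state
#'
#' A mechanism state is one pattern of substrate reduction and protonation:
#' the number of added electrons (0-2), the position of the Asp274-origin
#' proton and the position of the propionate-origin proton. A state is a
#' transition state exactly when one proton is in flight
#' (a "donor...acceptor" label).
#'
#' @param electrons electrons added to the substrate, 0, 1 or 2
#' @param asp position of the Asp274-origin proton: one of
#'   "Asp274", "C17", "C18*", "Asp274...C17", "Asp274...C18"
#' @param prop position of the propionate-origin proton: one of
#'   "Propionate", "C18", "C17*", "Propionate...C18", "Propionate...C17"
#' @return an object of class \code{mechanism_state}
#' @examples
#' mechanism_state(1, "Asp274", "C18")
#' mechanism_state(0, "Asp274", "Propionate...C18") # a transition state
#' @export
mechanism_state <- function(electrons, asp, prop) {
  asp <- .normalize_label(asp)
  prop <- .normalize_label(prop)
  if (!(electrons %in% 0:2)) stop("electrons must be 0, 1 or 2")
  if (!(asp %in% .ASP_LABELS)) {
    stop("unknown Asp274-proton position label: '", asp, "'")
  }
  if (!(prop %in% .PROP_LABELS)) {
    stop("unknown propionate-proton position label: '", prop, "'")
  }
  asp_carbon <- switch(asp, "C17" = "C17", "C18*" = "C18", NA_character_)
  prop_carbon <- switch(prop, "C18" = "C18", "C17*" = "C17", NA_character_)
  if (!is.na(asp_carbon) && !is.na(prop_carbon) && asp_carbon == prop_carbon) {
    stop("both protons cannot occupy ring carbon ", asp_carbon)
  }
  n_flight <- .is_in_flight(asp) + .is_in_flight(prop)
  if (n_flight > 1) stop("at most one proton may be in flight")
  structure(
    list(electrons = as.integer(electrons), asp = asp, prop = prop,
         is_ts = n_flight == 1L),
    class = "mechanism_state"
  )
}

#' @export
print.mechanism_state <- function(x, ...) {
  cat(sprintf("<mechanism state: %d e-, H+ on %s / %s%s>\n",
              x$electrons, x$asp, x$prop,
              if (x$is_ts) " [transition state]" else ""))
  invisible(x)
}

#' @export
format.mechanism_state <- function(x, ...) {
  sprintf("%d/%s/%s", x$electrons, x$asp, x$prop)
}

.state_key <- function(electrons, asp, prop) {
  paste(electrons, .normalize_label(asp), .normalize_label(prop), sep = "/")
}

#' Read a relative-enthalpy table of mechanism states
#'
#' Reads a comma-separated table with header
#' \code{electrons,asp_proton,prop_proton,is_ts,eps4,eps10,eps20,eps78}
#' (any non-empty subset of the \code{eps*} energy columns is accepted).
#' Energies are relative enthalpies in kcal/mol; the dielectric constants
#' attached to the energy columns are 4, 10, 20 and 78.36. Typographic
#' minus signs and bullet ellipses in proton labels are normalized on load.
#'
#' Validation enforces: a reference state (0 electrons, both protons on
#' their donors, not a transition state) present with energy 0 in every
#' energy column; no duplicated states; numeric energies throughout; known
#' proton-position labels; and consistency of the \code{is_ts} flag with
#' in-flight proton labels.
#'
#' @param source path to a CSV file, or a connection
#' @return an object of class \code{energy_table}
#' @examples
#' tab <- read_energy_table(system.file("extdata", "table1.csv",
#'                                      package = "pcetr"))
#' tab
#' @export
read_energy_table <- function(source) {
  raw <- read.csv(source, stringsAsFactors = FALSE, check.names = TRUE,
                  colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("no reference state: table is empty")
  needed <- c("electrons", "asp_proton", "prop_proton", "is_ts")
  if (!all(needed %in% names(raw))) {
    stop("missing required columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  eps_cols <- intersect(names(.EPS_COLUMNS), names(raw))
  if (length(eps_cols) == 0) stop("no energy (eps*) columns found")

  states <- lapply(seq_len(nrow(raw)), function(i) {
    mechanism_state(as.integer(raw$electrons[i]), raw$asp_proton[i],
                    raw$prop_proton[i])
  })
  declared_ts <- toupper(trimws(raw$is_ts)) %in% c("TRUE", "T", "1")
  actual_ts <- vapply(states, `[[`, logical(1), "is_ts")
  if (!all(declared_ts == actual_ts)) {
    stop("is_ts flag inconsistent with in-flight proton labels at row(s) ",
         paste(which(declared_ts != actual_ts), collapse = ", "))
  }

  energies <- matrix(NA_real_, nrow(raw), length(eps_cols),
                     dimnames = list(NULL, eps_cols))
  for (cc in eps_cols) {
    vals <- suppressWarnings(as.numeric(.normalize_label(raw[[cc]])))
    if (anyNA(vals)) {
      stop("non-numeric energy cell in column ", cc, " at row(s) ",
           paste(which(is.na(vals)), collapse = ", "))
    }
    energies[, cc] <- vals
  }

  keys <- vapply(states, function(s) .state_key(s$electrons, s$asp, s$prop),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate state rows: ", paste(unique(keys[duplicated(keys)]),
                                         collapse = "; "))
  }

  ref_key <- .state_key(0L, "Asp274", "Propionate")
  ref_row <- match(ref_key, keys)
  if (is.na(ref_row)) {
    stop("no reference state (0 e-, Asp274, Propionate) in table")
  }
  if (any(energies[ref_row, ] != 0)) {
    stop("reference state must have energy 0 in every column")
  }

  tab <- data.frame(
    electrons = vapply(states, `[[`, integer(1), "electrons"),
    asp_proton = vapply(states, `[[`, character(1), "asp"),
    prop_proton = vapply(states, `[[`, character(1), "prop"),
    is_ts = actual_ts,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(energies))
  structure(tab,
            class = c("energy_table", "data.frame"),
            eps = .EPS_COLUMNS[eps_cols],
            key = keys,
            reference = ref_key)
}

#' Write an energy table back to CSV
#'
#' Inverse of [read_energy_table()]: reproduces every numeric cell exactly
#' (energies are stored at the precision they were read at and never
#' re-rounded).
#'
#' @param table an \code{energy_table}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_energy_table <- function(table, path) {
  stopifnot(inherits(table, "energy_table"))
  out <- as.data.frame(table)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.energy_table <- function(x, ...) {
  eps <- attr(x, "eps")
  cat(sprintf(
    "<energy table: %d mechanism states (%d transition states), dielectrics %s>\n",
    nrow(x), sum(x$is_ts), paste(eps, collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

.eps_column <- function(table, eps) {
  eps_map <- attr(table, "eps")
  hit <- which(abs(eps_map - eps) < 1e-9)
  if (length(hit) != 1) {
    stop("dielectric ", eps, " not tabulated (available: ",
         paste(eps_map, collapse = ", "), ")")
  }
  names(eps_map)[hit]
}

#' Look up the relative enthalpy of a mechanism state
#'
#' @param table an \code{energy_table}
#' @param state a \code{mechanism_state}, or the electron count when
#'   \code{asp}/\code{prop} labels are given instead
#' @param eps dielectric constant (one of those tabulated, e.g. 10)
#' @param asp,prop optional proton-position labels used with a numeric
#'   \code{state}
#' @return relative enthalpy in kcal/mol
#' @examples
#' tab <- read_energy_table(system.file("extdata", "table1.csv",
#'                                      package = "pcetr"))
#' state_energy(tab, mechanism_state(1, "Asp274", "C18"), eps = 10) # -73.9
#' @export
state_energy <- function(table, state, eps, asp = NULL, prop = NULL) {
  stopifnot(inherits(table, "energy_table"))
  if (!inherits(state, "mechanism_state")) {
    state <- mechanism_state(state, asp, prop)
  }
  key <- .state_key(state$electrons, state$asp, state$prop)
  row <- match(key, attr(table, "key"))
  if (is.na(row)) {
    stop("state not tabulated: ", key)
  }
  unname(table[row, .eps_column(table, eps)])
}

#' List the mechanism states of an energy table
#'
#' @param table an \code{energy_table}
#' @return a list of \code{mechanism_state} objects, in table order
#' @export
table_states <- function(table) {
  stopifnot(inherits(table, "energy_table"))
  lapply(seq_len(nrow(table)), function(i) {
    mechanism_state(table$electrons[i], table$asp_proton[i],
                    table$prop_proton[i])
  })
}

#' Read a cluster-complex energy table
#'
#' Reads the companion table of intermediates in the presence of the
#' independently optimized [4Fe-4S] cluster: relative energies with the
#' cluster reduced and oxidized, the cluster redox potential, and the
#' substrate redox potentials with reduced/oxidized/no cluster (all at one
#' dielectric). Cells that are not determined or not applicable are NA.
#'
#' @param source path to a CSV file
#' @return a data.frame of class \code{cluster_table}
#' @export
read_cluster_table <- function(source) {
  raw <- read.csv(source, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("electrons", "asp_proton", "prop_proton")
  if (!all(needed %in% names(raw))) {
    stop("missing required columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  raw$asp_proton <- .normalize_label(raw$asp_proton)
  raw$prop_proton <- .normalize_label(raw$prop_proton)
  class(raw) <- c("cluster_table", "data.frame")
  raw
}

#' Read a protein-embedded (ONIOM-corrected) relative-energy table
#'
#' Reads a table of intermediate energies computed with a protein
#' electrostatic embedding: columns \code{electrons, asp_proton,
#' prop_proton, energy} (kcal/mol, relative to the unreduced
#' doubly-protonated reference).
#'
#' @param source path to a CSV file
#' @return a data.frame of class \code{oniom_table}
#' @export
read_oniom_table <- function(source) {
  raw <- read.csv(source, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("electrons", "asp_proton", "prop_proton", "energy")
  if (!all(needed %in% names(raw))) {
    stop("missing required columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  raw$asp_proton <- .normalize_label(raw$asp_proton)
  raw$prop_proton <- .normalize_label(raw$prop_proton)
  if (!is.numeric(raw$energy)) stop("non-numeric energy column")
  class(raw) <- c("oniom_table", "data.frame")
  raw
}
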