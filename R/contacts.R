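# Residue-residue contact-energy analysis between named segment groups:
# interaction-type classification (hydrogen bond, salt bridge, hydrophobic,
# repulsive), energy binning at the printed display thresholds,
# state-to-state comparison, and net-energy aggregation per residue.

#' Contact-energy map between two segment groups
#'
#' One record per residue pair with interaction energy of magnitude at or
#' above the presence floor.  Reporting energies are computed without a
#' cutoff so the table does not depend on the truncation radius.
#'
#' @param model a \code{\link{state_model}} or \code{molecular_system}.
#' @param group_a,group_b character vectors of segment ids (or group labels,
#'   see \code{groups_as}); must not overlap.
#' @param presence_floor minimum |energy| (kcal/mol) for a pair to be
#'   recorded.
#' @param groups_as interpret the groups as segment ids (default) or
#'   segment-group labels.
#' @param opts \code{\link{nonbonded_options}} for reporting (default: no
#'   cutoff).
#' @param state_label state label stored on the records (taken from the
#'   model when available).
#' @return data.frame of class \code{contact_records}: segment_a, resid_a,
#'   resname_a, segment_b, resid_b, resname_b, E_lj, E_coul, energy, types
#'   (comma-joined), state.
#' @export
contact_map <- function(model, group_a, group_b, presence_floor = 0.4,
                        groups_as = c("segment", "group"),
                        opts = nonbonded_options(cutoff = Inf),
                        state_label = NULL) {
  groups_as <- match.arg(groups_as)
  sys <- if (inherits(model, "state_model")) model$system else model
  if (is.null(state_label))
    state_label <- if (inherits(model, "state_model")) model$state_label else
      "custom"
  if (length(intersect(group_a, group_b)))
    stop("contact groups overlap: ", paste(intersect(group_a, group_b),
                                           collapse = ", "))
  br <- nonbonded_energy(sys, opts, group_filter = list(group_a, group_b),
                         groups_as = groups_as, breakdown = TRUE)
  pp <- br$per_pair
  res <- sys$residues
  keep <- abs(pp$E_total) >= presence_floor
  pp <- pp[keep, , drop = FALSE]
  if (nrow(pp) == 0) {
    out <- data.frame(segment_a = character(), resid_a = integer(),
                      resname_a = character(), segment_b = character(),
                      resid_b = integer(), resname_b = character(),
                      E_lj = numeric(), E_coul = numeric(),
                      energy = numeric(), types = character(),
                      state = character())
    class(out) <- c("contact_records", "data.frame")
    return(out)
  }
  # orient records so side a is in group_a
  key <- if (groups_as == "segment") res$segment else res$group
  ina <- key[pp$rindex_i] %in% group_a
  ra <- ifelse(ina, pp$rindex_i, pp$rindex_j)
  rb <- ifelse(ina, pp$rindex_j, pp$rindex_i)
  types <- character(nrow(pp))
  for (k in seq_len(nrow(pp)))
    types[k] <- paste(classify_interaction(sys, ra[k], rb[k],
                                           E_lj = pp$E_lj[k],
                                           E_coul = pp$E_coul[k],
                                           energy = pp$E_total[k]),
                      collapse = ",")
  out <- data.frame(
    segment_a = res$segment[ra], resid_a = res$resid[ra],
    resname_a = res$resname[ra], segment_b = res$segment[rb],
    resid_b = res$resid[rb], resname_b = res$resname[rb],
    E_lj = pp$E_lj, E_coul = pp$E_coul, energy = pp$E_total,
    types = types, state = state_label)
  out <- out[order(out$energy), ]
  rownames(out) <- NULL
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Classify the interaction type of a residue pair
#'
#' Geometric criteria: a hydrogen bond requires donor-heavy to acceptor
#' distance at most 3.5 Angstrom with a donor-H-acceptor angle of at least
#' 120 degrees; a salt bridge requires opposite net formal charges with any
#' N/O - N/O atom pair within 4 Angstrom; a pair that is neither and whose
#' energy is dominated by the Lennard-Jones term is hydrophobic; a positive
#' total energy marks the contact repulsive.
#'
#' @param system a \code{molecular_system} (Cartesian cache is refreshed).
#' @param rindex_a,rindex_b residue indices.
#' @param E_lj,E_coul,energy energy components of the pair (computed if
#'   missing).
#' @param opts options used when energies must be computed.
#' @return character vector: subset of \code{c("h_bond", "salt_bridge",
#'   "hydrophobic", "repulsive")}.
#' @export
classify_interaction <- function(system, rindex_a, rindex_b, E_lj = NULL,
                                 E_coul = NULL, energy = NULL,
                                 opts = nonbonded_options(cutoff = Inf)) {
  if (is.null(E_lj) || is.null(E_coul) || is.null(energy)) {
    br <- nonbonded_energy(system, opts, breakdown = TRUE)
    pp <- br$per_pair
    row <- pp[(pp$rindex_i == rindex_a & pp$rindex_j == rindex_b) |
                (pp$rindex_i == rindex_b & pp$rindex_j == rindex_a), ]
    if (nrow(row) == 0) { E_lj <- 0; E_coul <- 0; energy <- 0 } else {
      E_lj <- row$E_lj[1]; E_coul <- row$E_coul[1]; energy <- row$E_total[1]
    }
  }
  xyz <- to_cartesian(system)
  at <- system$atoms
  ia <- which(at$rindex == rindex_a)
  ib <- which(at$rindex == rindex_b)
  types <- character(0)
  if (.has_hbond(xyz, at, ia, ib) || .has_hbond(xyz, at, ib, ia))
    types <- c(types, "h_bond")
  qa <- sum(at$formal[ia]); qb <- sum(at$formal[ib])
  if (qa * qb < 0) {
    pa <- ia[at$element[ia] %in% c("N", "O")]
    pb <- ib[at$element[ib] %in% c("N", "O")]
    if (length(pa) && length(pb)) {
      d2 <- outer(rowSums(xyz[pa, , drop = FALSE]^2),
                  rowSums(xyz[pb, , drop = FALSE]^2), "+") -
        2 * xyz[pa, , drop = FALSE] %*% t(xyz[pb, , drop = FALSE])
      if (min(d2) <= 16) types <- c(types, "salt_bridge")
    }
  }
  if (!length(types) && abs(E_lj) >= abs(E_coul))
    types <- c(types, "hydrophobic")
  if (energy > 0) types <- c(types, "repulsive")
  types
}

# donor side = residue `ia` (its polar hydrogens), acceptor side = `ib`
.has_hbond <- function(xyz, at, ia, ib) {
  hyd <- ia[at$element[ia] == "H"]
  acc <- ib[at$element[ib] %in% c("N", "O", "S")]
  if (!length(hyd) || !length(acc)) return(FALSE)
  for (h in hyd) {
    d <- at$parent[h]
    if (is.na(d) || !at$element[d] %in% c("N", "O", "S")) next
    for (a in acc) {
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > 3.5) next
      ang <- bond_angle(xyz[d, ], xyz[h, ], xyz[a, ])
      if (rad2deg(ang) >= 120) return(TRUE)
    }
  }
  FALSE
}

#' Display-binning schemes for contact energies
#'
#' Two printed schemes ship: \code{"fourbin"} (bins -0.9 to -1.5, -1.51 to
#' -3.0, -3.01 to -5.0, below -5.0, with a display floor hiding contacts
#' weaker than 0.9) and \code{"threebin"} (bins -0.5 to -2.5, -2.51 to
#' -5.0, below -5.0).  Printed two-decimal boundaries are interpreted as
#' half-open intervals, e.g. (-1.505, -0.895].
#'
#' @param name \code{"fourbin"} or \code{"threebin"}.
#' @return a \code{bin_scheme}: list with \code{breaks} (descending,
#'   half-open upper bounds), \code{labels} and \code{floor}.
#' @export
bin_scheme <- function(name = c("fourbin", "threebin")) {
  name <- match.arg(name)
  if (name == "fourbin") {
    structure(list(name = name,
                   breaks = c(-0.895, -1.505, -3.005, -5.005),
                   labels = c("dotted", "thin", "intermediate", "thick"),
                   floor = -0.395), class = "bin_scheme")
  } else {
    structure(list(name = name,
                   breaks = c(-0.495, -2.505, -5.005),
                   labels = c("thin", "intermediate", "thick"),
                   floor = -0.495), class = "bin_scheme")
  }
}

#' Assign display bins to contact records
#'
#' Every record gets exactly one bin label; energies above the scheme's
#' display floor are marked not-displayed but retained in the data.
#'
#' @param records a \code{contact_records} data.frame (or any data.frame
#'   with an \code{energy} column).
#' @param scheme a \code{\link{bin_scheme}}.
#' @return the records with added columns \code{bin} and \code{displayed}.
#' @export
bin_contacts <- function(records, scheme = bin_scheme("fourbin")) {
  e <- records$energy
  br <- scheme$breaks
  bin <- rep("not_shown", length(e))
  # descending half-open intervals: (br[k+1], br[k]]
  for (k in seq_along(br)) {
    lo <- if (k < length(br)) br[k + 1] else -Inf
    bin[e <= br[k] & e > lo] <- scheme$labels[k]
  }
  # weaker than the weakest displayed class but above the recording floor
  bin[e > br[1] & e <= scheme$floor] <- "below_floor"
  bin[e > 0] <- "repulsive"
  records$bin <- bin
  records$displayed <- bin %in% scheme$labels
  records
}

#' Compare contact maps across states
#'
#' @param maps list of \code{contact_records} (each carrying its state
#'   label, e.g. from models of the open and closed channel).
#' @return a \code{state_comparison} data.frame: one row per residue pair
#'   with per-state presence flags and a classification
#'   (\code{"only-<state>"}, \code{"shared-all"} or \code{"partial"}).
#' @export
compare_states <- function(maps) {
  if (length(maps) < 2 && length(maps) != 0)
    stop("state comparison needs at least two maps")
  if (!length(maps)) {
    out <- data.frame(pair = character(), classification = character())
    class(out) <- c("state_comparison", "data.frame")
    return(out)
  }
  states <- vapply(maps, function(m)
    if (nrow(m)) m$state[1] else NA_character_, character(1))
  if (anyNA(states))
    states[is.na(states)] <- paste0("state", which(is.na(states)))
  allrows <- list()
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    if (!nrow(m)) next
    allrows[[k]] <- data.frame(
      pair = paste0(m$segment_a, ":", m$resid_a, "|", m$segment_b, ":",
                    m$resid_b),
      state = states[k])
  }
  if (!length(allrows)) {
    out <- data.frame(pair = character(), classification = character())
    class(out) <- c("state_comparison", "data.frame")
    return(out)
  }
  long <- do.call(rbind, allrows)
  pairs <- sort(unique(long$pair))
  pres <- matrix(FALSE, length(pairs), length(states),
                 dimnames = list(pairs, states))
  for (i in seq_len(nrow(long))) pres[long$pair[i], long$state[i]] <- TRUE
  classification <- apply(pres, 1, function(p) {
    if (all(p)) "shared-all" else if (sum(p) == 1)
      paste0("only-", states[which(p)]) else "partial"
  })
  out <- data.frame(pair = pairs, classification = classification,
                    stringsAsFactors = FALSE)
  for (s in states) out[[paste0("in_", s)]] <- pres[, s]
  rownames(out) <- NULL
  class(out) <- c("state_comparison", "data.frame")
  out
}

#' Net intersegment contact energy of a residue in one state
#'
#' Arithmetic sum of a residue's recorded intersegment contact energies,
#' rounded to two decimals for reporting — the quantity printed in the
#' net-energy rows of the contact tables.
#'
#' @param x a \code{fixture_table} (then \code{residue} is the mutant id,
#'   e.g. \code{"G402S"}) or a \code{contact_records} data.frame (then
#'   \code{residue} is a residue number present on side a).
#' @param residue mutant id or residue number.
#' @param state state label (\code{"open"} / \code{"closed"} for the
#'   fixture).
#' @return net energy, kcal/mol (rounded to 2 decimals).
#' @export
aggregate_net_energy <- function(x, residue, state) {
  if (inherits(x, "fixture_table")) {
    rows <- x$rows
    if (!"mutant" %in% names(rows))
      stop("fixture has no mutant column; aggregation undefined")
    sel <- rows$mutant == residue & rows$state == state
    if (!any(sel)) stop("no fixture rows for ", residue, " in state ", state)
    return(round(sum(rows$energy[sel]), 2))
  }
  sel <- (x$resid_a == residue | x$resid_b == residue) & x$state == state
  if (!any(sel)) {
    if (!nrow(x)) return(0)
    stop("residue ", residue, " has no recorded contacts in state ", state)
  }
  round(sum(x$energy[sel]), 2)
}

#' Write contact records as TSV
#' @param records a \code{contact_records} data.frame.
#' @param path output file.
#' @export
write_contacts_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
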