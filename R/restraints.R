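# Flat-bottom parabolic restraints.
#
# All restraint flavours share one functional form: zero penalty inside a
# tolerance window, quadratic growth k * (deviation - width)^2 outside it.
# Pins tether alpha carbons to template positions; distance restraints are
# the same device applied to an interatomic distance interval; torsion
# windows confine backbone dihedrals near reference values; helix restraints
# impose alpha-helical O(i)..N(i+4) hydrogen-bond distances.

#' Flat-bottom parabolic penalty
#'
#' Zero for \code{deviation <= d}, \code{k * (deviation - d)^2} beyond;
#' continuous at the window edge.
#'
#' @param deviation non-negative deviation from the anchor (Angstrom or
#'   degrees, matching \code{k}).
#' @param d penalty-free half-width.
#' @param k force constant (kcal/mol per squared unit).
#' @return penalty energy, kcal/mol.
#' @export
pin_energy <- function(deviation, d = 1, k = 10) {
  if (any(deviation < 0)) stop("deviation must be non-negative")
  stopifnot(d >= 0, k > 0)
  over <- pmax(deviation - d, 0)
  k * over * over
}

# interval version: penalty when x < lower or x > upper
.window_energy <- function(x, lower, upper, k) {
  over <- pmax(x - upper, 0) + pmax(lower - x, 0)
  k * over * over
}

#' Construct a pin restraint
#'
#' @param atom atom index (alpha carbon).
#' @param anchor length-3 template position, Angstrom.
#' @param d penalty-free half-width, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @param label optional label for audit dumps.
#' @export
pin_restraint <- function(atom, anchor, d = 1, k = 10, label = "") {
  stopifnot(d >= 0, k > 0, length(anchor) == 3)
  structure(list(atom = as.integer(atom), anchor = as.numeric(anchor),
                 d = d, k = k, label = label), class = "pin_restraint")
}

#' Construct a distance restraint (flat-bottom on an interval)
#'
#' @param atom_a,atom_b atom indices.
#' @param lower,upper penalty-free distance interval, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @param label optional label.
#' @export
distance_restraint <- function(atom_a, atom_b, lower, upper, k = 10,
                               label = "") {
  stopifnot(lower <= upper, k > 0)
  structure(list(atom_a = as.integer(atom_a), atom_b = as.integer(atom_b),
                 lower = lower, upper = upper, k = k, label = label),
            class = "distance_restraint")
}

#' Construct a torsion window restraint
#'
#' Confines a named torsion to within \code{half_width} degrees of
#' \code{reference}.
#'
#' @param torsion torsion key.
#' @param reference reference angle, degrees.
#' @param half_width penalty-free half-width, degrees.
#' @param k force constant, kcal/mol/deg^2.
#' @export
torsion_window_restraint <- function(torsion, reference, half_width = 5,
                                     k = 0.1) {
  stopifnot(half_width >= 0, k > 0)
  structure(list(torsion = torsion, reference = reference,
                 half_width = half_width, k = k),
            class = "torsion_window_restraint")
}

#' Construct alpha-helical hydrogen-bond restraints for a residue range
#'
#' One flat-bottom distance restraint per (i, i+4) pair: carbonyl O of
#' residue i to amide N of residue i+4, target 3.0 +/- 0.3 Angstrom.
#'
#' @param system a \code{molecular_system}.
#' @param segment segment id.
#' @param resids residue numbers of the helical range (length >= 5).
#' @param target,half_width target O..N distance and penalty-free half-width,
#'   Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @return object of class \code{helix_restraint} holding the pair list.
#' @export
make_helix_restraints <- function(system, segment, resids, target = 3.0,
                                  half_width = 0.3, k = 10) {
  resids <- sort(resids)
  if (length(resids) < 5)
    stop("helical range must span at least 5 residues")
  pairs <- list()
  for (i in resids[resids + 4 <= max(resids)]) {
    o <- atom_index(system, segment, i, "O")
    nn <- atom_index(system, segment, i + 4, "N")
    pairs[[length(pairs) + 1L]] <- c(o, nn)
  }
  structure(list(pairs = do.call(rbind, pairs), target = target,
                 half_width = half_width, k = k, segment = segment,
                 resids = resids),
            class = "helix_restraint")
}

#' Build pins from template coordinates
#'
#' One pin per selected atom, anchored at the matching template coordinate.
#' Residues flagged unpinnable on the system (e.g. vicinal-disulfide
#' cysteines) are skipped.
#'
#' @param system a \code{molecular_system}.
#' @param template_coords matrix of template coordinates; either one row per
#'   selected atom, or one row per system atom (then rows are picked by the
#'   selection).
#' @param selection integer atom indices to pin (default: all alpha carbons).
#' @param d penalty-free half-width, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @param label label recorded on each pin.
#' @return list of \code{pin_restraint}.
#' @export
make_pins_from_template <- function(system, template_coords,
                                    selection = which(system$atoms$name == "CA"),
                                    d = 1, k = 10, label = "pin") {
  if (length(selection) == 0) return(list())
  if (nrow(template_coords) == nrow(system$atoms)) {
    anchors <- template_coords[selection, , drop = FALSE]
  } else if (nrow(template_coords) == length(selection)) {
    anchors <- template_coords
  } else {
    stop("template coordinates missing for ", length(selection) -
           nrow(template_coords), " selected atoms")
  }
  if (anyNA(anchors)) {
    orphans <- selection[rowSums(is.na(anchors)) > 0]
    stop("no template correspondence for atoms: ",
         paste(orphans, collapse = ", "))
  }
  skip <- system$atoms$rindex[selection] %in% system$unpinnable
  out <- list()
  for (k2 in seq_along(selection)) {
    if (skip[k2]) next
    out[[length(out) + 1L]] <- pin_restraint(selection[k2], anchors[k2, ],
                                             d = d, k = k, label = label)
  }
  out
}

#' Assemble a restraint set
#'
#' @param pins list of \code{pin_restraint}.
#' @param distances list of \code{distance_restraint}.
#' @param torsion_windows list of \code{torsion_window_restraint}.
#' @param helices list of \code{helix_restraint}.
#' @return a \code{restraint_set}.
#' @export
restraint_set <- function(pins = list(), distances = list(),
                          torsion_windows = list(), helices = list()) {
  structure(list(pins = pins, distances = distances,
                 torsion_windows = torsion_windows, helices = helices),
            class = "restraint_set")
}

#' Merge restraint sets
#' @param ... \code{restraint_set} objects.
#' @return combined \code{restraint_set}.
#' @export
merge_restraints <- function(...) {
  sets <- list(...)
  restraint_set(
    pins = do.call(c, lapply(sets, `[[`, "pins")),
    distances = do.call(c, lapply(sets, `[[`, "distances")),
    torsion_windows = do.call(c, lapply(sets, `[[`, "torsion_windows")),
    helices = do.call(c, lapply(sets, `[[`, "helices")))
}

#' Total restraint energy with per-restraint breakdown
#'
#' @param system a \code{molecular_system}.
#' @param set a \code{restraint_set}.
#' @param breakdown if TRUE, attach a per-restraint data.frame.
#' @return list with \code{total} (kcal/mol, always >= 0) and optionally
#'   \code{per_restraint}.
#' @export
restraint_energy <- function(system, set, breakdown = FALSE) {
  xyz <- to_cartesian(system)
  rows <- list()
  total <- 0
  add <- function(kind, label, e) {
    total <<- total + e
    if (breakdown)
      rows[[length(rows) + 1L]] <<- data.frame(kind = kind, label = label,
                                               energy = e)
  }
  for (p in set$pins) {
    dev <- sqrt(sum((xyz[p$atom, ] - p$anchor)^2))
    add("pin", paste0(p$label, "@", p$atom), pin_energy(dev, p$d, p$k))
  }
  for (dr in set$distances) {
    r <- sqrt(sum((xyz[dr$atom_a, ] - xyz[dr$atom_b, ])^2))
    add("distance", paste0(dr$label, ":", dr$atom_a, "-", dr$atom_b),
        .window_energy(r, dr$lower, dr$upper, dr$k))
  }
  for (tw in set$torsion_windows) {
    cur <- rad2deg(wrap_angle(system$torsions[[tw$torsion]]))
    dev <- abs(rad2deg(wrap_angle(deg2rad(cur - tw$reference))))
    add("torsion_window", tw$torsion, pin_energy(dev, tw$half_width, tw$k))
  }
  for (h in set$helices) {
    if (is.null(h$pairs)) next
    for (k2 in seq_len(nrow(h$pairs))) {
      r <- sqrt(sum((xyz[h$pairs[k2, 1], ] - xyz[h$pairs[k2, 2], ])^2))
      add("helix_hbond", paste0(h$segment, ":", k2),
          .window_energy(r, h$target - h$half_width, h$target + h$half_width,
                         h$k))
    }
  }
  out <- list(total = total)
  if (breakdown)
    out$per_restraint <- if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(), label = character(), energy = numeric())
  out
}

#' Dump a restraint set as a data.frame (auditable TSV-ready)
#' @param set a \code{restraint_set}.
#' @return data.frame with one row per restraint.
#' @export
restraint_table <- function(set) {
  rows <- list()
  for (p in set$pins)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "pin", label = p$label, atom_a = p$atom, atom_b = NA,
      lower = NA, upper = p$d, k = p$k,
      anchor = paste(sprintf("%.3f", p$anchor), collapse = ","))
  for (d in set$distances)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "distance", label = d$label, atom_a = d$atom_a, atom_b = d$atom_b,
      lower = d$lower, upper = d$upper, k = d$k, anchor = "")
  for (tw in set$torsion_windows)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "torsion_window", label = tw$torsion, atom_a = NA, atom_b = NA,
      lower = tw$reference - tw$half_width,
      upper = tw$reference + tw$half_width, k = tw$k, anchor = "")
  for (h in set$helices)
    for (k2 in seq_len(nrow(h$pairs)))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "helix_hbond", label = h$segment, atom_a = h$pairs[k2, 1],
        atom_b = h$pairs[k2, 2], lower = h$target - h$half_width,
        upper = h$target + h$half_width, k = h$k, anchor = "")
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Number of restraints in a set
#' @param set a \code{restraint_set}.
#' @export
n_restraints <- function(set) {
  length(set$pins) + length(set$distances) + length(set$torsion_windows) +
    sum(vapply(set$helices, function(h) nrow(h$pairs), integer(1)))
}
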