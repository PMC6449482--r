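# Deterministic synthetic toy channel.
#
# A pseudo-4-fold helix bundle that emulates, at desk scale, the
# architecture relevant to gating-brake modelling: four outer helices (S5
# ring, structurally conserved between states), four inner gate helices (S6)
# whose C-terminal alpha-carbon ring sets the gate radius (open vs closed),
# an amphipathic AID-like helix resting in the groove of a two-helix
# "bedplate" (the Cavbeta stand-in) with its hydrophobic face toward the
# plate, and a short S0-like sensor helix carrying arginines whose polar
# face looks at the AID glutamine — a stand-in for the R518:Q443 contact.
# The two states differ only in the placement of the S6 helices (gate), the
# AID (slid along its own axis) and the sensor helix (shifted normal to its
# axis); the S5 ring and bedplate are identical, so the structurally
# conserved part of the channel carries exact atom correspondences.

.toy_seqs <- function(spec) {
  pad <- function(x, n) rep(x, length.out = n)
  list(
    s5 = pad(c("ALA", "ALA", "ALA", "VAL", "ALA", "ALA", "ALA", "ALA",
               "ALA", "ALA", "ALA", "ALA"), spec$s5_len),
    s6 = pad(c("ALA", "ALA", "LEU", "ALA", "ALA", "ALA", "GLY", "GLY",
               "GLY", "ALA", "GLY", "GLY"), spec$s6_len),
    aid = pad(c("ALA", "LEU", "ALA", "LEU", "GLN", "ALA", "LEU", "ALA",
                "ARG", "ALA", "LEU", "ALA"), spec$aid_len),
    bp = pad(rep("ALA", 10), spec$bp_len),
    iis0 = pad(c("ALA", "ARG", "ALA", "ALA", "ARG", "ALA", "ALA", "ALA"),
               spec$iis0_len))
}

#' Parametric description of the synthetic toy channel
#'
#' @param n_repeats number of pseudo-symmetric repeats (4).
#' @param s5_len,s6_len outer / inner helix lengths, residues.
#' @param open_radius,closed_radius gate radius: radial distance of the
#'   C-terminal S6 alpha carbon from the pore axis, Angstrom.
#' @param aid_len,bp_len,iis0_len lengths of the AID-like helix, each
#'   bedplate helix, and the sensor (S0-like) helix.
#' @param aid_polar_resids positions (1-based within AID) of the polar-face
#'   glutamine and arginine.
#' @param seed RNG seed recorded with the spec (generation itself is
#'   deterministic; the seed feeds derived generators).
#' @return a \code{toy_channel_spec}.
#' @export
toy_channel_spec <- function(n_repeats = 4, s5_len = 12, s6_len = 12,
                             open_radius = 6.0, closed_radius = 2.5,
                             aid_len = 12, bp_len = 10, iis0_len = 8,
                             aid_polar_resids = c(5, 9), seed = 1) {
  if (!(open_radius > closed_radius && closed_radius > 0))
    stop("need open_radius > closed_radius > 0")
  structure(as.list(environment()), class = "toy_channel_spec")
}

# rotation taking unit vector a to unit vector b
.rot_a_to_b <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- vnorm(v); cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) unit(cross3(a, c(1, 0, 0))) else
      unit(cross3(a, c(0, 1, 0)))
    return(axis_rot(p, pi))
  }
  axis_rot(v / s, atan2(s, cc))
}

# set ideal alpha-helical backbone torsions on a whole segment
.make_helical <- function(system, seg) {
  keys <- names(system$torsions)
  mine <- keys[startsWith(keys, paste0(seg, ":"))]
  phi <- mine[endsWith(mine, ":phi")]
  psi <- mine[endsWith(mine, ":psi")]
  vals <- c(stats::setNames(rep(-57, length(phi)), phi),
            stats::setNames(rep(-47, length(psi)), psi))
  set_torsions(system, vals)
}

# local-frame CA coordinates and fitted helix axis of a segment
.helix_local <- function(system, seg) {
  xyzl <- .build_segment_local(system, seg)
  rows <- .seg_atoms(system, seg)
  ca <- xyzl[system$atoms$name[rows] == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  u <- sv$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * u) < 0) u <- -u
  list(ca = ca, axis = u, center = ctr)
}

# place a helical segment so its fitted axis runs along `direction` and a
# chosen CA (anchor_index, 1 = first, n = last) lands on `anchor_point`;
# `roll` (radians) spins the helix about its own axis
.place_helix <- function(system, seg, direction, anchor_point,
                         anchor = c("first", "last"), roll = 0) {
  anchor <- match.arg(anchor)
  hl <- .helix_local(system, seg)
  R <- .rot_a_to_b(hl$axis, direction)
  R <- axis_rot(unit(direction), roll) %*% R
  ca_ref <- if (anchor == "first") hl$ca[1, ] else hl$ca[nrow(hl$ca), ]
  pos <- as.numeric(anchor_point - R %*% ca_ref)
  system <- .set_root_rad(system, seg, pos, rot_to_euler(R))
  system
}

# choose the roll that points the CA->CB vectors of the given residues as
# much as possible along `face` (world frame); deterministic scan
.face_roll <- function(system, seg, resids, direction, anchor_point, anchor,
                       face) {
  best <- 0; bestv <- -Inf
  for (roll in seq(0, 350, by = 10) * DEG) {
    s2 <- .place_helix(system, seg, direction, anchor_point, anchor, roll)
    xyz <- to_cartesian(s2)
    v <- 0
    for (r in resids) {
      ca <- xyz[atom_index(s2, seg, r, "CA"), ]
      cb <- xyz[atom_index(s2, seg, r, "CB"), ]
      v <- v + sum(unit(cb - ca) * face)
    }
    if (v > bestv) { bestv <- v; best <- roll }
  }
  best
}

.toy_mobile_segments <- function(spec)
  c(paste0("S6.", seq_len(spec$n_repeats)), "AID", "IIS0")

# gate anchor points of the S6 helices for a given gate radius
.toy_gate_points <- function(spec, r_gate) {
  aid_shift <- spec$open_radius - r_gate
  swirl <- deg2rad(20) * aid_shift / (spec$open_radius - spec$closed_radius)
  out <- list()
  for (m in seq_len(spec$n_repeats)) {
    th <- (m - 1) * 2 * pi / spec$n_repeats
    # alternate repeats end on slightly staggered planes so the terminal
    # carbonyls of the tight closed bundle interdigitate instead of colliding
    zg <- 1.2 * ((m - 1) %% 2)
    out[[m]] <- list(
      top = c(12 * cos(th), 12 * sin(th), 16),
      gate = c(r_gate * cos(th + swirl), r_gate * sin(th + swirl), zg))
  }
  out
}


# mechanism frame: u = direction of the repeat-1 gate displacement upon
# opening (the AID slide axis, pointing away from the pore), v = in-plane
# perpendicular (the groove's lateral direction)
.toy_frame <- function(spec) {
  g_open <- .toy_gate_points(spec, spec$open_radius)[[1]]$gate
  g_closed <- .toy_gate_points(spec, spec$closed_radius)[[1]]$gate
  slide <- g_open - g_closed
  u <- unit(c(slide[1], slide[2], 0))
  list(u = u, v = c(-u[2], u[1], 0), slide = slide,
       gate_open = g_open, gate_closed = g_closed)
}

# analytic placement of the state-dependent segments (S6 bundle, AID,
# sensor) for a given gate radius, followed by deterministic detangling
# state-definition pins: the AID and sensor helices are held near their
# analytic placement (first/middle/last alpha carbon, generous windows)
# during the canonical relaxation, so each state's pose is the designed one
# relaxed locally rather than an arbitrary nearby basin
.toy_definition_pins <- function(sys, spec, d = 0.5, k = 50) {
  xyz <- to_cartesian(sys)
  pins <- list()
  segs <- list(c("AID", 501L, spec$aid_len),
               c("IIS0", 701L, spec$iis0_len),
               c("BP1", 601L, spec$bp_len),
               c("BP2", 651L, spec$bp_len))
  for (m in seq_len(spec$n_repeats)) {
    segs[[length(segs) + 1L]] <- c(paste0("S5.", m), 100L * m + 1L,
                                   spec$s5_len)
    segs[[length(segs) + 1L]] <- c(paste0("S6.", m), 100L * m + 51L,
                                   spec$s6_len)
  }
  for (sg in segs) {
    n <- as.integer(sg[3])
    for (p in unique(c(1L, (n + 1L) %/% 2L, n))) {
      i <- atom_index(sys, sg[1], as.integer(sg[2]) + p - 1L, "CA")
      pins[[length(pins) + 1L]] <- pin_restraint(i, xyz[i, ], d = d, k = k,
                                                 label = "state definition")
    }
  }
  restraint_set(pins = pins)
}

.toy_place_mobile <- function(sys, spec, r_gate, rolls = NULL) {
  sq <- .toy_seqs(spec)
  aid_shift <- spec$open_radius - r_gate  # AID slides inward as the gate closes
  gp <- .toy_gate_points(spec, r_gate)
  for (m in seq_len(spec$n_repeats)) {
    # S6: tilted inward; C-terminal CA exactly on the gate ring
    sys <- .place_helix(sys, paste0("S6.", m),
                        unit(gp[[m]]$gate - gp[[m]]$top), gp[[m]]$gate, "last")
  }
  # spin each gate helix about its own axis to the least-overlapping roll
  # (the anchored C-terminal alpha carbon is roll-invariant); rolls chosen
  # once (open state) and reused so the states differ by near-rigid motions
  if (is.null(rolls$s6)) {
    rolls$s6 <- numeric(spec$n_repeats)
    for (m in seq_len(spec$n_repeats)) {
      rolls$s6[m] <- .best_roll(sys, paste0("S6.", m),
                                unit(gp[[m]]$gate - gp[[m]]$top),
                                gp[[m]]$gate, "last")
      sys <- .place_helix(sys, paste0("S6.", m),
                          unit(gp[[m]]$gate - gp[[m]]$top), gp[[m]]$gate,
                          "last", rolls$s6[m])
    }
  } else {
    for (m in seq_len(spec$n_repeats)) {
      sys <- .place_helix(sys, paste0("S6.", m),
                          unit(gp[[m]]$gate - gp[[m]]$top), gp[[m]]$gate,
                          "last", rolls$s6[m])
    }
  }
  # AID: its axis runs along the gate-displacement direction u so the pull
  # of the closing gate is purely axial; polar face (GLN/ARG) up toward the
  # sensor.  Roll angles are chosen once (open state) and reused for the
  # closed state so the two states differ by a pure slide along the axis.
  fr <- .toy_frame(spec)
  gp1 <- gp[[1]]$gate
  aid_start <- c(gp1[1], gp1[2], 0) + 2.0 * fr$u + c(0, 0, -7)
  if (is.null(rolls$aid))
    rolls$aid <- .face_roll(sys, "AID", 500L + spec$aid_polar_resids,
                            fr$u, aid_start, "first", c(0, 0, 1))
  sys <- .place_helix(sys, "AID", fr$u, aid_start, "first", rolls$aid)
  # sensor helix: perpendicular to AID, above it, arginines facing down;
  # follows the AID slide (a displacement normal to the sensor's own axis)
  arg_pos <- 700L + which(sq$iis0 == "ARG")
  iis0_start <- aid_start + 8.5 * fr$u - 5.3 * fr$v + c(0, 0, 12.5)
  if (is.null(rolls$iis0))
    rolls$iis0 <- .face_roll(sys, "IIS0", arg_pos, fr$v, iis0_start,
                             "first", c(0, 0, -1))
  sys <- .place_helix(sys, "IIS0", fr$v, iis0_start, "first",
                      rolls$iis0)
  sys <- .detangle_sidechains(sys, .toy_mobile_segments(spec))
  attr(sys, "toy_rolls") <- rolls
  sys
}

# the toy scaffold: loop connectivity + turret anchors + gate-ring pins at
# the state's nominal gate points; built once per state and reused verbatim
# by every stage so the canonical conformation is a minimum of exactly this
# restrained landscape
.toy_standing <- function(sys, spec, r_gate) {
  attr(sys, "toy_spec") <- spec
  attr(sys, "toy_restraints") <- NULL
  rs <- toy_connectivity_restraints(sys, gate_pins = FALSE, spec = spec)
  gp <- .toy_gate_points(spec, r_gate)
  pins <- list()
  for (m in seq_len(spec$n_repeats)) {
    ca <- atom_index(sys, paste0("S6.", m), 100L * m + 50L + spec$s6_len, "CA")
    pins[[m]] <- pin_restraint(ca, gp[[m]]$gate, d = 0.02, k = 800,
                               label = "gate scaffold")
  }
  merge_restraints(rs, restraint_set(pins = pins))
}

# deterministic canonical relaxation: rigid-body roots plus backbone and
# sidechain torsions of the given segments, under the standing scaffold.
# `bb_reference` (named degrees) adds 5-degree backbone torsion windows so a
# derived state stays helix-compatible with its parent state.
.toy_relax <- function(sys, spec, segments, r_gate, max_iter = 60,
                       bb_reference = NULL) {
  rs <- .toy_standing(sys, spec, r_gate)
  rs <- merge_restraints(rs, .toy_definition_pins(sys, spec))
  if (!is.null(bb_reference)) {
    tw <- lapply(names(bb_reference), function(k)
      torsion_window_restraint(k, unname(bb_reference[k]), 5, 0.5))
    rs <- merge_restraints(rs, restraint_set(torsion_windows = tw))
  }
  ridx <- which(sys$residues$segment %in% segments)
  tors <- residue_torsions(sys, ridx, classes = c("chi", "backbone"))
  rsys <- set_flexible(sys, torsions = tors, roots = segments)
  # iterate to approximate convergence so the canonical state is a local
  # minimum of the restrained landscape
  fit <- local_minimize(rsys, rs, max_iter)
  for (pass in 1:9) {
    nxt <- local_minimize(fit$system, rs, max_iter)
    done <- fit$energy - nxt$energy < 0.5
    fit <- nxt
    if (done) break
  }
  out <- fit$system
  # focused gate-tightening: with only the gate helices flexible, the
  # scaffold pins dominate and pull the ring onto its nominal radius
  s6 <- paste0("S6.", seq_len(spec$n_repeats))
  gp <- .toy_gate_points(spec, r_gate)
  gate_dev <- function(s) {
    x <- to_cartesian(s)
    max(vapply(seq_len(spec$n_repeats), function(m) {
      i <- atom_index(s, s6[m], 100L * m + 50L + spec$s6_len, "CA")
      vnorm(x[i, ] - gp[[m]]$gate)
    }, numeric(1)))
  }
  for (tries in 1:3) {
    if (gate_dev(out) < 0.08) break
    s6res <- which(out$residues$segment %in% s6)
    s6t <- residue_torsions(out, s6res, classes = c("chi", "backbone"))
    foc <- set_flexible(out, torsions = s6t, roots = s6)
    out <- local_minimize(foc, rs, 2L * max_iter)$system
  }
  # final snap: rigidly translate each gate helix so its C-terminal alpha
  # carbon sits exactly on the nominal gate point (sub-0.2 A corrections)
  x <- to_cartesian(out)
  for (m in seq_len(spec$n_repeats)) {
    i <- atom_index(out, s6[m], 100L * m + 50L + spec$s6_len, "CA")
    err <- gp[[m]]$gate - x[i, ]
    out <- set_root(out, s6[m], pos = out$roots[[s6[m]]]$pos + err)
  }
  # restore the build-time default flexibility mask
  out$torsion_flexible[] <- out$torsion_class != "omega"
  out$root_flexible[] <- TRUE
  attr(out, "toy_restraints") <- merge_restraints(
    .toy_standing(out, spec, r_gate), .toy_definition_pins(out, spec))
  out
}

.toy_cache <- new.env(parent = emptyenv())

#' Generate the synthetic toy channel in one state
#'
#' Pure function of (spec, state): the same spec always yields bit-identical
#' systems, and the open/closed systems share an identical atom ordering
#' (the atom correspondence between states is the identity).  Construction
#' is analytic placement of ideal helices followed by a deterministic
#' canonical relaxation (rigid-body roots and sidechains, under the loop
#' connectivity restraints, with the gate ring pinned on its exact radius)
#' so each state is a locally stable conformation.  The closed state is
#' derived from the relaxed open state by re-placing only the
#' state-dependent segments (S6 bundle, AID, sensor) and relaxing them in
#' the frozen field of the conserved S5 ring and bedplate, which therefore
#' stay bit-identical across states.  Results are memoized per (spec,
#' state).
#'
#' @param spec a \code{\link{toy_channel_spec}}.
#' @param state \code{"open"} or \code{"closed"}.
#' @return a \code{molecular_system} with attributes \code{toy_state} and
#'   \code{toy_spec}.
#' @export
generate_toy_channel <- function(spec = toy_channel_spec(),
                                 state = c("open", "closed")) {
  state <- match.arg(state)
  key <- paste(c(unlist(spec, use.names = TRUE), state), collapse = "|")
  if (!is.null(.toy_cache[[key]])) return(.cow(.toy_cache[[key]]))

  open_key <- paste(c(unlist(spec, use.names = TRUE), "open"), collapse = "|")
  if (is.null(.toy_cache[[open_key]])) {
    sq <- .toy_seqs(spec)
    segs <- list()
    for (m in seq_len(spec$n_repeats)) {
      segs[[length(segs) + 1L]] <- segment_spec(paste0("S5.", m), sq$s5,
                                                100L * m + 1L)
      segs[[length(segs) + 1L]] <- segment_spec(paste0("S6.", m), sq$s6,
                                                100L * m + 51L)
    }
    segs[[length(segs) + 1L]] <- segment_spec("AID", sq$aid, 501L)
    segs[[length(segs) + 1L]] <- segment_spec("BP1", sq$bp, 601L,
                                              group = "beta_subunit")
    segs[[length(segs) + 1L]] <- segment_spec("BP2", sq$bp, 651L,
                                              group = "beta_subunit")
    segs[[length(segs) + 1L]] <- segment_spec("IIS0", sq$iis0, 701L,
                                              group = "other")
    sys <- build_system(segs)
    for (sg in names(sys$roots)) sys <- .make_helical(sys, sg)
    # S5 ring and bedplate: placed once, conserved across states
    for (m in seq_len(spec$n_repeats)) {
      th5 <- (m - 1) * 2 * pi / spec$n_repeats + pi / spec$n_repeats
      sys <- .place_helix(sys, paste0("S5.", m), c(0, 0, 1),
                          c(15 * cos(th5), 15 * sin(th5), 2), "first")
    }
    fr0 <- .toy_frame(spec)
    gp1o <- .toy_gate_points(spec, spec$open_radius)[[1]]$gate
    aid0 <- c(gp1o[1], gp1o[2], 0) + 2.0 * fr0$u + c(0, 0, -7)
    for (k in 1:2) {
      side <- c(-4.8, 4.8)[k]
      st <- aid0 - 4.5 * fr0$u + side * fr0$v + c(0, 0, -3.5)
      leus <- 600L + 50L * (k - 1L) + which(.toy_seqs(spec)$bp == "LEU")
      # groove face: up and inward, toward the AID axis
      face <- unit(-side * fr0$v + c(0, 0, 3.2))
      rl <- .face_roll(sys, paste0("BP", k), leus, fr0$u, st, "first", face)
      sys <- .place_helix(sys, paste0("BP", k), fr0$u, st, "first", rl)
    }
    sys <- .toy_place_mobile(sys, spec, spec$open_radius)
    rolls <- attr(sys, "toy_rolls")
    mob_res0 <- which(sys$residues$segment %in%
                        c(.toy_mobile_segments(spec), "BP1", "BP2"))
    bb0 <- residue_torsions(sys, mob_res0, classes = "backbone")
    sys <- .toy_relax(sys, spec, names(sys$roots), spec$open_radius,
                      bb_reference = get_torsions(sys, bb0))
    attr(sys, "toy_rolls") <- rolls
    attr(sys, "toy_state") <- "open"
    attr(sys, "toy_spec") <- spec
    .toy_cache[[open_key]] <- sys
  }
  if (state == "open") return(.cow(.toy_cache[[open_key]]))

  sys <- .cow(.toy_cache[[open_key]])
  open_sys <- .toy_cache[[open_key]]
  mobile <- .toy_mobile_segments(spec)
  mob_res <- which(open_sys$residues$segment %in% mobile)
  bb_keys <- residue_torsions(open_sys, mob_res, classes = "backbone")
  bb_ref <- get_torsions(open_sys, bb_keys)
  sys <- .toy_place_mobile(sys, spec, spec$closed_radius,
                           rolls = attr(sys, "toy_rolls"))
  sys <- .toy_relax(sys, spec, mobile, spec$closed_radius,
                    bb_reference = bb_ref)
  attr(sys, "toy_state") <- "closed"
  attr(sys, "toy_spec") <- spec
  .toy_cache[[key]] <- sys
  .cow(sys)
}

# deterministic roll scan: place a helix at every 10-degree roll and return
# the roll with the smallest soft-overlap score against the rest of the
# system
.best_roll <- function(system, seg, direction, anchor_point, anchor) {
  rows <- .seg_atoms(system, seg)
  best <- 0; bestv <- Inf
  for (roll in seq(0, 350, by = 10) * DEG) {
    s2 <- .place_helix(system, seg, direction, anchor_point, anchor, roll)
    x <- to_cartesian(s2)
    other <- setdiff(seq_len(nrow(system$atoms)), rows)
    dd <- sqrt(pmax(outer(rowSums(x[rows, , drop = FALSE]^2),
                          rowSums(x[other, , drop = FALSE]^2), "+") -
                      2 * x[rows, , drop = FALSE] %*%
                      t(x[other, , drop = FALSE]), 1e-12))
    v <- sum((3.2 / pmin(dd, 3.2))^12)
    if (v < bestv - 1e-9) { bestv <- v; best <- roll }
  }
  best
}

# greedy deterministic clash relief: for residues of the given segments that
# make short inter-segment contacts, scan each chi torsion over a fixed grid
# and keep the value minimizing a soft repulsive overlap score
.detangle_sidechains <- function(system, segments, threshold = 2.6,
                                 sweeps = 3) {
  grid <- seq(-180, 150, by = 30)
  at <- system$atoms
  for (sw in seq_len(sweeps)) {
    xyz <- to_cartesian(system)
    D <- as.matrix(stats::dist(xyz)); diag(D) <- Inf
    inter <- outer(at$segment, at$segment, "!=")
    clash <- which(D < threshold & inter, arr.ind = TRUE)
    if (nrow(clash) == 0) break
    rids <- unique(at$rindex[clash[, 1]])
    rids <- rids[system$residues$segment[rids] %in% segments]
    if (length(rids) == 0) break
    score <- function(sys, rows) {
      x <- to_cartesian(sys)
      other <- setdiff(seq_len(nrow(at)), rows)
      dd <- sqrt(pmax(outer(rowSums(x[rows, , drop = FALSE]^2),
                            rowSums(x[other, , drop = FALSE]^2), "+") -
                        2 * x[rows, , drop = FALSE] %*%
                        t(x[other, , drop = FALSE]), 1e-12))
      sum((3.2 / pmin(dd, 3.2))^12)
    }
    for (ri in sort(rids)) {
      chis <- residue_torsions(system, ri, classes = "chi")
      if (!length(chis)) next
      rows <- which(at$rindex == ri)
      for (ch in chis) {
        best <- system$torsions[[ch]]; bestv <- Inf
        for (g in grid) {
          cand <- .set_torsions_rad(system, ch, deg2rad(g))
          v <- score(cand, rows)
          if (v < bestv - 1e-9) { bestv <- v; best <- deg2rad(g) }
        }
        system <- .set_torsions_rad(system, ch, best)
      }
    }
  }
  system
}

#' Atom correspondence between two states of the same toy spec
#'
#' @param spec a \code{\link{toy_channel_spec}}.
#' @return data.frame with one row per atom: segment, resid, name and the
#'   (identical) atom index in either state.
#' @export
toy_correspondence <- function(spec = toy_channel_spec()) {
  s <- generate_toy_channel(spec, "open")
  data.frame(index = s$atoms$idx, segment = s$atoms$segment,
             resid = s$atoms$resid, name = s$atoms$name)
}

#' Label map for the toy channel (o = S5, i = S6)
#' @param spec a \code{\link{toy_channel_spec}}.
#' @return a \code{label_map} with a \code{segment_id} column.
#' @export
toy_label_map <- function(spec = toy_channel_spec()) {
  rows <- list()
  for (m in seq_len(spec$n_repeats)) {
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_ = m, segment = "o", index_origin = 1L,
      index_max = spec$s5_len, anchor_resid = 100L * m + 1L,
      segment_id = paste0("S5.", m))
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_ = m, segment = "i", index_origin = 1L,
      index_max = spec$s6_len, anchor_resid = 100L * m + 51L,
      segment_id = paste0("S6.", m))
  }
  as_label_map(do.call(rbind, rows))
}

#' Generate a template/model pair with sequence mismatches
#'
#' Starts from the toy template and substitutes \code{n_substitutions}
#' randomly chosen residues in the model sequence, producing the alignment
#' (template map) with mismatches flagged — the input expected by the
#' homology threading stage.
#'
#' @param spec a \code{\link{toy_channel_spec}}.
#' @param n_substitutions number of substituted positions.
#' @param seed RNG seed (sites differ across seeds).
#' @param state template state.
#' @return list with \code{template} (system), \code{model_segments} (list
#'   of \code{segment_spec}) and \code{map} (a \code{template_map}).
#' @export
generate_mismatched_sequence <- function(spec = toy_channel_spec(),
                                         n_substitutions = 0, seed = 1,
                                         state = "open") {
  template <- generate_toy_channel(spec, state)
  res <- template$residues
  if (n_substitutions > nrow(res))
    stop("more substitutions than residues")
  set.seed(seed)
  subs <- if (n_substitutions > 0)
    sort(sample.int(nrow(res), n_substitutions)) else integer(0)
  menu <- c(ALA = "SER", LEU = "MET", VAL = "THR", ILE = "LEU", GLY = "ALA",
            GLN = "GLU", ARG = "LYS", SER = "ALA", THR = "VAL", MET = "LEU")
  model_res <- res$resname
  for (i in subs) model_res[i] <- unname(menu[res$resname[i]])
  specs <- list()
  for (sid in unique(res$segment)) {
    rr <- which(res$segment == sid)
    specs[[sid]] <- segment_spec(sid, model_res[rr], res$resid[rr[1]],
                                 res$group[rr[1]])
  }
  map <- template_map(model_rindex = seq_len(nrow(res)),
                      template_rindex = seq_len(nrow(res)),
                      match = model_res == res$resname)
  list(template = template, model_segments = specs, map = map)
}

# locate a packaged data file, falling back to the source tree during
# development
.pkg_file <- function(...) {
  p <- system.file("extdata", ..., package = "channelmcm")
  if (nzchar(p)) p else file.path("inst", "extdata", ...)
}

#' Machine-readable transcriptions of the printed contact-energy tables
#'
#' Verbatim transcriptions (signs and blanks preserved) of the three printed
#' tables of state-dependent intersegment contact energies: \code{"table2"}
#' (R518C contacts, reduced vs vicinal-disulfide cysteines),
#' \code{"table3"} (R518H contacts by histidine tautomer) and
#' \code{"table4"} (G402S / G406R contacts in closed and open states).  For
#' table 4 the printed net-energy row is stored separately from the row
#' data, including its annotation: the printed open-state net energy for
#' G406R (-4.98) does not equal the sum of that column's printed entries
#' (-4.89); the transcription records the discrepancy rather than
#' reconciling it.
#'
#' @param table_id \code{"table2"}, \code{"table3"} or \code{"table4"}.
#' @return a \code{fixture_table}: list with \code{id}, \code{rows}
#'   (data.frame), and for table 4 \code{sigma_printed} plus \code{note}.
#' @export
table_fixture <- function(table_id) {
  if (!table_id %in% c("table2", "table3", "table4"))
    stop("unknown fixture table: ", table_id)
  rows <- utils::read.delim(.pkg_file(paste0(table_id, ".tsv")),
                            stringsAsFactors = FALSE)
  out <- list(id = table_id, rows = rows)
  if (table_id == "table4") {
    sg <- utils::read.delim(.pkg_file("table4_sigma.tsv"),
                            stringsAsFactors = FALSE)
    out$sigma_printed <- stats::setNames(sg$energy,
                                         paste(sg$mutant, sg$state, sep = "_"))
    out$note <- paste("printed sigma for G406R/open (-4.98) differs from the",
                      "sum of the printed column entries (-4.89)")
  }
  structure(out, class = "fixture_table")
}

#' Standing restraints of the toy channel: loop connectivity and turret
#' anchors
#'
#' The toy channel represents each helix as a free segment; the covalent
#' loops that join them in a real channel, the pore-turret ring and the
#' membrane are not modeled.  Two stand-ins are therefore part of the toy
#' system itself and applied in every optimization stage, playing the role
#' bonded terms would play: flat-bottom distance restraints between
#' consecutive segment termini (S5 to S6 within each repeat via the re-
#' entrant loop, and the gate helix of repeat 1 to the AID-like helix), and
#' wide flat-bottom pins on the extracellular-end alpha carbon of each
#' transmembrane helix (the structurally conserved extracellular third).
#'
#' @param system a generated toy channel.
#' @param slack penalty-free half-width around the generated terminus
#'   distance, Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @return a \code{restraint_set} of distance restraints.
#' @export
toy_connectivity_restraints <- function(system, slack = 0.5, k = 10,
                                        turret_d = 0.75, turret_k = 10,
                                        gate_pins = TRUE,
                                        spec = attr(system, "toy_spec")) {
  pre <- attr(system, "toy_restraints")
  if (!is.null(pre) && gate_pins) return(pre)
  if (is.null(spec)) stop("not a generated toy channel")
  xyz <- to_cartesian(system)
  link <- function(seg_a, resid_a, seg_b, resid_b, label) {
    a <- atom_index(system, seg_a, resid_a, "C")
    b <- atom_index(system, seg_b, resid_b, "N")
    d0 <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    distance_restraint(a, b, max(d0 - slack, 0), d0 + slack, k, label = label)
  }
  dists <- list()
  for (m in seq_len(spec$n_repeats)) {
    dists[[length(dists) + 1L]] <- link(
      paste0("S5.", m), 100L * m + spec$s5_len,
      paste0("S6.", m), 100L * m + 51L, paste0("loop S5-S6 repeat ", m))
  }
  dists[[length(dists) + 1L]] <- link("S6.1", 151L + spec$s6_len - 1L,
                                      "AID", 501L, "S6-AID linker")
  # the AID backbone may not separate from the bedplate by more than 9 A;
  # only alpha carbons actually seated over the plate (within 7.5 A of a
  # bedplate alpha carbon) are capped — the overhanging tail has no plate
  # underneath it
  bp_ca <- which(system$atoms$name == "CA" &
                   system$atoms$segment %in% c("BP1", "BP2"))
  aid_ca <- which(system$atoms$name == "CA" & system$atoms$segment == "AID")
  for (a in aid_ca) {
    dd <- sqrt(rowSums(sweep(xyz[bp_ca, , drop = FALSE], 2, xyz[a, ])^2))
    j <- bp_ca[which.min(dd)]
    if (min(dd) > 7.5) next
    dists[[length(dists) + 1L]] <- distance_restraint(
      a, j, 0, 9, 10, label = "AID-bedplate cap")
  }
  # turret anchors: the extracellular ends of S5 (C-terminal) and S6
  # (N-terminal) are held near their current positions
  pins <- list()
  # soft bedplate: all bedplate alpha carbons pinned with penalty-free
  # displacement up to 2.5 Angstrom
  for (i in which(system$atoms$name == "CA" &
                    system$atoms$segment %in% c("BP1", "BP2"))) {
    pins[[length(pins) + 1L]] <- pin_restraint(i, xyz[i, ], d = 2.5, k = 10,
                                               label = "bedplate")
  }
  for (m in seq_len(spec$n_repeats)) {
    for (at in list(c(paste0("S5.", m), 100L * m + spec$s5_len),
                    c(paste0("S6.", m), 100L * m + 51L))) {
      i <- atom_index(system, at[1], as.integer(at[2]), "CA")
      pins[[length(pins) + 1L]] <- pin_restraint(i, xyz[i, ], d = turret_d,
                                                 k = turret_k,
                                                 label = "turret anchor")
    }
  }
  # gate-ring scaffold: the state-defining gate radius is held near its
  # current (canonical) value; dropped when a stage steers the gate itself
  if (gate_pins) {
    for (m in seq_len(spec$n_repeats)) {
      i <- atom_index(system, paste0("S6.", m), 100L * m + 50L + spec$s6_len,
                      "CA")
      pins[[length(pins) + 1L]] <- pin_restraint(i, xyz[i, ], d = gate_d,
                                                 k = gate_k,
                                                 label = "gate scaffold")
    }
  }
  restraint_set(pins = pins, distances = dists)
}
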