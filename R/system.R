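# Molecular systems in internal (generalized) coordinates.
#
# A system is a set of free segments.  Each segment is an atom tree rooted at
# the backbone nitrogen of its first residue; the root carries a position
# (Cartesian, Angstrom) and an orientation (intrinsic Z-Y-X Euler angles).
# All other atoms are placed by rigid bond lengths and bond angles plus
# dihedrals, some of which are named flexible torsions (phi, psi, omega,
# chi1..chi4, hydroxyl/thiol rotations).  Bond lengths and angles are rigid
# except at registered flexible-bond-angle sites (prolines, vicinal-disulfide
# cysteines).  Cartesian coordinates are a pure function of the generalized
# coordinates and are cached per segment.

#' Define one segment of a molecular system
#'
#' @param id segment identifier (e.g. \code{"IS6"}, \code{"AID"}).
#' @param sequence character vector of 3-letter residue codes.
#' @param start_resid first residue number (source numbering is preserved).
#' @param group segment group: \code{"alpha1"}, \code{"beta_subunit"} or
#'   \code{"other"}.
#' @param variants optional named list residue number -> protonation variant
#'   (\code{"HID"}, \code{"HIE"}, \code{"HIP"}, \code{"CYS-reduced"},
#'   \code{"CYS-disulfide"}).
#' @return a \code{segment_spec} list.
#' @export
segment_spec <- function(id, sequence, start_resid = 1L, group = "alpha1",
                         variants = list()) {
  stopifnot(is.character(sequence))
  if (length(sequence) == 0) stop("empty segment: ", id)
  if (!group %in% c("alpha1", "beta_subunit", "other"))
    stop("unknown segment group: ", group)
  structure(list(id = id, sequence = toupper(sequence),
                 start_resid = as.integer(start_resid), group = group,
                 variants = variants),
            class = "segment_spec")
}

.tkey <- function(seg, resid, name) sprintf("%s:%d:%s", seg, resid, name)
.akey <- function(seg, resid, name) sprintf("%s:%d:%s", seg, resid, name)

# backbone atom rows for one residue
.backbone_rows <- function(topo, resname, first) {
  bb <- topo$backbone
  q <- if (resname == "PRO") bb$q_pro else bb$q
  rows <- list(
    list(name = "N", element = "N", lj = "N", q = unname(q["N"])),
    list(name = "CA", element = "C",
         lj = if (resname == "GLY") "CH2" else "CH1", q = unname(q["CA"])),
    list(name = "C", element = "C", lj = "C", q = unname(q["C"]))
  )
  if (resname != "PRO")
    rows <- c(rows, list(list(name = "H", element = "H", lj = "Hp",
                              q = unname(q["H"]))))
  c(rows, list(list(name = "O", element = "O", lj = "O", q = unname(q["O"]))))
}

#' Build a molecular system from segment definitions
#'
#' Threads each segment's sequence through the residue topology library,
#' producing a system whose torsions are initialized to ideal values:
#' backbone phi/psi to an extended conformation (180 degrees), omega trans,
#' sidechain torsions trans.  Each segment receives one root (position +
#' Euler orientation), initially placing segments at successive x offsets.
#'
#' @param segments list of \code{\link{segment_spec}} objects.
#' @param topology a \code{topology_library}; defaults to the built-in one.
#' @return an object of class \code{molecular_system}.
#' @export
build_system <- function(segments, topology = default_topology()) {
  if (inherits(segments, "segment_spec")) segments <- list(segments)
  known <- topology_residues(topology)
  ids <- vapply(segments, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids")

  atoms <- list(); residues <- list(); tors <- numeric(); tclass <- character()
  tor_atom <- integer()  # representative atom index per torsion
  idx <- 0L; rindex <- 0L

  for (seg in segments) {
    nres <- length(seg$sequence)
    for (r in seq_len(nres)) {
      resname <- seg$sequence[r]
      if (!resname %in% known)
        stop("unknown residue name '", resname, "' in segment ", seg$id)
      resid <- seg$start_resid + r - 1L
      variant <- seg$variants[[as.character(resid)]]
      if (is.null(variant)) variant <- "default"
      key <- .variant_key(resname, variant)
      rindex <- rindex + 1L
      residues[[rindex]] <- data.frame(
        rindex = rindex, segment = seg$id, group = seg$group, resid = resid,
        resname = resname, variant = variant, key = key, pos_in_seg = r,
        stringsAsFactors = FALSE)

      first <- r == 1L
      bb <- topology$backbone

      # helper to append one atom row
      add_atom <- function(name, element, lj, q, parent, gp, ggp, blen, bang,
                           tor, toff, formal = 0L, ionized = FALSE,
                           backbone = FALSE) {
        idx <<- idx + 1L
        atoms[[idx]] <<- data.frame(
          idx = idx, name = name, element = element, lj = lj, q = q,
          eps = topology$lj[[lj]][2], rmin2 = topology$lj[[lj]][1],
          formal = as.integer(formal), ionized = ionized,
          heavy = element != "H", resname = resname, variant = variant,
          rindex = rindex, resid = resid, segment = seg$id, group = seg$group,
          parent = parent, gp = gp, ggp = ggp, blen = blen,
          bang = deg2rad(bang), tor = tor, toff = deg2rad(toff),
          backbone = backbone, stringsAsFactors = FALSE)
        idx
      }
      reg_torsion <- function(name, value, class, atom_idx) {
        k <- .tkey(seg$id, resid, name)
        if (!k %in% names(tors)) {
          tors[k] <<- deg2rad(value)
          tclass[k] <<- class
          tor_atom[k] <<- atom_idx
        }
        k
      }

      bbq <- if (resname == "PRO") bb$q_pro else bb$q
      if (first) {
        # root triplet: placed from the segment root, but parent pointers are
        # kept so the bonded graph (exclusions) is complete
        iN <- add_atom("N", "N", "N", unname(bbq["N"]), NA, NA, NA, NA, 0,
                       NA, 0, backbone = TRUE)
        iCA <- add_atom("CA", "C", if (resname == "GLY") "CH2" else "CH1",
                        unname(bbq["CA"]), iN, NA, NA, NA, 0, NA, 0,
                        backbone = TRUE)
        iC <- add_atom("C", "C", "C", unname(bbq["C"]), iCA, iN, NA, NA, 0,
                       NA, 0, backbone = TRUE)
      } else {
        iNp <- bbidx[["N"]]; iCAp <- bbidx[["CA"]]; iCp <- bbidx[["C"]]
        iN <- add_atom("N", "N", "N", unname(bbq["N"]), iCp, iCAp, iNp,
                       unname(bb$blen["N"]), unname(bb$bang["N"]),
                       .tkey(seg$id, resid - 1L, "psi"), 0, backbone = TRUE)
        # psi of previous residue measured at this N
        tor_atom[.tkey(seg$id, resid - 1L, "psi")] <- iN
        komega <- reg_torsion("omega", 180, "omega", NA)
        iCA <- add_atom("CA", "C", if (resname == "GLY") "CH2" else "CH1",
                        unname(bbq["CA"]), iN, iCp, iCAp,
                        unname(bb$blen["CA"]), unname(bb$bang["CA"]),
                        komega, 0, backbone = TRUE)
        tor_atom[komega] <- iCA
        kphi <- reg_torsion("phi", 180, "backbone", NA)
        iC <- add_atom("C", "C", "C", unname(bbq["C"]), iCA, iN, iCp,
                       unname(bb$blen["C"]), unname(bb$bang["C"]),
                       kphi, 0, backbone = TRUE)
        tor_atom[kphi] <- iC
        if (resname != "PRO") {
          add_atom("H", "H", "Hp", unname(bbq["H"]), iN, iCp, iCAp,
                   unname(bb$blen["H"]), unname(bb$bang["H"]),
                   komega, 180, backbone = TRUE)
        }
      }
      # psi of this residue: registered now, measured at O (off 180) until a
      # following N overrides the driver
      kpsi_own <- reg_torsion("psi", 180, "backbone", NA)
      iO <- add_atom("O", "O", "O", unname(bbq["O"]), iC, iCA, iN,
                     unname(bb$blen["O"]), unname(bb$bang["O"]),
                     kpsi_own, 180, backbone = TRUE)
      if (is.na(tor_atom[kpsi_own])) tor_atom[kpsi_own] <- iO
      if (first && resname != "PRO") {
        add_atom("H", "H", "Hp", unname(bbq["H"]), iN, iCA, iC,
                 unname(bb$blen["H"]), 114.0, NA, 180, backbone = TRUE)
      }

      # sidechain
      sc <- topology$residues[[key]]
      if (!is.null(sc)) {
        scidx <- c(N = iN, CA = iCA, C = iC)
        for (j in seq_len(nrow(sc))) {
          row <- sc[j, ]
          ip <- unname(scidx[row$parent])
          if (is.na(ip)) stop("bad sidechain parent ", row$parent)
          # grandparent chain: CB hangs off CA with gp N; others follow parents
          if (row$parent == "CA") {
            # CB hangs off CA; its dihedral references C(r-1) when it exists
            # (and is then tied to phi) or this residue's C otherwise
            ig <- iN
            igg <- if (first) iC else atoms[[iN]]$parent
          } else {
            ig <- atoms[[ip]]$parent
            igg <- atoms[[ig]]$parent
            if (is.na(igg)) igg <- iC  # references through a first-residue N
            if (is.na(ig)) stop("unresolvable z-matrix reference")
          }
          tor <- NA_character_; toff <- row$off
          if (!is.na(row$tor)) {
            tor <- reg_torsion(row$tor, 180, "chi", NA)
            if (row$off == 0 && is.na(tor_atom[tor])) tor_atom[tor] <- idx + 1L
          } else if (row$parent == "CA") {
            # CB: tied to phi when phi exists, fixed offset otherwise
            if (!first) {
              tor <- .tkey(seg$id, resid, "phi")
              toff <- topology$backbone$cb_offset
            } else {
              toff <- topology$backbone$cb_offset
            }
          }
          scidx[row$name] <- add_atom(row$name, row$element, row$lj, row$q,
                                      ip, ig, igg, row$blen, row$bang, tor,
                                      toff, row$formal, row$ionized)
        }
      }
      bbidx <- c(N = iN, CA = iCA, C = iC)
    }
  }

  atoms <- do.call(rbind, atoms)
  residues <- do.call(rbind, residues)
  rownames(atoms) <- NULL

  roots <- list()
  for (k in seq_along(segments)) {
    roots[[segments[[k]]$id]] <- list(pos = c((k - 1) * 30, 0, 0),
                                      euler = c(0, 0, 0))
  }

  flexible <- rep(TRUE, length(tors)); names(flexible) <- names(tors)
  flexible[tclass == "omega"] <- FALSE

  # proline bond angles are flexible by convention
  flex_angles <- character()
  pro <- residues[residues$resname == "PRO", , drop = FALSE]
  if (nrow(pro) > 0) {
    for (i in seq_len(nrow(pro))) {
      flex_angles <- c(flex_angles,
                       .akey(pro$segment[i], pro$resid[i], c("CB", "CG", "CD")))
    }
  }

  sys <- structure(list(
    atoms = atoms, residues = residues,
    torsions = tors, torsion_class = tclass, torsion_atom = tor_atom,
    roots = roots, root_flexible = stats::setNames(rep(TRUE, length(roots)),
                                                   names(roots)),
    torsion_flexible = flexible,
    angles = stats::setNames(numeric(0), character(0)),
    flex_angle_sites = unique(flex_angles),
    extra_bonds = matrix(integer(0), ncol = 2),
    unpinnable = integer(0),
    backbone = topology$backbone,
    cache = new.env(parent = emptyenv())
  ), class = "molecular_system")
  sys <- .activate_angles(sys)
  .invalidate(sys, names(roots))
  sys
}

# flexible-bond-angle sites become scalar coordinates initialized from topology
.activate_angles <- function(system) {
  new_sites <- setdiff(system$flex_angle_sites, names(system$angles))
  for (site in new_sites) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    i <- which(system$atoms$segment == parts[1] &
                 system$atoms$resid == as.integer(parts[2]) &
                 system$atoms$name == parts[3])
    if (length(i) == 1) system$angles[site] <- system$atoms$bang[i]
  }
  # drop sites that no longer resolve (e.g. after a mutation)
  system$angles <- system$angles[!is.na(system$angles)]
  system
}

.invalidate <- function(system, segs) {
  system$cache$dirty_local <- union(system$cache$dirty_local, segs)
  invisible(system)
}

# copy-on-write: detach the cache environment so that modified copies of a
# system never alias the original's Cartesian cache
.cow <- function(system) {
  old <- system$cache
  cache <- new.env(parent = emptyenv())
  for (nm in ls(old)) assign(nm, get(nm, old), cache)
  system$cache <- cache
  system
}

.seg_atoms <- function(system, seg) which(system$atoms$segment == seg)

# rebuild the local-frame coordinates of one segment (hot path: columns are
# pre-extracted and the NeRF placement is inlined)
.build_segment_local <- function(system, seg) {
  at <- system$atoms
  rows <- .seg_atoms(system, seg)
  bb <- system$backbone
  v_tor <- at$tor[rows]; v_toff <- at$toff[rows]
  v_blen <- at$blen[rows]; v_bang <- at$bang[rows]
  v_par <- at$parent[rows]; v_gp <- at$gp[rows]; v_ggp <- at$ggp[rows]
  # flexible bond-angle overrides
  angles <- system$angles
  if (length(angles)) {
    akeys <- .akey(at$segment[rows], at$resid[rows], at$name[rows])
    hit <- match(akeys, names(angles))
    v_bang[!is.na(hit)] <- angles[hit[!is.na(hit)]]
  }
  # map global -> local row
  lmap <- integer(max(rows)); lmap[rows] <- seq_along(rows)
  n <- length(rows)
  loc <- matrix(NA_real_, n, 3)
  bCA <- unname(bb$blen["CA"]); bC <- unname(bb$blen["C"])
  aC <- deg2rad(unname(bb$bang["C"]))
  loc[1, ] <- c(0, 0, 0)
  loc[2, ] <- c(bCA, 0, 0)
  loc[3, ] <- c(bCA - bC * cos(aC), bC * sin(aC), 0)
  tors <- system$torsions
  tval <- rep(0, n)
  ht <- !is.na(v_tor)
  tval[ht] <- tors[v_tor[ht]]
  dihs <- v_toff + tval
  cosd <- cos(dihs); sind <- sin(dihs)
  cosb <- cos(v_bang); sinb <- sin(v_bang)
  for (k in 4:n) {
    a <- loc[lmap[v_ggp[k]], ]; b <- loc[lmap[v_gp[k]], ]
    cc <- loc[lmap[v_par[k]], ]
    bc <- cc - b
    bc <- bc / sqrt(sum(bc * bc))
    ab <- b - a
    nvec <- c(ab[2] * bc[3] - ab[3] * bc[2],
              ab[3] * bc[1] - ab[1] * bc[3],
              ab[1] * bc[2] - ab[2] * bc[1])
    nn <- sqrt(sum(nvec * nvec))
    if (nn < 1e-10) {
      ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      nvec <- c(ref[2] * bc[3] - ref[3] * bc[2],
                ref[3] * bc[1] - ref[1] * bc[3],
                ref[1] * bc[2] - ref[2] * bc[1])
      nn <- sqrt(sum(nvec * nvec))
    }
    nvec <- nvec / nn
    m <- c(nvec[2] * bc[3] - nvec[3] * bc[2],
           nvec[3] * bc[1] - nvec[1] * bc[3],
           nvec[1] * bc[2] - nvec[2] * bc[1])
    d2 <- v_blen[k] * sinb[k]
    loc[k, ] <- cc - (v_blen[k] * cosb[k]) * bc +
      (d2 * cosd[k]) * m - (d2 * sind[k]) * nvec
  }
  loc
}

#' Cartesian coordinates of a molecular system
#'
#' Forward kinematics: rebuilds (only) segments whose internal coordinates
#' changed since the last call and applies each segment's rigid root
#' transform.  The result is a pure function of the generalized coordinates;
#' repeated calls without coordinate changes return identical coordinates.
#'
#' @param system a \code{molecular_system}.
#' @return numeric matrix (n_atoms x 3), Angstrom, rows in atom order.
#' @export
to_cartesian <- function(system) {
  cache <- system$cache
  if (is.null(cache$local)) cache$local <- list()
  dirty <- union(system$cache$dirty_local,
                 setdiff(names(system$roots), names(cache$local)))
  for (seg in dirty) cache$local[[seg]] <- .build_segment_local(system, seg)
  cache$dirty_local <- character(0)
  segs <- names(system$roots)
  need <- if (is.null(cache$xyz)) segs else union(dirty, cache$dirty_xyz)
  if (is.null(cache$xyz)) cache$xyz <- matrix(NA_real_, nrow(system$atoms), 3)
  for (seg in need) {
    rt <- system$roots[[seg]]
    R <- euler_to_rot(rt$euler)
    rows <- .seg_atoms(system, seg)
    cache$xyz[rows, ] <- sweep(cache$local[[seg]] %*% t(R), 2, rt$pos, `+`)
  }
  cache$dirty_xyz <- character(0)
  cache$xyz
}

#' Set named torsions (degrees)
#'
#' @param system a \code{molecular_system}.
#' @param values named numeric vector, degrees; names are torsion keys
#'   (\code{"<segment>:<resid>:<name>"}).
#' @return the modified system.
#' @export
set_torsions <- function(system, values) {
  system <- .cow(system)
  bad <- setdiff(names(values), names(system$torsions))
  if (length(bad)) stop("unknown torsions: ", paste(bad, collapse = ", "))
  system$torsions[names(values)] <- wrap_angle(deg2rad(values))
  segs <- unique(sub(":.*$", "", names(values)))
  .invalidate(system, segs)
  system
}

# internal radian setter used by the minimizer (no validation, fast path);
# only segments whose torsion values actually change are invalidated
.set_torsions_rad <- function(system, keys, values) {
  system <- .cow(system)
  values <- wrap_angle(values)
  changed <- abs(system$torsions[keys] - values) > 1e-15
  system$torsions[keys] <- values
  if (any(changed))
    .invalidate(system, unique(sub(":.*$", "", keys[changed])))
  system
}

#' Get torsion values in degrees
#' @param system a \code{molecular_system}.
#' @param keys optional character vector of torsion keys.
#' @return named numeric vector, degrees.
#' @export
get_torsions <- function(system, keys = NULL) {
  v <- rad2deg(system$torsions)
  if (is.null(keys)) v else v[keys]
}

#' Set a segment root (position and/or orientation)
#'
#' @param system a \code{molecular_system}.
#' @param segment segment id.
#' @param pos length-3 position, Angstrom.
#' @param euler length-3 intrinsic Z-Y-X Euler angles, degrees.
#' @return the modified system.
#' @export
set_root <- function(system, segment, pos = NULL, euler = NULL) {
  system <- .cow(system)
  if (!segment %in% names(system$roots)) stop("unknown segment: ", segment)
  if (!is.null(pos)) system$roots[[segment]]$pos <- as.numeric(pos)
  if (!is.null(euler)) system$roots[[segment]]$euler <- deg2rad(as.numeric(euler))
  system$cache$dirty_xyz <- union(system$cache$dirty_xyz, segment)
  system
}

.set_root_rad <- function(system, segment, pos, euler) {
  system <- .cow(system)
  system$roots[[segment]] <- list(pos = pos, euler = euler)
  system$cache$dirty_xyz <- union(system$cache$dirty_xyz, segment)
  system
}

#' Locate a residue by segment and source residue number
#' @param system a \code{molecular_system}.
#' @param segment segment id.
#' @param resid source residue number.
#' @return the global residue index.
#' @export
locate_residue <- function(system, segment, resid) {
  i <- which(system$residues$segment == segment & system$residues$resid == resid)
  if (length(i) != 1) stop("no residue ", resid, " in segment ", segment)
  i
}

#' Torsion keys belonging to residues
#' @param system a \code{molecular_system}.
#' @param rindex global residue indices.
#' @param classes restrict to torsion classes
#'   (\code{"backbone"}, \code{"omega"}, \code{"chi"}).
#' @return character vector of torsion keys.
#' @export
residue_torsions <- function(system, rindex,
                             classes = c("backbone", "omega", "chi")) {
  res <- system$residues[rindex, , drop = FALSE]
  pref <- sprintf("%s:%d:", res$segment, res$resid)
  keys <- names(system$torsions)
  hit <- rep(FALSE, length(keys))
  for (p in pref) hit <- hit | startsWith(keys, p)
  keys[hit & system$torsion_class %in% classes]
}

#' Set all flexible sidechain torsions of given residues to trans
#'
#' Residues whose sequence differs from the template start from all-trans
#' sidechain conformations; this applies that starting assignment.
#'
#' @param system a \code{molecular_system}.
#' @param rindex global residue indices (e.g. from
#'   \code{\link{locate_residue}}).
#' @return the modified system.
#' @export
set_all_trans <- function(system, rindex) {
  if (length(rindex) == 0) return(system)
  if (any(rindex < 1 | rindex > nrow(system$residues)))
    stop("residue index outside system")
  keys <- residue_torsions(system, rindex, classes = "chi")
  if (length(keys) == 0) return(system)
  vals <- rep(180, length(keys)); names(vals) <- keys
  set_torsions(system, vals)
}

#' Measure a named torsion from Cartesian coordinates
#' @param system a \code{molecular_system}.
#' @param key torsion key.
#' @return angle in degrees, measured from the current Cartesian cache.
#' @export
measure_torsion <- function(system, key) {
  i <- system$torsion_atom[[key]]
  if (is.na(i)) stop("torsion ", key, " has no representative atom")
  xyz <- to_cartesian(system)
  at <- system$atoms
  d <- dihedral(xyz[at$ggp[i], ], xyz[at$gp[i], ], xyz[at$parent[i], ],
                xyz[i, ])
  rad2deg(wrap_angle(d - at$toff[i]))
}

#' Atom indices by residue and atom name
#' @param system a \code{molecular_system}.
#' @param segment segment id (vectorized with resid).
#' @param resid source residue numbers.
#' @param name atom name (e.g. \code{"CA"}).
#' @return integer atom indices.
#' @export
atom_index <- function(system, segment, resid, name = "CA") {
  at <- system$atoms
  out <- integer(length(resid))
  segment <- rep(segment, length.out = length(resid))
  for (k in seq_along(resid)) {
    i <- which(at$segment == segment[k] & at$resid == resid[k] &
                 at$name == name)
    if (length(i) != 1)
      stop("no atom ", name, " in ", segment[k], ":", resid[k])
    out[k] <- i
  }
  out
}

#' Apply a point mutation
#'
#' Replaces the sidechain topology of one residue, preserving the backbone
#' geometry and all other residues' generalized coordinates.  When
#' \code{disulfide_partner} is given (both residues cysteine), an S-S bond is
#' recorded, both cysteines switch to the oxidized variant with flexible
#' sidechain bond angles, and both alpha carbons are excluded from future pin
#' sets.
#'
#' @param system a \code{molecular_system}.
#' @param segment,resid residue locator.
#' @param new_residue 3-letter code of the replacement residue.
#' @param variant protonation variant for the new residue.
#' @param disulfide_partner optional \code{list(segment=, resid=)} locator of
#'   a cysteine to bond with (the mutated residue must then be CYS).
#' @param topology topology library.
#' @return the mutated \code{molecular_system}.
#' @export
apply_mutation <- function(system, segment, resid, new_residue,
                           variant = "default", disulfide_partner = NULL,
                           topology = default_topology()) {
  new_residue <- toupper(new_residue)
  ri <- locate_residue(system, segment, resid)
  res <- system$residues
  if (!is.null(disulfide_partner)) {
    if (new_residue != "CYS")
      stop("disulfide partner only valid for cysteine mutations")
    variant <- "CYS-disulfide"
  }
  specs <- list()
  for (sid in names(system$roots)) {
    rr <- res[res$segment == sid, , drop = FALSE]
    vars <- list()
    seqs <- rr$resname
    for (j in seq_len(nrow(rr))) {
      if (rr$segment[j] == segment && rr$resid[j] == resid) {
        seqs[j] <- new_residue
        if (variant != "default") vars[[as.character(rr$resid[j])]] <- variant
      } else if (rr$variant[j] != "default") {
        vars[[as.character(rr$resid[j])]] <- rr$variant[j]
      }
    }
    specs[[sid]] <- segment_spec(sid, seqs, rr$resid[1], rr$group[1], vars)
  }

  partner_ri <- NULL
  if (!is.null(disulfide_partner)) {
    partner_ri <- locate_residue(system, disulfide_partner$segment,
                                 disulfide_partner$resid)
    if (res$resname[partner_ri] != "CYS")
      stop("disulfide partner is not a cysteine")
    # check reachability on the current structure (CA-CA distance)
    xyz <- to_cartesian(system)
    ca1 <- xyz[atom_index(system, segment, resid, "CA"), ]
    ca2 <- xyz[atom_index(system, disulfide_partner$segment,
                          disulfide_partner$resid, "CA"), ]
    d <- vnorm(ca1 - ca2)
    if (d > 8)
      stop(sprintf(paste0("disulfide between %s:%d and %s:%d is geometrically",
                          " unreachable: CA-CA distance %.2f A > 8 A"),
                   segment, resid, disulfide_partner$segment,
                   disulfide_partner$resid, d))
    ps <- disulfide_partner$segment; pr <- disulfide_partner$resid
    sp <- specs[[ps]]
    sp$variants[[as.character(pr)]] <- "CYS-disulfide"
    specs[[ps]] <- sp
  }

  new <- build_system(specs, topology)
  # carry over coordinates
  shared <- intersect(names(new$torsions), names(system$torsions))
  new$torsions[shared] <- system$torsions[shared]
  new$roots <- system$roots
  sharedf <- intersect(names(new$torsion_flexible),
                       names(system$torsion_flexible))
  new$torsion_flexible[sharedf] <- system$torsion_flexible[sharedf]
  new$root_flexible <- system$root_flexible
  new$flex_angle_sites <- union(new$flex_angle_sites, system$flex_angle_sites)
  new <- .activate_angles(new)
  shared_a <- intersect(names(new$angles), names(system$angles))
  new$angles[shared_a] <- system$angles[shared_a]
  new$unpinnable <- system$unpinnable
  new$extra_bonds <- .remap_bonds(system, new)

  if (!is.null(disulfide_partner)) {
    sg1 <- atom_index(new, segment, resid, "SG")
    sg2 <- atom_index(new, disulfide_partner$segment, disulfide_partner$resid,
                      "SG")
    new$extra_bonds <- rbind(new$extra_bonds, c(sg1, sg2))
    new$flex_angle_sites <- union(
      new$flex_angle_sites,
      c(.akey(segment, resid, c("CB", "SG")),
        .akey(disulfide_partner$segment, disulfide_partner$resid,
              c("CB", "SG"))))
    new$unpinnable <- union(new$unpinnable,
                            c(locate_residue(new, segment, resid),
                              locate_residue(new, disulfide_partner$segment,
                                             disulfide_partner$resid)))
    new <- .activate_angles(new)
  }
  .invalidate(new, names(new$roots))
  new
}

# remap extra bonds from an old system to a rebuilt one via (seg, resid, name)
.remap_bonds <- function(old, new) {
  eb <- old$extra_bonds
  if (nrow(eb) == 0) return(eb)
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nrow(eb))) {
    a <- old$atoms[eb[k, 1], ]; b <- old$atoms[eb[k, 2], ]
    ia <- tryCatch(atom_index(new, a$segment, a$resid, a$name),
                   error = function(e) NA_integer_)
    ib <- tryCatch(atom_index(new, b$segment, b$resid, b$name),
                   error = function(e) NA_integer_)
    if (!is.na(ia) && !is.na(ib)) out <- rbind(out, c(ia, ib))
  }
  out
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues,", length(x$roots), "segments\n")
  cat("  segments:", paste(names(x$roots), collapse = ", "), "\n")
  cat("  torsions:", length(x$torsions),
      sprintf("(%d flexible)", sum(x$torsion_flexible)), "\n")
  invisible(x)
}

#' @export
summary.molecular_system <- function(object, ...) {
  res <- object$residues
  seg <- split(res, res$segment)
  cat("molecular_system with", length(seg), "segments\n")
  for (s in names(object$roots)) {
    rr <- seg[[s]]
    cat(sprintf("  %-10s %3d residues (%d-%d) group=%s\n", s, nrow(rr),
                min(rr$resid), max(rr$resid), rr$group[1]))
  }
  invisible(object)
}

# ---- flattened coordinate interface (used by the minimizer) ----

#' Keys of flexible generalized coordinates
#'
#' @param system a \code{molecular_system}.
#' @return data.frame with columns \code{type} (\code{torsion},
#'   \code{root_pos}, \code{root_euler}, \code{angle}), \code{key} and
#'   \code{comp} (component 1..3 for roots, 0 otherwise) — one row per scalar
#'   degree of freedom.
#' @export
flexible_coords <- function(system) {
  out <- list()
  tk <- names(system$torsions)[system$torsion_flexible]
  if (length(tk))
    out[[length(out) + 1L]] <- data.frame(type = "torsion", key = tk, comp = 0L,
                                          stringsAsFactors = FALSE)
  for (seg in names(system$roots)[system$root_flexible[names(system$roots)]]) {
    out[[length(out) + 1L]] <- data.frame(
      type = rep(c("root_pos", "root_euler"), each = 3),
      key = seg, comp = rep(1:3, 2), stringsAsFactors = FALSE)
  }
  ak <- names(system$angles)
  if (!is.null(system$angle_flexible))
    ak <- ak[system$angle_flexible[ak]]
  if (length(ak))
    out[[length(out) + 1L]] <- data.frame(type = "angle", key = ak,
                                          comp = 0L, stringsAsFactors = FALSE)
  if (!length(out)) return(data.frame(type = character(), key = character(),
                                      comp = integer()))
  do.call(rbind, out)
}

#' Get the flexible coordinates as a numeric vector (internal units)
#' @param system a \code{molecular_system}.
#' @param keys a data.frame from \code{\link{flexible_coords}}.
#' @return numeric vector (radians / Angstrom).
#' @export
get_par <- function(system, keys = flexible_coords(system)) {
  n <- nrow(keys)
  v <- numeric(n)
  for (i in seq_len(n)) {
    v[i] <- switch(keys$type[i],
      torsion = system$torsions[[keys$key[i]]],
      root_pos = system$roots[[keys$key[i]]]$pos[keys$comp[i]],
      root_euler = system$roots[[keys$key[i]]]$euler[keys$comp[i]],
      angle = system$angles[[keys$key[i]]])
  }
  v
}

#' Set the flexible coordinates from a numeric vector (internal units)
#' @param system a \code{molecular_system}.
#' @param par numeric vector as returned by \code{\link{get_par}}.
#' @param keys a data.frame from \code{\link{flexible_coords}}.
#' @return the modified system.
#' @export
set_par <- function(system, par, keys = flexible_coords(system)) {
  stopifnot(length(par) == nrow(keys))
  it <- keys$type == "torsion"
  if (any(it)) system <- .set_torsions_rad(system, keys$key[it], par[it])
  ia <- keys$type == "angle"
  if (any(ia)) {
    system$angles[keys$key[ia]] <- par[ia]
    .invalidate(system, unique(sub(":.*$", "", keys$key[ia])))
  }
  segs <- unique(keys$key[keys$type %in% c("root_pos", "root_euler")])
  for (seg in segs) {
    rp <- keys$type == "root_pos" & keys$key == seg
    re <- keys$type == "root_euler" & keys$key == seg
    pos <- system$roots[[seg]]$pos
    eul <- system$roots[[seg]]$euler
    pos[keys$comp[rp]] <- par[rp]
    eul[keys$comp[re]] <- par[re]
    system <- .set_root_rad(system, seg, pos, eul)
  }
  system
}

#' Restrict which coordinates are flexible
#'
#' @param system a \code{molecular_system}.
#' @param torsions character vector of torsion keys to leave flexible
#'   (\code{NULL} = leave unchanged; \code{character(0)} = freeze all).
#' @param roots character vector of segment ids with flexible roots.
#' @param angles character vector of flexible-bond-angle sites to leave
#'   flexible (\code{NULL} = leave unchanged).
#' @return the modified system.
#' @export
set_flexible <- function(system, torsions = NULL, roots = NULL,
                         angles = NULL) {
  if (!is.null(torsions)) {
    system$torsion_flexible[] <- FALSE
    system$torsion_flexible[torsions] <- TRUE
  }
  if (!is.null(roots)) {
    system$root_flexible[] <- FALSE
    system$root_flexible[intersect(roots, names(system$root_flexible))] <- TRUE
  }
  if (!is.null(angles)) {
    af <- stats::setNames(rep(FALSE, length(system$angles)),
                          names(system$angles))
    af[intersect(angles, names(af))] <- TRUE
    system$angle_flexible <- af
  }
  system
}

#' Deep-copy a molecular system
#'
#' The Cartesian cache lives in an environment; copy it so that minimizer
#' scratch systems do not alias the caller's cache.
#' @param system a \code{molecular_system}.
#' @return an independent copy.
#' @export
clone_system <- function(system) {
  new <- system
  new$cache <- new.env(parent = emptyenv())
  for (nm in ls(system$cache)) assign(nm, get(nm, system$cache), new$cache)
  new
}
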