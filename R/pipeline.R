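# Pipeline stages: homology threading (three-trajectory protocol), steered
# state transformation, and double-shell mutant sampling.

#' Pairwise model/template residue alignment
#'
#' @param model_rindex,template_rindex integer residue indices (strictly
#'   increasing, equal length).
#' @param match logical: TRUE where the aligned residues are identical.
#' @return a \code{template_map}.
#' @export
template_map <- function(model_rindex, template_rindex, match) {
  stopifnot(length(model_rindex) == length(template_rindex),
            length(match) == length(model_rindex))
  if (is.unsorted(model_rindex, strictly = TRUE) ||
      is.unsorted(template_rindex, strictly = TRUE))
    stop("alignment must be strictly increasing on both sides")
  structure(data.frame(model_rindex = as.integer(model_rindex),
                       template_rindex = as.integer(template_rindex),
                       match = as.logical(match)),
            class = c("template_map", "data.frame"))
}

# provenance sufficient to re-run a stage bit-identically
.provenance <- function(stage, config, seed = config$rng_seed,
                        inputs = list()) {
  tf <- tempfile(); on.exit(unlink(tf))
  saveRDS(list(config = unclass(config), inputs = inputs), tf)
  list(stage = stage, tool_version = .pkg_version(), config_hash = unname(tools::md5sum(tf)), seed = seed)
}

#' A state-labelled model with provenance
#' @param system a \code{molecular_system}.
#' @param state_label \code{"inactivated"}, \code{"open"}, \code{"closed"}
#'   or \code{"custom"}.
#' @param provenance provenance record.
#' @param details stage-specific extras (RMSD reports, trajectories).
#' @export
state_model <- function(system, state_label = "custom", provenance = NULL,
                        details = list()) {
  stopifnot(state_label %in% c("inactivated", "open", "closed", "custom"))
  structure(list(state_label = state_label, system = system,
                 provenance = provenance, details = details),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("state_model [", x$state_label, "]: ", nrow(x$system$atoms), " atoms\n",
      sep = "")
  if (!is.null(x$details$rmsd_ca))
    cat(sprintf("  final CA RMSD to template: %.3f A\n", x$details$rmsd_ca))
  invisible(x)
}

#' Homology threading with the three-trajectory optimization protocol
#'
#' Threads the model sequence onto the template's generalized coordinates
#' (backbone torsions and segment roots copied; mismatched residues start
#' from all-trans sidechains) and optimizes in three consecutive MCM
#' trajectories: (1) sidechain torsions only, (2) all generalized
#' coordinates under alpha-carbon pins to the template (default half-width
#' 1 Angstrom, force constant 10 kcal/mol/A^2), (3) unpinned, to confirm the
#' model is energetically stable.  Each trajectory runs to the configured
#' convergence window.
#'
#' @param template a \code{molecular_system} providing coordinates.
#' @param map a \code{\link{template_map}} aligning model residues to
#'   template residues; must cover every model residue.
#' @param model_segments list of \code{\link{segment_spec}} for the model
#'   sequence (same segmentation as the template).
#' @param config an \code{\link{mcm_config}}.
#' @param opts \code{\link{nonbonded_options}}.
#' @param pin_d,pin_k trajectory-2 pin parameters.
#' @param standing optional \code{restraint_set} of standing terms that play
#'   the role of bonded interactions (e.g. the toy channel's
#'   loop-connectivity stand-ins); present in all three trajectories.
#' @return a \code{\link{state_model}} labelled \code{"custom"} with
#'   \code{details$rmsd_ca}, \code{details$trajectories}.
#' @export
stage_homology <- function(template, map, model_segments,
                           config = mcm_config(), opts = nonbonded_options(),
                           pin_d = 1, pin_k = 10, standing = NULL) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  model <- build_system(model_segments)
  if (nrow(map) < nrow(model$residues)) {
    missing <- setdiff(seq_len(nrow(model$residues)), map$model_rindex)
    mr <- model$residues[missing[1], ]
    stop("alignment does not cover modeled residue ", mr$segment, ":",
         mr$resid)
  }
  # thread: copy template generalized coordinates for aligned residues
  tt <- template$torsions
  shared <- intersect(names(model$torsions), names(tt))
  model$torsions[shared] <- tt[shared]
  model$roots <- template$roots
  .invalidate(model, names(model$roots))
  # mismatched residues start all-trans
  mism <- map$model_rindex[!map$match]
  model <- set_all_trans(model, mism)

  chi_keys <- names(model$torsions)[model$torsion_class == "chi"]
  bb_keys <- names(model$torsions)[model$torsion_class == "backbone"]

  cfg <- config; cfg$rng_seed <- NULL
  if (is.null(standing)) standing <- restraint_set()
  # trajectory 1: sidechains only
  m1 <- set_flexible(model, torsions = chi_keys, roots = character(0))
  t1 <- run_mcm(m1, standing, cfg, opts)
  # trajectory 2: everything flexible, pinned to template CA positions
  ca_sel <- which(model$atoms$name == "CA")
  tmpl_ca <- to_cartesian(template)[which(template$atoms$name == "CA"), ,
                                    drop = FALSE]
  if (length(ca_sel) != nrow(tmpl_ca))
    stop("template and model alpha-carbon counts differ")
  pins <- make_pins_from_template(t1$lowest$system, tmpl_ca, ca_sel,
                                  d = pin_d, k = pin_k, label = "homology")
  m2 <- set_flexible(t1$lowest$system, torsions = c(chi_keys, bb_keys),
                     roots = names(model$roots))
  t2 <- run_mcm(m2, merge_restraints(restraint_set(pins = pins), standing),
                cfg, opts)
  # trajectory 3: unpinned
  t3 <- run_mcm(t2$lowest$system, standing, cfg, opts)

  final <- t3$lowest$system
  # superpose before comparing, as models are compared after a least-squares
  # alpha-carbon fit
  rms <- superpose(to_cartesian(final)[ca_sel, , drop = FALSE], tmpl_ca)$rmsd
  state_model(final, "custom",
              .provenance("homology", config,
                          inputs = list(n_res = nrow(model$residues))),
              details = list(
                rmsd_ca = rms, all_trans_rindex = mism,
                trajectories = list(t1 = t1, t2 = t2, t3 = t3)))
}

#' Steered state transformation
#'
#' Drives selected alpha carbons to target coordinates through the staged
#' steering protocol of \code{\link{run_steered}}, under companion
#' restraints (helical hydrogen bonds, backbone torsion windows, bedplate
#' and sensor pins, the optional sensor-AID anchor bias or the AID-bedplate
#' separation cap for unbiased deactivation).
#'
#' @param model a \code{\link{state_model}}.
#' @param target_coords matrix of target positions (one row per selected
#'   atom).
#' @param selection integer atom indices to steer (e.g. from
#'   \code{\link{select_by_labels}}).
#' @param restraints companion \code{restraint_set}.
#' @param config \code{\link{mcm_config}}.
#' @param opts \code{\link{nonbonded_options}}.
#' @param state_label label for the resulting model.
#' @param half_width,k steering restraint window and force constant.
#' @param stability_minimizations unconstrained stability leg length.
#' @return a \code{\link{state_model}} with \code{details$steered}
#'   (the \code{steered_result}) and \code{details$restraint_dump}.
#' @export
stage_transform <- function(model, target_coords, selection,
                            restraints = restraint_set(),
                            config = mcm_config(),
                            opts = nonbonded_options(),
                            state_label = "custom", half_width = 0.3, k = 10,
                            stability_minimizations = 10,
                            stability_restraints = NULL) {
  sys <- model$system
  if (any(selection < 1 | selection > nrow(sys$atoms)))
    stop("selection index outside system")
  xyz <- to_cartesian(sys)
  sched <- steer_schedule(selection, xyz[selection, , drop = FALSE],
                          as.matrix(target_coords), half_width = half_width,
                          k = k)
  res <- run_steered(sys, sched, restraints, config, opts,
                     stability_minimizations = stability_minimizations,
                     stability_restraints = stability_restraints)
  state_model(res$system, state_label,
              .provenance("transform", config,
                          inputs = list(n_sel = length(selection))),
              details = list(steered = res,
                             restraint_dump = restraint_table(restraints)))
}

#' Double-shell partition around a mutation site
#'
#' The flexible shell holds every residue with at least one heavy atom
#' within \code{r_flex} of any heavy atom of the center residue; the rigid
#' shell holds residues outside the flexible shell with a heavy atom within
#' \code{r_rigid}; everything else is outside (excluded from the energy).
#'
#' @param system a \code{molecular_system} (or \code{state_model}).
#' @param segment,resid locator of the mutated residue.
#' @param r_flex,r_rigid shell radii, Angstrom (defaults 15 / 20).
#' @return a \code{shell_partition}: list with \code{center},
#'   \code{flexible}, \code{rigid}, \code{outside} (residue indices) and
#'   \code{distances} (per-residue minimal heavy-atom distance).
#' @export
build_shells <- function(system, segment, resid, r_flex = 15, r_rigid = 20) {
  if (inherits(system, "state_model")) system <- system$system
  center <- locate_residue(system, segment, resid)
  xyz <- to_cartesian(system)
  at <- system$atoms
  heavy <- at$heavy
  cidx <- which(at$rindex == center & heavy)
  n_res <- nrow(system$residues)
  dmin <- rep(Inf, n_res)
  hidx <- which(heavy)
  # min distance from each heavy atom to the center residue's heavy atoms
  dmat <- sqrt(pmax(outer(rowSums(xyz[hidx, , drop = FALSE]^2),
                          rowSums(xyz[cidx, , drop = FALSE]^2), "+") -
                      2 * xyz[hidx, , drop = FALSE] %*%
                      t(xyz[cidx, , drop = FALSE]), 0))
  amin <- apply(dmat, 1, min)
  agg <- tapply(amin, at$rindex[hidx], min)
  dmin[as.integer(names(agg))] <- agg
  flexible <- which(dmin <= r_flex)
  rigid <- setdiff(which(dmin <= r_rigid), flexible)
  outside <- setdiff(seq_len(n_res), c(flexible, rigid))
  structure(list(center = center, flexible = flexible, rigid = rigid,
                 outside = outside, distances = dmin,
                 r_flex = r_flex, r_rigid = r_rigid),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat(sprintf(paste0("shell_partition: center residue %d; %d flexible,",
                     " %d rigid, %d outside\n"), x$center,
              length(x$flexible), length(x$rigid), length(x$outside)))
  invisible(x)
}

#' Double-shell mutant sampling
#'
#' Applies the mutation, randomizes the sidechain torsions of the flexible
#' shell in \code{n_starts} starting conformations (uniform resampling;
#' optionally also the shell backbone), minimizes each start, and assembles
#' the ensemble of minimized structures within \code{window} kcal/mol of the
#' apparent global minimum.  Rigid-shell coordinates are frozen
#' (bit-identical across starts); outside-shell residues are excluded from
#' the energy.
#'
#' @param model a \code{\link{state_model}} of the wild-type channel.
#' @param segment,resid mutation site.
#' @param new_residue replacement residue (3-letter code); use the wild-type
#'   residue to re-sample the native sidechain packing.
#' @param variant protonation variant (see \code{\link{apply_mutation}}).
#' @param disulfide_partner optional partner locator for vicinal disulfides.
#' @param shells a \code{\link{build_shells}} partition of the mutated
#'   model; built automatically when NULL.
#' @param n_starts number of random starting conformations (128 at the
#'   production settings).
#' @param window ensemble energy window above the minimum, kcal/mol.
#' @param randomize \code{"sidechain"} (default) or \code{"all"} (also the
#'   flexible-shell backbone torsions).
#' @param config \code{\link{mcm_config}} (its \code{rng_seed} seeds the
#'   start generation; \code{max_min_iterations} caps each minimization).
#' @param opts \code{\link{nonbonded_options}}.
#' @param r_flex,r_rigid shell radii when \code{shells} is NULL.
#' @return a \code{mutant_ensemble}: list with \code{starts} (data.frame of
#'   minimized energies), \code{best} (list: system, energy, start),
#'   \code{window_members} (start indices with E <= best + window),
#'   \code{shells}, \code{mutant_system}.
#' @export
stage_mutant <- function(model, segment, resid, new_residue,
                         variant = "default", disulfide_partner = NULL,
                         shells = NULL, n_starts = 128, window = 7,
                         randomize = c("sidechain", "all"),
                         config = mcm_config(), opts = nonbonded_options(),
                         r_flex = 15, r_rigid = 20) {
  randomize <- match.arg(randomize)
  if (n_starts < 1) stop("n_starts must be at least 1")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  sys <- if (inherits(model, "state_model")) model$system else model
  mut <- apply_mutation(sys, segment, resid, new_residue, variant,
                        disulfide_partner)
  if (is.null(shells))
    shells <- build_shells(mut, segment, resid, r_flex, r_rigid)
  classes <- if (randomize == "sidechain") "chi" else c("chi", "backbone")
  flex_keys <- residue_torsions(mut, shells$flexible, classes = "chi")
  rand_keys <- residue_torsions(mut, shells$flexible, classes = classes)
  mut <- set_flexible(mut, torsions = flex_keys, roots = character(0))
  keys <- flexible_coords(mut)

  rows <- list(); results <- list()
  for (s in seq_len(n_starts)) {
    start <- set_torsions(mut, stats::setNames(
      stats::runif(length(rand_keys), -180, 180), rand_keys))
    fit <- local_minimize(start, NULL, config$max_min_iterations, opts,
                          exclude_rindex = shells$outside)
    rows[[s]] <- data.frame(start = s, energy = fit$energy,
                            start_energy = fit$start_energy)
    results[[s]] <- fit$system
  }
  starts <- do.call(rbind, rows)
  ib <- which.min(starts$energy)
  members <- which(starts$energy <= starts$energy[ib] + window)
  structure(list(starts = starts,
                 best = list(system = results[[ib]],
                             energy = starts$energy[ib], start = ib),
                 systems = results,
                 window_members = members, window = window,
                 shells = shells, mutant_system = mut,
                 provenance = .provenance("mutant", config,
                                          inputs = list(site = resid,
                                                        to = new_residue))),
            class = "mutant_ensemble")
}

#' @export
print.mutant_ensemble <- function(x, ...) {
  cat(sprintf(paste0("mutant_ensemble: %d starts, best %.4f kcal/mol,",
                     " %d within %.1f kcal/mol\n"),
              nrow(x$starts), x$best$energy, length(x$window_members),
              x$window))
  invisible(x)
}

# ---- toy transform profile -------------------------------------------------

#' Default steering profile for the synthetic toy channel
#'
#' Assembles the inputs of \code{\link{stage_transform}} for the toy
#' open/closed pair: steering targets on the S5/S6 alpha carbons, bedplate
#' pins (penalty-free up to 2.5 Angstrom), helical hydrogen-bond restraints
#' on S5 and S6, 5-degree backbone torsion windows on the AID helix and the
#' C-terminal third of S6, a gate-to-AID linker restraint standing in for
#' the covalent S6-AID connection, and either the sensor-arginine-to-AID-
#' glutamine anchor bias (\code{biased = TRUE}) or a 9-Angstrom cap on the
#' AID-bedplate backbone separation (\code{biased = FALSE}, the unbiased
#' deactivation variant).  AID and the sensor helix carry no pins so they
#' move freely.
#'
#' @param from the starting-state toy system.
#' @param to the target-state toy system (same spec).
#' @param biased use the sensor-AID anchor restraint (TRUE) or the
#'   separation cap (FALSE).
#' @param half_width,k steering restraint parameters.
#' @return list with \code{selection}, \code{target}, \code{restraints},
#'   \code{system} (the start system with the transform's flexibility
#'   profile applied), \code{half_width}, \code{k}.
#' @export
toy_transform_profile <- function(from, to, biased = TRUE, half_width = 1.0,
                                  k = 150) {
  spec <- attr(from, "toy_spec")
  if (is.null(spec)) stop("'from' is not a generated toy channel")
  map <- toy_label_map(spec)
  # steer the outer-helix ring and the cytoplasmic two thirds of each gate
  # helix; the conserved extracellular end is left to follow
  sel_o <- select_by_labels(from, 1:spec$n_repeats, "o", 1:spec$s5_len, map)
  i_from <- max(1L, ceiling(spec$s6_len / 3) + 1L)
  sel_i <- select_by_labels(from, 1:spec$n_repeats, "i",
                            i_from:spec$s6_len, map)
  selection <- c(sel_o, sel_i)
  target <- to_cartesian(to)[selection, , drop = FALSE]
  xyz <- to_cartesian(from)

  # bedplate pins, d = 2.5
  bp_ca <- which(from$atoms$name == "CA" &
                   from$atoms$segment %in% c("BP1", "BP2"))
  pins <- make_pins_from_template(from, xyz[bp_ca, , drop = FALSE], bp_ca,
                                  d = 2.5, k = 10, label = "bedplate")

  # helix H-bond restraints on S5 and S6
  helices <- list()
  for (m in seq_len(spec$n_repeats)) {
    helices[[length(helices) + 1L]] <-
      make_helix_restraints(from, paste0("S5.", m),
                            100L * m + seq_len(spec$s5_len))
    helices[[length(helices) + 1L]] <-
      make_helix_restraints(from, paste0("S6.", m),
                            100L * m + 50L + seq_len(spec$s6_len))
  }

  # 5-degree torsion windows on AID backbone and the C-third of each S6
  tw <- list()
  aid_bb <- residue_torsions(from, which(from$residues$segment == "AID"),
                             classes = "backbone")
  s6_cpart <- which(from$residues$segment %in%
                      paste0("S6.", seq_len(spec$n_repeats)) &
                      from$residues$pos_in_seg > ceiling(spec$s6_len * 2 / 3))
  s6_bb <- residue_torsions(from, s6_cpart, classes = "backbone")
  for (tk in c(aid_bb, s6_bb))
    tw[[length(tw) + 1L]] <- torsion_window_restraint(
      tk, rad2deg(from$torsions[[tk]]), 5, 0.1)

  dists <- list()
  if (biased) {
    # sensor arginine to AID glutamine anchor
    arg_cz <- atom_index(from, "IIS0", 702L, "CZ")
    gln_oe <- atom_index(from, "AID", 500L + spec$aid_polar_resids[1], "OE1")
    d1 <- sqrt(sum((xyz[arg_cz, ] - xyz[gln_oe, ])^2))
    dists[[length(dists) + 1L]] <- distance_restraint(
      arg_cz, gln_oe, 0, max(d1, 5), 10, label = "sensor-AID anchor")
  }
  # the AID backbone may not separate from the bedplate by more than 9 A
  # (active in both the biased and the unbiased variant)
  bp_ca_xyz <- xyz[bp_ca, , drop = FALSE]
  aid_cas <- which(from$atoms$name == "CA" & from$atoms$segment == "AID")
  for (a in aid_cas) {
    dd <- sqrt(rowSums(sweep(bp_ca_xyz, 2, xyz[a, ])^2))
    if (min(dd) > 7.5) next  # the overhanging tail has no plate beneath it
    dists[[length(dists) + 1L]] <- distance_restraint(
      a, bp_ca[which.min(dd)], 0, 9, 10, label = "AID-bedplate cap")
  }
  # transform variant of the toy scaffold: gate pins are replaced by the
  # steering targets; S6 turret anchors are dropped (those atoms are
  # steered); loop-connectivity windows are widened to admit both endpoint
  # geometries
  spec2 <- attr(from, "toy_spec")
  xyz_to <- to_cartesian(to)
  link <- function(i_a, i_b, label, k = 10) {
    d_from <- sqrt(sum((xyz[i_a, ] - xyz[i_b, ])^2))
    d_to <- sqrt(sum((xyz_to[i_a, ] - xyz_to[i_b, ])^2))
    distance_restraint(i_a, i_b, max(min(d_from, d_to) - 0.5, 0),
                       max(d_from, d_to) + 0.5, k, label = label)
  }
  for (m in seq_len(spec2$n_repeats)) {
    dists[[length(dists) + 1L]] <- link(
      atom_index(from, paste0("S5.", m), 100L * m + spec2$s5_len, "C"),
      atom_index(from, paste0("S6.", m), 100L * m + 51L, "N"),
      paste0("loop S5-S6 repeat ", m))
  }
  last6 <- 151L + spec2$s6_len - 1L
  dists[[length(dists) + 1L]] <- link(
    atom_index(from, "S6.1", last6, "C"), atom_index(from, "AID", 501L, "N"),
    "S6-AID linker")
  for (m in seq_len(spec2$n_repeats)) {
    i <- atom_index(from, paste0("S5.", m), 100L * m + spec2$s5_len, "CA")
    pins[[length(pins) + 1L]] <- pin_restraint(i, xyz[i, ], d = 0.75, k = 10,
                                               label = "turret anchor")
  }
  restraints <- restraint_set(pins = pins, distances = dists,
                              torsion_windows = tw, helices = helices)
  standing <- restraint_set(distances = dists)

  # flexibility profile: helices moved by their roots; the AID backbone and
  # the sidechains of all state-dependent segments stay free
  mobile_res <- which(from$residues$segment %in%
                        c(paste0("S6.", seq_len(spec$n_repeats)), "AID",
                          "IIS0"))
  mobile_chi <- residue_torsions(from, mobile_res, classes = "chi")
  # the C-third of each gate helix flexes within its 5-degree windows so the
  # terminal backbones can repack at the tight closed ring
  sys <- set_flexible(from, torsions = c(aid_bb, s6_bb, mobile_chi),
                      roots = names(from$roots))
  list(selection = selection, target = target, restraints = restraints,
       system = sys, half_width = half_width, k = k,
       stability_restraints = standing)
}
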