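# Monte Carlo minimization (MCM) in generalized coordinates.
#
# One MCM step: perturb one randomly chosen flexible coordinate, locally
# minimize the total energy (nonbonded + restraints) over all flexible
# coordinates with a bounded iteration budget, and accept or reject the
# minimized point by the Metropolis criterion applied to minimized energies.
# A trajectory terminates when a window of consecutive minimizations fails
# to improve the lowest energy found (the convergence rule), or at a hard
# minimization cap.  The steered driver interpolates restraint anchors
# linearly from start to target over a fixed number of stages, running a
# short MCM leg per stage with a tight per-minimization iteration limit so
# consecutive accepted points stay structurally close.

KBOLTZ <- 0.0019872041  # kcal/mol/K

#' MCM engine configuration
#'
#' @param temperature Metropolis temperature, K.
#' @param max_min_iterations iteration cap per local minimization (the
#'   steered driver uses \code{steered_max_min_iterations}).
#' @param steered_max_min_iterations iteration cap per minimization inside a
#'   steering stage; small so consecutive steps stay close.
#' @param convergence_window number of consecutive minimizations without a
#'   new lowest energy that terminates a trajectory.
#' @param max_minimizations hard cap on minimizations per trajectory.
#' @param stage_accept,stage_proposals a steering stage ends after this many
#'   accepted points or proposals, whichever comes first.
#' @param n_stages number of linear anchor-interpolation stages.
#' @param rng_seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param torsion_resample if TRUE a proposed torsion is resampled uniformly
#'   in (-180, 180]; otherwise perturbed by a Gaussian of
#'   \code{torsion_sigma} degrees.
#' @param torsion_sigma,root_pos_sigma,euler_sigma,angle_sigma move
#'   amplitudes (degrees / Angstrom / degrees / degrees).
#' @param segment_move_prob probability of a whole-segment rigid-body move
#'   (all six root coordinates of one randomly chosen flexible segment
#'   perturbed together) instead of a single-coordinate move.
#' @param segment_pos_sigma,segment_euler_sigma amplitudes of the rigid-body
#'   segment move (Angstrom / degrees).
#' @return an \code{mcm_config} list.
#' @export
mcm_config <- function(temperature = 600, max_min_iterations = 1000,
                       steered_max_min_iterations = 100,
                       convergence_window = 2000, max_minimizations = 10000,
                       stage_accept = 50, stage_proposals = 500,
                       n_stages = 10, rng_seed = NULL,
                       torsion_resample = TRUE, torsion_sigma = 30,
                       root_pos_sigma = 0.5, euler_sigma = 10,
                       angle_sigma = 2, segment_move_prob = 0.4,
                       segment_pos_sigma = 0.5, segment_euler_sigma = 5) {
  stopifnot(temperature > 0, max_min_iterations >= 0,
            convergence_window > 0, max_minimizations > 0, n_stages > 0)
  structure(as.list(environment()), class = "mcm_config")
}

# compile a restraint set into vectors for fast evaluation
.compile_restraints <- function(set) {
  if (is.null(set)) set <- restraint_set()
  pins <- set$pins
  cmp <- list()
  cmp$pin_atom <- vapply(pins, `[[`, integer(1), "atom")
  cmp$pin_anchor <- if (length(pins))
    do.call(rbind, lapply(pins, `[[`, "anchor")) else matrix(0, 0, 3)
  cmp$pin_d <- vapply(pins, `[[`, numeric(1), "d")
  cmp$pin_k <- vapply(pins, `[[`, numeric(1), "k")
  ds <- set$distances
  cmp$d_a <- vapply(ds, `[[`, integer(1), "atom_a")
  cmp$d_b <- vapply(ds, `[[`, integer(1), "atom_b")
  cmp$d_lo <- vapply(ds, `[[`, numeric(1), "lower")
  cmp$d_hi <- vapply(ds, `[[`, numeric(1), "upper")
  cmp$d_k <- vapply(ds, `[[`, numeric(1), "k")
  tw <- set$torsion_windows
  cmp$t_key <- vapply(tw, `[[`, character(1), "torsion")
  cmp$t_ref <- deg2rad(vapply(tw, `[[`, numeric(1), "reference"))
  cmp$t_hw <- vapply(tw, `[[`, numeric(1), "half_width")
  cmp$t_k <- vapply(tw, `[[`, numeric(1), "k")
  hp <- lapply(set$helices, `[[`, "pairs")
  hp <- hp[!vapply(hp, is.null, logical(1))]
  cmp$h_pairs <- if (length(hp)) do.call(rbind, hp) else matrix(0L, 0, 2)
  hx <- set$helices
  cmp$h_lo <- unlist(lapply(hx, function(h)
    rep(h$target - h$half_width, nrow(h$pairs))))
  cmp$h_hi <- unlist(lapply(hx, function(h)
    rep(h$target + h$half_width, nrow(h$pairs))))
  cmp$h_k <- unlist(lapply(hx, function(h) rep(h$k, nrow(h$pairs))))
  cmp
}

.restraint_e_fast <- function(xyz, torsions, cmp) {
  e <- 0
  if (length(cmp$pin_atom)) {
    dev <- sqrt(rowSums((xyz[cmp$pin_atom, , drop = FALSE] -
                           cmp$pin_anchor)^2))
    over <- pmax(dev - cmp$pin_d, 0)
    e <- e + sum(cmp$pin_k * over * over)
  }
  if (length(cmp$d_a)) {
    r <- sqrt(rowSums((xyz[cmp$d_a, , drop = FALSE] -
                         xyz[cmp$d_b, , drop = FALSE])^2))
    over <- pmax(r - cmp$d_hi, 0) + pmax(cmp$d_lo - r, 0)
    e <- e + sum(cmp$d_k * over * over)
  }
  if (length(cmp$t_key)) {
    dev <- abs(rad2deg(wrap_angle(torsions[cmp$t_key] - cmp$t_ref)))
    over <- pmax(dev - cmp$t_hw, 0)
    e <- e + sum(cmp$t_k * over * over)
  }
  if (nrow(cmp$h_pairs)) {
    r <- sqrt(rowSums((xyz[cmp$h_pairs[, 1], , drop = FALSE] -
                         xyz[cmp$h_pairs[, 2], , drop = FALSE])^2))
    over <- pmax(r - cmp$h_hi, 0) + pmax(cmp$h_lo - r, 0)
    e <- e + sum(cmp$h_k * over * over)
  }
  e
}

# dependency lists: for each named torsion, the atoms that move when it
# turns (atoms whose dihedral references it, plus all their tree
# descendants), and the two atoms defining its rotation axis
.torsion_deps <- function(system) {
  cache <- system$cache
  sig <- nrow(system$atoms)
  if (!is.null(cache$tordeps) && identical(cache$tordepsig, sig))
    return(cache$tordeps)
  at <- system$atoms
  n <- nrow(at)
  kids <- split(at$idx[!is.na(at$parent)], at$parent[!is.na(at$parent)])
  descend <- function(seed) {
    out <- seed; frontier <- seed
    while (length(frontier)) {
      nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
      nxt <- setdiff(nxt, out)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  deps <- list()
  for (t in names(system$torsions)) {
    drivers <- which(!is.na(at$tor) & at$tor == t)
    if (!length(drivers)) next
    dep <- descend(drivers)
    deps[[t]] <- list(dep = sort(dep), axis = c(at$gp[drivers[1]],
                                                at$parent[drivers[1]]))
  }
  cache$tordeps <- deps
  cache$tordepsig <- sig
  deps
}

# r-derivative of the shifted pair energy, vectorized (same conventions as
# .pair_e_vec)
.pair_de_vec <- function(epsij, rmij, kqq, r, opts, nocut) {
  rc <- opts$cutoff
  dlj <- .lj_draw(epsij, rmij, r)
  dco <- .coul_draw(kqq, r)
  g <- dlj + dco
  if (is.finite(rc)) {
    inside <- r < rc & !nocut
    outside <- !nocut & !inside
    if (opts$shift_mode == "shifted_force") {
      gc <- .lj_draw(epsij, rmij, rc) + .coul_draw(kqq, rc)
      g <- ifelse(inside, g - gc, g)
    }
    g[outside] <- 0
  }
  g
}

#' Build a total-energy closure over the flexible coordinates
#'
#' Returns an objective usable by the minimizer and the MCM loop: the
#' nonbonded energy (precompiled pair table, optionally pruned to pairs
#' within cutoff + skin of the starting conformation), the restraint energy
#' and an optional extra analytic term, as a function of the flattened
#' flexible coordinate vector.  An analytic gradient (atom forces projected
#' onto the generalized coordinates) is provided for the nonbonded and
#' restraint terms.
#'
#' @param system a \code{molecular_system}.
#' @param restraints a \code{restraint_set} or NULL.
#' @param opts \code{\link{nonbonded_options}}.
#' @param exclude_rindex residues excluded from the nonbonded energy.
#' @param nonbonded include the nonbonded term (disable for analytic test
#'   potentials).
#' @param extra_energy optional \code{function(system)} returning kcal/mol
#'   (differentiated numerically).
#' @param verlet_skin with a finite cutoff, drop pairs farther than
#'   cutoff + skin at closure creation (Angstrom); \code{Inf} disables
#'   pruning.
#' @return list with \code{fn(par)}, \code{gr(par)}, \code{keys},
#'   \code{par0}, \code{with_par(par)} and \code{energy(system)}.
#' @export
system_objective <- function(system, restraints = NULL,
                             opts = nonbonded_options(),
                             exclude_rindex = NULL, nonbonded = TRUE,
                             extra_energy = NULL, verlet_skin = 4) {
  keys <- flexible_coords(system)
  cmp <- .compile_restraints(restraints)
  tab <- if (nonbonded) pair_table(system, opts, exclude_rindex) else NULL
  if (!is.null(tab) && is.finite(opts$cutoff) && is.finite(verlet_skin)) {
    xyz0 <- to_cartesian(system)
    r0 <- sqrt((xyz0[tab$i, 1] - xyz0[tab$j, 1])^2 +
                 (xyz0[tab$i, 2] - xyz0[tab$j, 2])^2 +
                 (xyz0[tab$i, 3] - xyz0[tab$j, 3])^2)
    act <- r0 < opts$cutoff + verlet_skin | tab$nocut
    tab <- lapply(tab, function(v) v[act])
  }
  if (!is.null(tab) && is.finite(opts$cutoff)) {
    # per-pair shift constants at the cutoff (hot path)
    rc <- opts$cutoff
    tab$e_rc <- .lj_raw(tab$epsij, tab$rmij, rc) + .coul_raw(tab$kqq, rc)
    tab$de_rc <- .lj_draw(tab$epsij, tab$rmij, rc) + .coul_draw(tab$kqq, rc)
  }
  n_at <- nrow(system$atoms)
  sf <- opts$shift_mode == "shifted_force"
  rc <- opts$cutoff

  pair_energy_fast <- function(r) {
    s6 <- (tab$rmij / r)^6
    e <- tab$epsij * (s6 * s6 - 2 * s6) + tab$kqq / (r * r)
    if (is.finite(rc)) {
      inside <- r < rc & !tab$nocut
      if (sf) {
        esh <- e - tab$e_rc - (r - rc) * tab$de_rc
      } else {
        esh <- e - tab$e_rc
      }
      e[inside] <- esh[inside]
      e[!inside & !tab$nocut] <- 0
    }
    e
  }
  pair_dedr_fast <- function(r) {
    s6 <- (tab$rmij / r)^6
    g <- tab$epsij * 12 * (s6 - s6 * s6) / r - 2 * tab$kqq / (r^3)
    if (is.finite(rc)) {
      inside <- r < rc & !tab$nocut
      if (sf) g[inside] <- g[inside] - tab$de_rc[inside]
      g[!inside & !tab$nocut] <- 0
    }
    g
  }

  energy_of <- function(sys) {
    xyz <- to_cartesian(sys)
    e <- 0
    if (!is.null(tab)) {
      dx <- xyz[tab$i, 1] - xyz[tab$j, 1]
      dy <- xyz[tab$i, 2] - xyz[tab$j, 2]
      dz <- xyz[tab$i, 3] - xyz[tab$j, 3]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      e <- e + sum(pair_energy_fast(r))
    }
    e <- e + .restraint_e_fast(xyz, sys$torsions, cmp)
    if (!is.null(extra_energy)) e <- e + extra_energy(sys)
    e
  }

  # per-atom Cartesian gradient dE/dr_i of nonbonded + restraint terms
  grad_atoms <- function(sys) {
    xyz <- to_cartesian(sys)
    g <- matrix(0, n_at, 3)
    if (!is.null(tab)) {
      dx <- xyz[tab$i, 1] - xyz[tab$j, 1]
      dy <- xyz[tab$i, 2] - xyz[tab$j, 2]
      dz <- xyz[tab$i, 3] - xyz[tab$j, 3]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      dEdr <- pair_dedr_fast(r)
      w <- dEdr / r
      gi <- rowsum(cbind(w * dx, w * dy, w * dz), tab$i)
      g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
      gj <- rowsum(cbind(w * dx, w * dy, w * dz), tab$j)
      g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] - gj
    }
    # pin forces
    if (length(cmp$pin_atom)) {
      dv <- xyz[cmp$pin_atom, , drop = FALSE] - cmp$pin_anchor
      dev <- sqrt(rowSums(dv^2))
      over <- pmax(dev - cmp$pin_d, 0)
      w <- ifelse(dev > 1e-12, 2 * cmp$pin_k * over / dev, 0)
      gi <- rowsum(dv * w, cmp$pin_atom)
      g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
    }
    # distance-window forces
    if (length(cmp$d_a)) {
      dv <- xyz[cmp$d_a, , drop = FALSE] - xyz[cmp$d_b, , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      over <- pmax(r - cmp$d_hi, 0) - pmax(cmp$d_lo - r, 0)
      w <- ifelse(r > 1e-12, 2 * cmp$d_k * over / r, 0)
      gi <- rowsum(dv * w, cmp$d_a)
      g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
      gj <- rowsum(dv * w, cmp$d_b)
      g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] - gj
    }
    # helix H-bond forces
    if (nrow(cmp$h_pairs)) {
      dv <- xyz[cmp$h_pairs[, 1], , drop = FALSE] -
        xyz[cmp$h_pairs[, 2], , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      over <- pmax(r - cmp$h_hi, 0) - pmax(cmp$h_lo - r, 0)
      w <- ifelse(r > 1e-12, 2 * cmp$h_k * over / r, 0)
      gi <- rowsum(dv * w, cmp$h_pairs[, 1])
      g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
      gj <- rowsum(dv * w, cmp$h_pairs[, 2])
      g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] - gj
    }
    g
  }

  deps <- if (nonbonded || !is.null(restraints)) .torsion_deps(system) else NULL

  gr_of <- function(sys) {
    ga <- grad_atoms(sys)
    xyz <- sys$cache$xyz
    out <- numeric(nrow(keys))
    at <- sys$atoms
    for (k in seq_len(nrow(keys))) {
      type <- keys$type[k]; key <- keys$key[k]; comp <- keys$comp[k]
      if (type == "torsion") {
        d <- deps[[key]]
        if (is.null(d)) next
        p1 <- xyz[d$axis[1], ]; p2 <- xyz[d$axis[2], ]
        u <- unit(p2 - p1)
        rel <- sweep(xyz[d$dep, , drop = FALSE], 2, p2)
        # velocity of dependent atoms per unit torsion change: -(u x rel)
        vel <- -cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                      u[3] * rel[, 1] - u[1] * rel[, 3],
                      u[1] * rel[, 2] - u[2] * rel[, 1])
        out[k] <- sum(ga[d$dep, , drop = FALSE] * vel)
        # torsion-window direct term
        if (length(cmp$t_key)) {
          hit <- which(cmp$t_key == key)
          for (h in hit) {
            devd <- rad2deg(wrap_angle(sys$torsions[[key]] - cmp$t_ref[h]))
            over <- sign(devd) * pmax(abs(devd) - cmp$t_hw[h], 0)
            out[k] <- out[k] + 2 * cmp$t_k[h] * over * rad2deg(1)
          }
        }
      } else if (type == "root_pos") {
        rows <- .seg_atoms(sys, key)
        out[k] <- sum(ga[rows, comp])
      } else if (type == "root_euler") {
        rows <- .seg_atoms(sys, key)
        rt <- sys$roots[[key]]
        L <- sys$cache$local[[key]]
        h <- 1e-6
        ep <- rt$euler; em <- rt$euler
        ep[comp] <- ep[comp] + h; em[comp] <- em[comp] - h
        A <- (euler_to_rot(ep) - euler_to_rot(em)) / (2 * h)
        out[k] <- sum(ga[rows, , drop = FALSE] * (L %*% t(A)))
      } else {
        # flexible bond angle: numerical (few of these)
        par <- get_par(sys, keys)
        hh <- 1e-5
        pp <- par; pp[k] <- pp[k] + hh
        pm <- par; pm[k] <- pm[k] - hh
        out[k] <- (energy_of(set_par(sys, pp, keys)) -
                     energy_of(set_par(sys, pm, keys))) / (2 * hh)
      }
    }
    out
  }

  cur <- system
  fn <- function(par) {
    cur <<- set_par(cur, par, keys)
    energy_of(cur)
  }
  gr <- function(par) {
    cur <<- set_par(cur, par, keys)
    g <- gr_of(cur)
    if (!is.null(extra_energy)) {
      h <- 1e-5
      for (k in seq_len(nrow(keys))) {
        pp <- par; pp[k] <- pp[k] + h
        pm <- par; pm[k] <- pm[k] - h
        g[k] <- g[k] + (extra_energy(set_par(cur, pp, keys)) -
                          extra_energy(set_par(cur, pm, keys))) / (2 * h)
      }
    }
    g
  }
  list(fn = fn, gr = gr, keys = keys, par0 = get_par(system, keys),
       with_par = function(par) set_par(system, par, keys),
       energy = energy_of)
}

#' Bounded local energy minimization over flexible coordinates
#'
#' Quasi-Newton (L-BFGS-B with numerical gradients) minimization of the
#' total energy.  The returned energy never exceeds the starting energy; the
#' iteration cap bounds the work per call.
#'
#' @param system a \code{molecular_system}.
#' @param restraints a \code{restraint_set} or NULL.
#' @param max_iter iteration cap (0 returns the input unchanged).
#' @param opts \code{\link{nonbonded_options}}.
#' @param ... passed to \code{\link{system_objective}}.
#' @return list with \code{system}, \code{energy} and \code{start_energy}.
#' @export
local_minimize <- function(system, restraints = NULL, max_iter = 200,
                           opts = nonbonded_options(), ...) {
  obj <- system_objective(system, restraints, opts, ...)
  if (nrow(obj$keys) == 0) stop("no flexible coordinates to minimize")
  e0 <- obj$energy(system)
  if (!is.finite(e0)) {
    xyz <- to_cartesian(system)
    d <- as.matrix(stats::dist(xyz)); diag(d) <- Inf
    w <- which(d == min(d), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite starting energy (closest atoms %d and %d at %.4f A)",
                 w[1], w[2], min(d)))
  }
  if (max_iter == 0)
    return(list(system = system, energy = e0, start_energy = e0))
  res <- tryCatch(
    stats::optim(obj$par0, obj$fn, obj$gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = 1e7, lmm = 20)),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$value > e0)
    return(list(system = system, energy = e0, start_energy = e0))
  list(system = obj$with_par(res$par), energy = res$value, start_energy = e0)
}

#' Propose a random perturbation of one flexible coordinate
#'
#' Draws one flexible scalar coordinate uniformly and perturbs it: torsions
#' are resampled uniformly in (-180, 180] (or nudged by a Gaussian,
#' configurable), root positions by a Gaussian of sigma 0.5 Angstrom per
#' component, root orientations by a Gaussian of sigma 10 degrees, flexible
#' bond angles by a Gaussian of sigma 2 degrees.  Consumes the R RNG stream,
#' so runs are reproducible under a fixed seed.
#'
#' @param system a \code{molecular_system}.
#' @param config an \code{mcm_config}.
#' @return list with the perturbed \code{system} and the picked \code{key} row.
#' @export
propose_move <- function(system, config = mcm_config()) {
  keys <- flexible_coords(system)
  if (nrow(keys) == 0) stop("system has no flexible coordinates")
  segs <- unique(keys$key[keys$type == "root_pos"])
  if (length(segs) && stats::runif(1) < config$segment_move_prob) {
    seg <- segs[sample.int(length(segs), 1)]
    rt <- system$roots[[seg]]
    system <- .set_root_rad(
      system, seg,
      rt$pos + stats::rnorm(3, 0, config$segment_pos_sigma),
      rt$euler + stats::rnorm(3, 0, deg2rad(config$segment_euler_sigma)))
    return(list(system = system,
                key = data.frame(type = "segment", key = seg, comp = 0L)))
  }
  pick <- sample.int(nrow(keys), 1)
  row <- keys[pick, ]
  par <- get_par(system, keys)
  par[pick] <- switch(row$type,
    torsion = if (config$torsion_resample)
      stats::runif(1, -pi, pi) else
        par[pick] + stats::rnorm(1, 0, deg2rad(config$torsion_sigma)),
    root_pos = par[pick] + stats::rnorm(1, 0, config$root_pos_sigma),
    root_euler = par[pick] + stats::rnorm(1, 0, deg2rad(config$euler_sigma)),
    angle = par[pick] + stats::rnorm(1, 0, deg2rad(config$angle_sigma)))
  list(system = set_par(system, par, keys), key = row)
}

# convergence rule: given the running sequence of minimized energies, did the
# last `window` minimizations fail to improve the lowest energy seen before
# them?  Exposed for direct testing with injected sequences.
#' Windowed no-improvement convergence rule
#'
#' Returns the 1-based index of the minimization at which a trajectory
#' terminates: the first position where the preceding \code{window}
#' minimizations produced no new lowest energy, or \code{NA} if the rule
#' never fires within the sequence.
#'
#' @param energies numeric vector of minimized energies in trajectory order.
#' @param window convergence window length.
#' @export
convergence_index <- function(energies, window) {
  best <- Inf; last_improve <- 0L
  for (i in seq_along(energies)) {
    if (energies[i] < best - 1e-12) {
      best <- energies[i]
      last_improve <- i
    }
    if (i - last_improve >= window) return(i)
  }
  NA_integer_
}

#' Run a Monte Carlo minimization trajectory
#'
#' @param system a \code{molecular_system} (its flexible mask defines the
#'   search space).
#' @param restraints a \code{restraint_set} or NULL.
#' @param config an \code{mcm_config}.
#' @param opts \code{\link{nonbonded_options}}.
#' @param nonbonded,extra_energy see \code{\link{system_objective}}.
#' @param exclude_rindex residues excluded from the nonbonded energy.
#' @param max_iter overrides \code{config$max_min_iterations}.
#' @return an \code{mcm_trajectory}: list with \code{accepted} (data.frame of
#'   accepted minimized energies), \code{lowest} (list: \code{system},
#'   \code{energy}), \code{n_minimizations}, \code{converged}, \code{config}.
#' @export
run_mcm <- function(system, restraints = NULL, config = mcm_config(),
                    opts = nonbonded_options(), nonbonded = TRUE,
                    extra_energy = NULL, exclude_rindex = NULL,
                    max_iter = NULL) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(max_iter)) max_iter <- config$max_min_iterations
  kT <- KBOLTZ * config$temperature

  minimize <- function(sys) local_minimize(sys, restraints, max_iter, opts,
                                           nonbonded = nonbonded,
                                           extra_energy = extra_energy,
                                           exclude_rindex = exclude_rindex)
  cur <- minimize(system)
  best <- cur
  energies <- cur$energy
  acc <- data.frame(n_min = 1L, energy = cur$energy, accepted = TRUE)
  n_min <- 1L
  last_improve <- 1L
  converged <- FALSE
  while (n_min < config$max_minimizations) {
    prop <- propose_move(cur$system, config)
    cand <- minimize(prop$system)
    n_min <- n_min + 1L
    energies <- c(energies, cand$energy)
    dE <- cand$energy - cur$energy
    accept <- dE < 0 || stats::runif(1) < exp(-dE / kT)
    if (accept) cur <- cand
    acc <- rbind(acc, data.frame(n_min = n_min, energy = cand$energy,
                                 accepted = accept))
    if (cand$energy < best$energy - 1e-12) {
      best <- cand
      last_improve <- n_min
    }
    if (n_min - last_improve >= config$convergence_window) {
      converged <- TRUE
      break
    }
  }
  structure(list(accepted = acc[acc$accepted, c("n_min", "energy")],
                 proposals = acc,
                 lowest = list(system = best$system, energy = best$energy),
                 n_minimizations = n_min, converged = converged,
                 config = config),
            class = "mcm_trajectory")
}

#' @export
print.mcm_trajectory <- function(x, ...) {
  cat(sprintf(paste0("mcm_trajectory: %d minimizations, %d accepted, lowest",
                     " %.4f kcal/mol, %sconverged\n"),
              x$n_minimizations, nrow(x$accepted), x$lowest$energy,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.mcm_trajectory <- function(object, ...) {
  print(object)
  e <- object$proposals$energy
  cat(sprintf("  energy: start %.4f, median %.4f, lowest %.4f\n",
              e[1], stats::median(e), object$lowest$energy))
  invisible(object)
}

#' Define a steering schedule
#'
#' @param targeted_atoms integer atom indices (alpha carbons) to steer.
#' @param start_anchors,end_anchors matrices (n x 3) of start and target
#'   positions for the targeted atoms.
#' @param half_width penalty-free half-width of the per-stage target
#'   restraints, Angstrom.
#' @param k force constant of the target restraints, kcal/mol/A^2.
#' @param n_stages number of linear interpolation stages (NULL: use config).
#' @export
steer_schedule <- function(targeted_atoms, start_anchors, end_anchors,
                           half_width = 0.3, k = 10, n_stages = NULL) {
  start_anchors <- as.matrix(start_anchors); end_anchors <- as.matrix(end_anchors)
  if (nrow(start_anchors) != length(targeted_atoms) ||
      nrow(end_anchors) != length(targeted_atoms))
    stop("anchor matrices must have one row per targeted atom")
  structure(list(targeted_atoms = as.integer(targeted_atoms),
                 start_anchors = start_anchors, end_anchors = end_anchors,
                 half_width = half_width, k = k, n_stages = n_stages),
            class = "steer_schedule")
}

#' Steered MCM: walk targeted atoms to end anchors through staged restraints
#'
#' Anchors are interpolated linearly over the stages; each stage runs a short
#' MCM leg whose local minimizations are capped at
#' \code{config$steered_max_min_iterations} so consecutive accepted points
#' stay structurally close.  The final stage runs with the convergence
#' window, after which an unconstrained stability leg is computed and the
#' alpha-carbon drift it causes is reported.
#'
#' @param system a \code{molecular_system}.
#' @param schedule a \code{\link{steer_schedule}}.
#' @param restraints companion static restraints (helix restraints, torsion
#'   windows, pins on non-steered groups, separation caps).
#' @param config an \code{mcm_config}.
#' @param opts \code{\link{nonbonded_options}}.
#' @param stability_minimizations length of the stability leg run after the
#'   steering restraints are released (0 skips it).
#' @param stability_restraints restraints retained during the stability leg
#'   (terms that play the role of bonded interactions, e.g. the toy
#'   channel's loop-connectivity stand-ins); the steering targets and all
#'   companion restraints are dropped.
#' @return a \code{steered_result}: list with \code{system} (steered,
#'   post-stability), \code{steered_system} (before the stability leg),
#'   \code{stage_log} (data.frame), \code{target_dev} (final per-atom
#'   distances to end anchors), \code{ca_drift} (per-CA drift of the
#'   stability leg), \code{converged}.
#' @export
run_steered <- function(system, schedule, restraints = NULL,
                        config = mcm_config(), opts = nonbonded_options(),
                        stability_minimizations = 10,
                        stability_restraints = NULL) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  ta <- schedule$targeted_atoms
  if (any(ta < 1 | ta > nrow(system$atoms)))
    stop("targeted atom index outside system")
  n_stages <- if (!is.null(schedule$n_stages)) schedule$n_stages else
    config$n_stages
  cur <- system
  stage_rows <- list()
  converged <- FALSE
  for (stage in seq_len(n_stages)) {
    f <- stage / n_stages
    anchors <- schedule$start_anchors * (1 - f) + schedule$end_anchors * f
    pins <- lapply(seq_along(ta), function(i)
      pin_restraint(ta[i], anchors[i, ], d = schedule$half_width,
                    k = schedule$k, label = "steer"))
    rset <- merge_restraints(restraint_set(pins = pins),
                             if (is.null(restraints)) restraint_set() else
                               restraints)
    last <- stage == n_stages
    cfg <- config
    cfg$rng_seed <- NULL  # seed consumed once at entry
    if (!last) {
      cfg$convergence_window <- config$stage_proposals + 1L
      cfg$max_minimizations <- config$stage_proposals
    }
    # relaxation leg: deeper minimizations absorb the anchor step before
    # the short-capped MCM leg samples around it
    for (p in 1:4) {
      deep <- local_minimize(cur, rset,
                             3L * config$steered_max_min_iterations, opts)
      done <- deep$start_energy - deep$energy < 1
      cur <- deep$system
      if (done) break
    }
    traj <- run_mcm(cur, rset, cfg, opts,
                    max_iter = config$steered_max_min_iterations)
    # within a stage, continue from the lowest-energy point found
    cur <- traj$lowest$system
    xyz <- to_cartesian(cur)
    dev <- sqrt(rowSums((xyz[ta, , drop = FALSE] - anchors)^2))
    stage_rows[[stage]] <- data.frame(
      stage = stage, n_min = traj$n_minimizations,
      energy = traj$lowest$energy, max_target_dev = max(dev))
    if (last) converged <- traj$converged
  }
  # convergence tail: deep minimizations under the final-stage restraints
  # until the energy settles (the production protocol runs its final leg to
  # an exhaustive no-improvement window)
  final_anchors <- schedule$end_anchors
  final_pins <- lapply(seq_along(ta), function(i)
    pin_restraint(ta[i], final_anchors[i, ], d = schedule$half_width,
                  k = schedule$k, label = "steer"))
  final_rset <- merge_restraints(restraint_set(pins = final_pins),
                                 if (is.null(restraints)) restraint_set()
                                 else restraints)
  for (p in 1:6) {
    deep <- local_minimize(cur, final_rset,
                           6L * config$steered_max_min_iterations, opts)
    done <- deep$start_energy - deep$energy < 0.5
    cur <- deep$system
    if (done) break
  }
  steered <- cur
  xyz_st <- to_cartesian(steered)
  target_dev <- sqrt(rowSums((xyz_st[ta, , drop = FALSE] -
                                schedule$end_anchors)^2))
  ca_idx <- which(system$atoms$name == "CA")
  ca_drift <- NULL
  if (stability_minimizations > 0) {
    cfg <- config
    cfg$rng_seed <- NULL
    cfg$convergence_window <- stability_minimizations + 1L
    cfg$max_minimizations <- stability_minimizations
    stab <- run_mcm(steered, stability_restraints, cfg, opts,
                    max_iter = config$steered_max_min_iterations)
    cur <- stab$lowest$system
    xyz_fin <- to_cartesian(cur)
    ca_drift <- sqrt(rowSums((xyz_fin[ca_idx, , drop = FALSE] -
                                xyz_st[ca_idx, , drop = FALSE])^2))
  }
  structure(list(system = cur, steered_system = steered,
                 stage_log = do.call(rbind, stage_rows),
                 target_dev = target_dev, ca_drift = ca_drift,
                 converged = converged),
            class = "steered_result")
}

#' @export
print.steered_result <- function(x, ...) {
  cat(sprintf(paste0("steered_result: %d stages, final max target deviation",
                     " %.3f A, %sconverged\n"),
              nrow(x$stage_log), max(x$target_dev),
              if (x$converged) "" else "NOT "))
  if (!is.null(x$ca_drift))
    cat(sprintf("  stability leg CA drift: mean %.3f A, max %.3f A\n",
                mean(x$ca_drift), max(x$ca_drift)))
  invisible(x)
}

#' Write an MCM trajectory log as JSONL
#'
#' One record per minimization: \code{n_min}, \code{energy},
#' \code{accepted}, \code{lowest_so_far}.
#' @param trajectory an \code{mcm_trajectory}.
#' @param path output file.
#' @export
write_trajectory_jsonl <- function(trajectory, path) {
  pr <- trajectory$proposals
  lows <- cummin(pr$energy)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pr))) {
    writeLines(jsonlite::toJSON(list(n_min = pr$n_min[i],
                                     energy = pr$energy[i],
                                     accepted = pr$accepted[i],
                                     lowest_so_far = lows[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
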