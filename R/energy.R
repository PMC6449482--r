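# Nonbonded energy: Lennard-Jones 6-12 plus Coulomb with a distance-dependent
# dielectric eps(r) = slope * r, truncated at a cutoff with a shifting
# function.  Pairs in which both atoms belong to ionized groups bypass the
# cutoff entirely.  1-2 and 1-3 bonded pairs are excluded, 1-4 pairs scaled.
# Energies decompose exactly into residue-pair contributions.

COULOMB_K <- 332.06  # kcal*Angstrom/(mol*e^2)

#' Nonbonded interaction options
#'
#' @param cutoff distance cutoff, Angstrom.
#' @param dielectric_slope slope of the distance-dependent dielectric
#'   eps(r) = slope * r (dimensionless per Angstrom).
#' @param shift_mode \code{"shifted_force"} (energy and derivative vanish at
#'   the cutoff) or \code{"shifted_energy"} (energy only).
#' @param ionized_no_cutoff if TRUE, pairs where both atoms carry ionized-
#'   group membership are computed without any cutoff.
#' @param scale14 scale factor applied to 1-4 bonded pairs.
#' @return a \code{nonbonded_options} list.
#' @export
nonbonded_options <- function(cutoff = 9, dielectric_slope = 4,
                              shift_mode = c("shifted_force", "shifted_energy"),
                              ionized_no_cutoff = TRUE, scale14 = 0.5) {
  shift_mode <- match.arg(shift_mode)
  stopifnot(cutoff > 0, dielectric_slope > 0)
  structure(list(cutoff = cutoff, dielectric_slope = dielectric_slope,
                 shift_mode = shift_mode,
                 ionized_no_cutoff = ionized_no_cutoff, scale14 = scale14),
            class = "nonbonded_options")
}

# raw (unshifted) pair terms and their r-derivatives, vectorized
.lj_raw <- function(epsij, rmij, r) {
  s6 <- (rmij / r)^6
  epsij * (s6 * s6 - 2 * s6)
}
.lj_draw <- function(epsij, rmij, r) {
  s6 <- (rmij / r)^6
  epsij * 12 * (s6 - s6 * s6) / r
}
.coul_raw <- function(kqq, r) kqq / (r * r)       # kqq = K q_i q_j / slope
.coul_draw <- function(kqq, r) -2 * kqq / (r^3)

# shifted pair energy for vectors of parameters; pairs flagged nocut skip the
# cutoff and the shift
.pair_e_vec <- function(epsij, rmij, kqq, r, opts, nocut,
                        split = FALSE) {
  rc <- opts$cutoff
  elj <- .lj_raw(epsij, rmij, r)
  eco <- .coul_raw(kqq, r)
  if (is.finite(rc)) {
    inside <- r < rc & !nocut
    outside <- !nocut & !inside
    # shift: subtract value (and, in shifted_force mode, the linear term)
    ljc <- .lj_raw(epsij, rmij, rc)
    coc <- .coul_raw(kqq, rc)
    if (opts$shift_mode == "shifted_force") {
      dljc <- .lj_draw(epsij, rmij, rc)
      dcoc <- .coul_draw(kqq, rc)
      elj <- ifelse(inside, elj - ljc - (r - rc) * dljc, elj)
      eco <- ifelse(inside, eco - coc - (r - rc) * dcoc, eco)
    } else {
      elj <- ifelse(inside, elj - ljc, elj)
      eco <- ifelse(inside, eco - coc, eco)
    }
    elj[outside] <- 0
    eco[outside] <- 0
  }
  if (split) list(lj = elj, coul = eco) else elj + eco
}

#' Nonbonded energy of one atom pair
#'
#' Lennard-Jones 6-12 with arithmetic rmin / geometric epsilon combining
#' rules plus Coulomb with the distance-dependent dielectric
#' eps(r) = slope * r.  Truncated and shifted at the cutoff unless both atoms
#' are members of ionized groups (and \code{ionized_no_cutoff} is set).
#'
#' @param atom_i,atom_j lists or single-row data.frames with fields \code{q},
#'   \code{eps} (kcal/mol), \code{rmin2} (Angstrom) and \code{ionized}.
#' @param r interatomic distance, Angstrom (> 0).
#' @param opts \code{\link{nonbonded_options}}.
#' @return energy in kcal/mol.
#' @export
pair_energy <- function(atom_i, atom_j, r, opts = nonbonded_options()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  epsij <- sqrt(atom_i$eps * atom_j$eps)
  rmij <- atom_i$rmin2 + atom_j$rmin2
  kqq <- COULOMB_K * atom_i$q * atom_j$q / opts$dielectric_slope
  nocut <- isTRUE(opts$ionized_no_cutoff) &&
    isTRUE(atom_i$ionized) && isTRUE(atom_j$ionized)
  .pair_e_vec(epsij, rmij, kqq, r, opts, rep(nocut, length(r)))
}

# bonded-separation exclusion table: returns for all i<j candidate pairs a
# code 0 (excluded: separation 1 or 2 bonds), s14 (3 bonds) or 1.
.bond_graph <- function(system) {
  n <- nrow(system$atoms)
  p <- system$atoms$parent
  e1 <- cbind(which(!is.na(p)), p[!is.na(p)])
  edges <- rbind(e1, system$extra_bonds)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# set of atom-pair codes within 3 bonds, as named integer vector keyed i*n+j
.separation_codes <- function(system) {
  cache <- system$cache
  sig <- paste(nrow(system$atoms), nrow(system$extra_bonds))
  if (!is.null(cache$sepcodes) && identical(cache$sepsig, sig))
    return(cache$sepcodes)
  adj <- .bond_graph(system)
  n <- length(adj)
  keys <- integer(0); codes <- integer(0)
  for (a in seq_len(n)) {
    n1 <- adj[[a]]
    n2 <- unique(unlist(adj[n1]))
    n3 <- unique(unlist(adj[n2]))
    for (lvl in 1:3) {
      nb <- switch(lvl, n1, setdiff(n2, c(a, n1)),
                   setdiff(n3, c(a, n1, n2)))
      nb <- nb[nb > a]
      if (length(nb)) {
        keys <- c(keys, (a - 1) * n + nb)
        codes <- c(codes, rep(lvl, length(nb)))
      }
    }
  }
  sep <- codes[!duplicated(keys)]
  names(sep) <- keys[!duplicated(keys)]
  # keep the smallest separation for duplicated pairs
  o <- order(as.numeric(names(sep)))
  sep <- sep[o]
  cache$sepcodes <- sep
  cache$sepsig <- sig
  sep
}

# Precomputed pair table: all i<j atom pairs with combined parameters,
# exclusions applied.  Depends on topology only, cached on the system.
pair_table <- function(system, opts = nonbonded_options(),
                       exclude_rindex = NULL) {
  cache <- system$cache
  sig <- paste(nrow(system$atoms), nrow(system$extra_bonds),
               opts$dielectric_slope, opts$scale14,
               paste(exclude_rindex, collapse = ","))
  if (!is.null(cache$pairtab) && identical(cache$pairsig, sig))
    return(cache$pairtab)
  at <- system$atoms
  n <- nrow(at)
  keep <- seq_len(n)
  if (length(exclude_rindex))
    keep <- keep[!(at$rindex %in% exclude_rindex)]
  m <- length(keep)
  # all i<j pairs over `keep`
  ii <- unlist(lapply(seq_len(m - 1), function(k) rep(keep[k], m - k)))
  jj <- unlist(lapply(seq_len(m - 1), function(k) keep[(k + 1):m]))
  sep <- .separation_codes(system)
  pk <- (ii - 1) * n + jj
  code <- sep[as.character(pk)]
  code[is.na(code)] <- 99L
  scale <- ifelse(code <= 2, 0, ifelse(code == 3, opts$scale14, 1))
  live <- scale > 0
  ii <- ii[live]; jj <- jj[live]; scale <- scale[live]
  tab <- list(
    i = ii, j = jj,
    epsij = sqrt(at$eps[ii] * at$eps[jj]) * scale,
    rmij = at$rmin2[ii] + at$rmin2[jj],
    kqq = COULOMB_K * at$q[ii] * at$q[jj] / opts$dielectric_slope * scale,
    nocut = isTRUE(opts$ionized_no_cutoff) & at$ionized[ii] & at$ionized[jj],
    ri = at$rindex[ii], rj = at$rindex[jj])
  cache$pairtab <- tab
  cache$pairsig <- sig
  tab
}

#' Total nonbonded energy with residue-pair decomposition
#'
#' @param system a \code{molecular_system} (the Cartesian cache is refreshed
#'   automatically).
#' @param opts \code{\link{nonbonded_options}}.
#' @param group_filter optional character pair: restrict to atom pairs with
#'   one residue in each of the two segment groups or segment-id sets (see
#'   \code{groups_as}).
#' @param groups_as interpret \code{group_filter} entries as segment
#'   \code{"group"} labels or as \code{"segment"} id vectors (then
#'   \code{group_filter} is a list of two character vectors).
#' @param exclude_rindex residues excluded from the energy entirely (the
#'   double-shell "outside" region).
#' @param breakdown if TRUE, return per-residue-pair energies.
#' @return an \code{energy_breakdown}: list with \code{total}, \code{lj},
#'   \code{coul} and (optionally) \code{per_pair} data.frame with columns
#'   \code{rindex_i}, \code{rindex_j}, \code{E_lj}, \code{E_coul},
#'   \code{E_total}.
#' @export
nonbonded_energy <- function(system, opts = nonbonded_options(),
                             group_filter = NULL,
                             groups_as = c("group", "segment"),
                             exclude_rindex = NULL, breakdown = TRUE) {
  groups_as <- match.arg(groups_as)
  xyz <- to_cartesian(system)
  tab <- pair_table(system, opts, exclude_rindex)
  sel <- TRUE
  if (!is.null(group_filter)) {
    res <- system$residues
    key <- if (groups_as == "group") res$group else res$segment
    in_a <- key[tab$ri] %in% group_filter[[1]]
    in_b <- key[tab$rj] %in% group_filter[[2]]
    in_a2 <- key[tab$rj] %in% group_filter[[1]]
    in_b2 <- key[tab$ri] %in% group_filter[[2]]
    sel <- (in_a & in_b) | (in_a2 & in_b2)
    if (any(key[tab$ri] %in% group_filter[[1]] &
            key[tab$ri] %in% group_filter[[2]]))
      stop("group_filter groups overlap")
  }
  i <- tab$i[sel]; j <- tab$j[sel]
  dx <- xyz[i, 1] - xyz[j, 1]
  dy <- xyz[i, 2] - xyz[j, 2]
  dz <- xyz[i, 3] - xyz[j, 3]
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  e <- .pair_e_vec(tab$epsij[sel], tab$rmij[sel], tab$kqq[sel], r, opts,
                   tab$nocut[sel], split = TRUE)
  out <- list(total = sum(e$lj) + sum(e$coul), lj = sum(e$lj),
              coul = sum(e$coul))
  if (breakdown) {
    # pairs truncated to zero by the cutoff carry no information
    nz <- e$lj != 0 | e$coul != 0
    e$lj <- e$lj[nz]; e$coul <- e$coul[nz]
    key <- paste(tab$ri[sel][nz], tab$rj[sel][nz])
    lj <- rowsum(e$lj, key)
    co <- rowsum(e$coul, key)
    parts <- do.call(rbind, strsplit(rownames(lj), " "))
    out$per_pair <- data.frame(
      rindex_i = as.integer(parts[, 1]), rindex_j = as.integer(parts[, 2]),
      E_lj = as.numeric(lj), E_coul = as.numeric(co),
      E_total = as.numeric(lj) + as.numeric(co))
  }
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("nonbonded energy: %.4f kcal/mol (LJ %.4f, Coulomb %.4f)\n",
              x$total, x$lj, x$coul))
  if (!is.null(x$per_pair))
    cat("  residue pairs with nonzero energy:", nrow(x$per_pair), "\n")
  invisible(x)
}

#' Export per-pair energies as TSV
#'
#' Columns: chain_i, res_i, chain_j, res_j, E_LJ, E_coul, E_total.
#' @param system the system the breakdown was computed from.
#' @param breakdown an \code{energy_breakdown} with \code{per_pair}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pair_energies <- function(system, breakdown, path) {
  pp <- breakdown$per_pair
  if (is.null(pp)) stop("breakdown has no per-pair data")
  res <- system$residues
  df <- data.frame(chain_i = res$segment[pp$rindex_i],
                   res_i = res$resid[pp$rindex_i],
                   chain_j = res$segment[pp$rindex_j],
                   res_j = res$resid[pp$rindex_j],
                   E_LJ = pp$E_lj, E_coul = pp$E_coul, E_total = pp$E_total)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
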