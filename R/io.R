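# Readers and writers: PDB (through bio3d), FASTA alignments, YAML run
# configuration, provenance records, and atomic file writes.

#' Read a PDB file into a structure skeleton
#'
#' Parses ATOM/HETATM records (via bio3d), keeping for each alternate-
#' location group only the highest-occupancy conformer, preserving insertion
#' codes, and flagging (not dropping) residues with missing backbone atoms.
#'
#' @param path PDB file.
#' @return a \code{pdb_skeleton}: list with \code{atoms} (data.frame: name,
#'   resname, chain, resid, insert, segid, occupancy, b), \code{xyz}
#'   (n x 3 matrix, Angstrom) and \code{flagged_residues} (residues lacking
#'   N, CA or C).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  short <- which(rec & nchar(lines) < 54)
  if (length(short))
    stop("malformed ATOM/HETATM record at line ", short[1],
         " (truncated: ", nchar(lines[short[1]]), " characters)")
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  # altloc policy: highest occupancy per (chain, resno, insert, atom name)
  at$o[is.na(at$o)] <- 1
  grp <- paste(at$chain, at$resno, at$insert, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(ix) {
    ix[which.max(at$o[ix])]
  }), use.names = FALSE)
  keep <- sort(keep)
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(name = at$elety, resname = at$resid, chain = at$chain,
                      resid = at$resno, insert = at$insert,
                      segid = ifelse(is.na(at$segid) | at$segid == "",
                                     at$chain, at$segid),
                      occupancy = at$o, b = at$b, stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  rkey <- paste(atoms$chain, atoms$resid, atoms$insert)
  flagged <- unique(rkey[!vapply(split(atoms$name, rkey)[rkey], function(nm)
    all(c("N", "CA", "C") %in% nm), logical(1))])
  structure(list(atoms = atoms, xyz = xyz, flagged_residues = flagged),
            class = "pdb_skeleton")
}

#' Write a system or skeleton as PDB
#'
#' @param x a \code{molecular_system}, \code{state_model} or
#'   \code{pdb_skeleton}.
#' @param path output file (written atomically: temp file + rename).
#' @return the path, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "state_model")) x <- x$system
  tmp <- paste0(path, ".tmp")
  if (inherits(x, "molecular_system")) {
    xyz <- to_cartesian(x)
    at <- x$atoms
    chains <- LETTERS[match(at$segment, names(x$roots)) %% 26 + 1]
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(xyz)), resno = at$resid,
                     resid = at$resname, elety = at$name, chain = chains,
                     segid = substr(at$segment, 1, 4),
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  } else if (inherits(x, "pdb_skeleton")) {
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(x$xyz)),
                     resno = x$atoms$resid, resid = x$atoms$resname,
                     elety = x$atoms$name, chain = x$atoms$chain,
                     segid = x$atoms$segid, o = x$atoms$occupancy,
                     b = x$atoms$b)
  } else stop("cannot write object of class ", class(x)[1])
  file.rename(tmp, path)
  invisible(path)
}

#' Percent sequence identity of a pairwise alignment
#'
#' Reads an aligned FASTA file (two sequences of equal length, gaps as
#' \code{-}) or takes two aligned character strings, and returns the
#' percent identity over columns where both sequences have residues,
#' optionally restricted to a span of (ungapped) positions of the first
#' sequence.
#'
#' @param x path to an aligned FASTA file, or a character vector of two
#'   aligned sequences.
#' @param span optional integer range of positions in the first sequence
#'   (1-based, ungapped numbering) over which to compute identity.
#' @return percent identity (0-100).
#' @export
alignment_identity <- function(x, span = NULL) {
  if (length(x) == 1 && file.exists(x)) {
    fa <- seqinr::read.fasta(x, seqtype = "AA", as.string = TRUE)
    if (length(fa) < 2) stop("alignment needs two sequences")
    x <- toupper(c(as.character(fa[[1]]), as.character(fa[[2]])))
  }
  a <- strsplit(x[1], "")[[1]]
  b <- strsplit(x[2], "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences differ in length")
  posa <- cumsum(a != "-")
  cols <- a != "-" & b != "-"
  if (!is.null(span)) cols <- cols & posa >= min(span) & posa <= max(span)
  if (!any(cols)) stop("no aligned columns in the requested span")
  100 * sum(a[cols] == b[cols]) / sum(cols)
}

# ---- configuration ---------------------------------------------------------

#' Default hierarchical run configuration
#'
#' Keys: \code{energy} (see \code{\link{nonbonded_options}}), \code{mcm}
#' (see \code{\link{mcm_config}}), \code{contacts} (presence floor, bin
#' scheme), \code{toy} (see \code{\link{toy_channel_spec}}), \code{seed},
#' \code{output_dir}.
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    energy = list(cutoff = 9, dielectric_slope = 4,
                  shift_mode = "shifted_force", ionized_no_cutoff = TRUE,
                  scale14 = 0.5),
    mcm = list(temperature = 600, max_min_iterations = 1000,
               steered_max_min_iterations = 100, convergence_window = 2000,
               max_minimizations = 10000, stage_accept = 50,
               stage_proposals = 500, n_stages = 10),
    contacts = list(presence_floor = 0.4, scheme = "fourbin"),
    toy = list(n_repeats = 4, s5_len = 12, s6_len = 12, open_radius = 6.0,
               closed_radius = 2.5, aid_len = 12, bp_len = 10, iis0_len = 8))
}

#' Read a YAML run configuration, merging over the defaults
#'
#' Unknown keys are rejected; the resolved configuration should be
#' serialized next to stage outputs (see \code{\link{write_run_outputs}}).
#'
#' @param path YAML file (NULL returns the defaults).
#' @return resolved configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  merge_into(cfg, user)
}

# constructors from a resolved config
.opts_from_config <- function(cfg) do.call(nonbonded_options, cfg$energy)
.mcm_from_config <- function(cfg, seed = cfg$seed) {
  c2 <- cfg$mcm; c2$rng_seed <- as.integer(seed)
  do.call(mcm_config, c2)
}

#' Write stage outputs with provenance, atomically
#'
#' Writes the resolved configuration (YAML) and a provenance record (JSON:
#' tool version, config hash, seed, input digests, stage id) into the
#' output directory alongside the stage outputs.
#'
#' @param dir output directory (created if needed).
#' @param stage stage id string.
#' @param config resolved configuration list.
#' @param inputs named character vector of input file paths (digested).
#' @return provenance list, invisibly.
#' @export
write_run_outputs <- function(dir, stage, config, inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.resolved.yaml")
  tmp <- paste0(cfg_path, ".tmp")
  yaml::write_yaml(config, tmp)
  file.rename(tmp, cfg_path)
  prov <- list(
    tool_version = .pkg_version(),
    stage = stage,
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    input_digests = as.list(if (length(inputs))
      tools::md5sum(inputs) else character()))
  pv_path <- file.path(dir, "provenance.json")
  tmp <- paste0(pv_path, ".tmp")
  jsonlite::write_json(prov, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, pv_path)
  invisible(prov)
}
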