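# Built-in united-atom amino-acid topology.
#
# The library follows the united-atom lineage of classic protein force fields:
# aliphatic hydrogens are merged into their carbons, polar hydrogens (on N, O,
# S) are explicit.  Parameters (partial charges, Lennard-Jones epsilon and
# rmin/2) form a self-consistent set: neutral residues have zero net sidechain
# charge, ionized sidechains carry integer formal charge on the charged group.
# Geometry is encoded as a z-matrix per residue: each sidechain atom is placed
# from its parent by a rigid bond length and bond angle plus a dihedral that is
# either a named flexible torsion (chi1, chi2, ...) or a fixed offset from one.

# Lennard-Jones atom classes: rmin/2 (Angstrom) and epsilon (kcal/mol)
.lj_classes <- list(
  N   = c(1.750, 0.160),   # amide / aromatic nitrogen
  Hp  = c(0.600, 0.020),   # polar hydrogen
  C   = c(1.850, 0.120),   # carbonyl / carboxylate / guanidinium carbon
  CR  = c(1.950, 0.110),   # aromatic CH (united)
  CH1 = c(2.000, 0.090),
  CH2 = c(1.925, 0.120),
  CH3 = c(2.000, 0.150),
  O   = c(1.600, 0.200),   # carbonyl / carboxylate oxygen
  OH  = c(1.650, 0.150),   # hydroxyl oxygen
  S   = c(2.000, 0.250)
)

# one sidechain z-matrix row
.sc <- function(name, elem, lj, q, parent, blen, bang, tor = NA_character_,
                off = 0, formal = 0L, ionized = FALSE) {
  data.frame(name = name, element = elem, lj = lj, q = q, parent = parent,
             blen = blen, bang = bang, tor = tor, off = off,
             formal = as.integer(formal), ionized = ionized,
             stringsAsFactors = FALSE)
}

.scrbind <- function(...) do.call(rbind, list(...))

# Sidechain definitions.  `parent` refers to an atom name in the same residue
# (CA/N/C are backbone).  Angles in degrees.
.sidechains <- local({
  CC <- 1.526; CA_ANG <- 111.1
  defs <- list()

  defs$GLY <- NULL
  defs$ALA <- .sc("CB", "C", "CH3", 0, "CA", CC, CA_ANG)

  defs$SER <- .scrbind(
    .sc("CB", "C", "CH2", 0.150, "CA", CC, CA_ANG),
    .sc("OG", "O", "OH", -0.548, "CB", 1.417, 108.0, "chi1"),
    .sc("HG", "H", "Hp", 0.398, "OG", 0.960, 108.5, "chi2"))

  defs$THR <- .scrbind(
    .sc("CB", "C", "CH1", 0.150, "CA", CC, CA_ANG),
    .sc("OG1", "O", "OH", -0.548, "CB", 1.417, 108.0, "chi1"),
    .sc("HG1", "H", "Hp", 0.398, "OG1", 0.960, 108.5, "chi2"),
    .sc("CG2", "C", "CH3", 0, "CB", CC, 110.5, "chi1", off = -120))

  defs$CYS <- .scrbind(
    .sc("CB", "C", "CH2", 0.100, "CA", CC, CA_ANG),
    .sc("SG", "S", "S", -0.450, "CB", 1.810, 110.0, "chi1"),
    .sc("HG", "H", "Hp", 0.350, "SG", 1.340, 96.0, "chi2"))

  # oxidized cysteine: no thiol hydrogen, neutral sulfur
  defs$CYX <- .scrbind(
    .sc("CB", "C", "CH2", 0.050, "CA", CC, CA_ANG),
    .sc("SG", "S", "S", -0.050, "CB", 1.810, 110.0, "chi1"))

  defs$VAL <- .scrbind(
    .sc("CB", "C", "CH1", 0, "CA", CC, CA_ANG),
    .sc("CG1", "C", "CH3", 0, "CB", CC, 110.5, "chi1"),
    .sc("CG2", "C", "CH3", 0, "CB", CC, 110.5, "chi1", off = 120))

  defs$LEU <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH1", 0, "CB", CC, 114.0, "chi1"),
    .sc("CD1", "C", "CH3", 0, "CG", CC, 110.5, "chi2"),
    .sc("CD2", "C", "CH3", 0, "CG", CC, 110.5, "chi2", off = 120))

  defs$ILE <- .scrbind(
    .sc("CB", "C", "CH1", 0, "CA", CC, CA_ANG),
    .sc("CG1", "C", "CH2", 0, "CB", CC, 110.5, "chi1"),
    .sc("CG2", "C", "CH3", 0, "CB", CC, 110.5, "chi1", off = -120),
    .sc("CD1", "C", "CH3", 0, "CG1", CC, 110.5, "chi2"))

  defs$MET <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH2", 0.060, "CB", CC, 110.5, "chi1"),
    .sc("SD", "S", "S", -0.120, "CG", 1.810, 110.0, "chi2"),
    .sc("CE", "C", "CH3", 0.060, "SD", 1.790, 100.0, "chi3"))

  defs$PRO <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, 103.0),
    .sc("CG", "C", "CH2", 0, "CB", CC, 104.0, "chi1"),
    .sc("CD", "C", "CH2", 0, "CG", CC, 105.0, "chi2"))

  ring6 <- function(q_cz = 0) .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", 1.510, 114.0),
    .sc("CG", "C", "CR", 0, "CB", 1.510, 114.0, "chi1"),
    .sc("CD1", "C", "CR", 0, "CG", 1.400, 120.0, "chi2"),
    .sc("CD2", "C", "CR", 0, "CG", 1.400, 120.0, "chi2", off = 180),
    .sc("CE1", "C", "CR", 0, "CD1", 1.400, 120.0, off = 180),
    .sc("CE2", "C", "CR", 0, "CD2", 1.400, 120.0, off = 180),
    .sc("CZ", "C", "CR", q_cz, "CE1", 1.400, 120.0, off = 0))
  defs$PHE <- ring6()
  defs$TYR <- .scrbind(
    ring6(q_cz = 0.150),
    .sc("OH", "O", "OH", -0.548, "CZ", 1.364, 120.0, off = 180),
    .sc("HH", "H", "Hp", 0.398, "OH", 0.960, 110.0, "chi3"))

  defs$TRP <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", 1.510, 114.0),
    .sc("CG", "C", "CR", 0, "CB", 1.510, 114.0, "chi1"),
    .sc("CD1", "C", "CR", 0.060, "CG", 1.370, 127.0, "chi2"),
    .sc("CD2", "C", "CR", 0, "CG", 1.430, 126.0, "chi2", off = 180),
    .sc("NE1", "N", "N", -0.500, "CD1", 1.380, 110.0, off = 180),
    .sc("HE1", "H", "Hp", 0.380, "NE1", 1.010, 125.0, off = 180),
    .sc("CE2", "C", "CR", 0.060, "NE1", 1.370, 109.0, off = 0),
    .sc("CE3", "C", "CR", 0, "CD2", 1.400, 133.0, off = 180),
    .sc("CZ2", "C", "CR", 0, "CE2", 1.400, 122.0, off = 180),
    .sc("CZ3", "C", "CR", 0, "CE3", 1.400, 118.0, off = 180),
    .sc("CH2", "C", "CR", 0, "CZ2", 1.400, 117.0, off = 180))

  defs$ASP <- .scrbind(
    .sc("CB", "C", "CH2", -0.100, "CA", CC, CA_ANG),
    .sc("CG", "C", "C", 0.550, "CB", 1.527, 112.6, "chi1",
        formal = -1L, ionized = TRUE),
    .sc("OD1", "O", "O", -0.725, "CG", 1.250, 118.4, "chi2", ionized = TRUE),
    .sc("OD2", "O", "O", -0.725, "CG", 1.250, 118.4, "chi2", off = 180,
        ionized = TRUE))

  defs$GLU <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH2", -0.100, "CB", CC, 110.5, "chi1"),
    .sc("CD", "C", "C", 0.550, "CG", 1.527, 112.6, "chi2",
        formal = -1L, ionized = TRUE),
    .sc("OE1", "O", "O", -0.725, "CD", 1.250, 118.4, "chi3", ionized = TRUE),
    .sc("OE2", "O", "O", -0.725, "CD", 1.250, 118.4, "chi3", off = 180,
        ionized = TRUE))

  defs$ASN <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "C", 0.550, "CB", 1.522, 112.7, "chi1"),
    .sc("OD1", "O", "O", -0.550, "CG", 1.229, 120.4, "chi2"),
    .sc("ND2", "N", "N", -0.780, "CG", 1.335, 116.6, "chi2", off = 180),
    .sc("HD21", "H", "Hp", 0.390, "ND2", 1.010, 119.8, off = 0),
    .sc("HD22", "H", "Hp", 0.390, "ND2", 1.010, 119.8, off = 180))

  defs$GLN <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH2", 0, "CB", CC, 110.5, "chi1"),
    .sc("CD", "C", "C", 0.550, "CG", 1.522, 112.7, "chi2"),
    .sc("OE1", "O", "O", -0.550, "CD", 1.229, 120.4, "chi3"),
    .sc("NE2", "N", "N", -0.780, "CD", 1.335, 116.6, "chi3", off = 180),
    .sc("HE21", "H", "Hp", 0.390, "NE2", 1.010, 119.8, off = 0),
    .sc("HE22", "H", "Hp", 0.390, "NE2", 1.010, 119.8, off = 180))

  defs$LYS <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH2", 0, "CB", CC, 110.5, "chi1"),
    .sc("CD", "C", "CH2", 0, "CG", CC, 110.5, "chi2"),
    .sc("CE", "C", "CH2", 0.310, "CD", CC, 110.5, "chi3"),
    .sc("NZ", "N", "N", -0.300, "CE", 1.470, 110.0, "chi4",
        formal = 1L, ionized = TRUE),
    .sc("HZ1", "H", "Hp", 0.330, "NZ", 1.010, 109.5, off = 180, ionized = TRUE),
    .sc("HZ2", "H", "Hp", 0.330, "NZ", 1.010, 109.5, off = 60, ionized = TRUE),
    .sc("HZ3", "H", "Hp", 0.330, "NZ", 1.010, 109.5, off = -60, ionized = TRUE))

  defs$ARG <- .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", CC, CA_ANG),
    .sc("CG", "C", "CH2", 0, "CB", CC, 110.5, "chi1"),
    .sc("CD", "C", "CH2", 0.100, "CG", CC, 110.5, "chi2"),
    .sc("NE", "N", "N", -0.400, "CD", 1.470, 112.0, "chi3", ionized = TRUE),
    .sc("CZ", "C", "C", 0.750, "NE", 1.330, 124.0, "chi4",
        formal = 1L, ionized = TRUE),
    .sc("HE", "H", "Hp", 0.350, "NE", 1.010, 118.0, "chi4", off = 180,
        ionized = TRUE),
    .sc("NH1", "N", "N", -0.600, "CZ", 1.330, 120.0, off = 0, ionized = TRUE),
    .sc("NH2", "N", "N", -0.600, "CZ", 1.330, 120.0, off = 180, ionized = TRUE),
    .sc("HH11", "H", "Hp", 0.350, "NH1", 1.010, 120.0, off = 0, ionized = TRUE),
    .sc("HH12", "H", "Hp", 0.350, "NH1", 1.010, 120.0, off = 180, ionized = TRUE),
    .sc("HH21", "H", "Hp", 0.350, "NH2", 1.010, 120.0, off = 0, ionized = TRUE),
    .sc("HH22", "H", "Hp", 0.350, "NH2", 1.010, 120.0, off = 180, ionized = TRUE))

  his_ring <- function(qCG, qND1, qCD2, qCE1, qNE2, ioniz = FALSE,
                       formalNE2 = 0L) .scrbind(
    .sc("CB", "C", "CH2", 0, "CA", 1.510, 114.0),
    .sc("CG", "C", "CR", qCG, "CB", 1.500, 114.0, "chi1", ionized = ioniz),
    .sc("ND1", "N", "N", qND1, "CG", 1.380, 122.0, "chi2", ionized = ioniz),
    .sc("CD2", "C", "CR", qCD2, "CG", 1.360, 131.0, "chi2", off = 180,
        ionized = ioniz),
    .sc("CE1", "C", "CR", qCE1, "ND1", 1.320, 109.0, off = 180, ionized = ioniz),
    .sc("NE2", "N", "N", qNE2, "CD2", 1.370, 107.0, off = 180,
        formal = formalNE2, ionized = ioniz))

  defs$HID <- .scrbind(
    his_ring(0.10, -0.56, 0.10, 0.38, -0.40),
    .sc("HD1", "H", "Hp", 0.380, "ND1", 1.010, 126.0, off = 0))
  defs$HIE <- .scrbind(
    his_ring(0.10, -0.40, 0.10, 0.38, -0.56),
    .sc("HE2", "H", "Hp", 0.380, "NE2", 1.010, 126.0, off = 180))
  defs$HIP <- .scrbind(
    his_ring(0.20, -0.40, 0.20, 0.50, -0.40, ioniz = TRUE, formalNE2 = 1L),
    .sc("HD1", "H", "Hp", 0.450, "ND1", 1.010, 126.0, off = 0, ionized = TRUE),
    .sc("HE2", "H", "Hp", 0.450, "NE2", 1.010, 126.0, off = 180, ionized = TRUE))

  defs
})

# canonical residue name + protonation variant -> sidechain table key
.variant_key <- function(resname, variant = "default") {
  v <- tolower(gsub("[-_ ]?like$", "", variant))
  if (resname == "HIS") {
    return(switch(v, default = "HID", hid = "HID", hie = "HIE", hip = "HIP",
                  stop("unknown HIS variant: ", variant)))
  }
  if (resname == "CYS") {
    if (v %in% c("default", "cys-reduced", "cysreduced", "reduced")) return("CYS")
    if (v %in% c("cys-disulfide", "cysdisulfide", "disulfide", "oxidized"))
      return("CYX")
    stop("unknown CYS variant: ", variant)
  }
  if (!identical(v, "default"))
    stop("residue ", resname, " has no protonation variant '", variant, "'")
  resname
}

#' Built-in amino-acid topology library
#'
#' Returns the packaged united-atom residue topology: 20 amino acids plus
#' histidine tautomers (\code{HID}, \code{HIE}, \code{HIP}) and the oxidized
#' cysteine (\code{CYX}).  Each entry carries a backbone template (N, H, CA,
#' C, O with the amide hydrogen explicit, none for proline) and a sidechain
#' z-matrix with per-atom partial charge, Lennard-Jones class, formal charge
#' and ionized-group membership.
#'
#' @return an object of class \code{topology_library}: a list with elements
#'   \code{residues} (named list of sidechain z-matrix data frames),
#'   \code{lj} (Lennard-Jones class table) and \code{backbone} (backbone
#'   geometry constants).
#' @export
default_topology <- function() {
  structure(list(
    residues = .sidechains,
    lj = .lj_classes,
    backbone = list(
      # internal coordinates of the repeating backbone unit
      blen = c(N = 1.329, CA = 1.458, C = 1.525, O = 1.231, H = 1.010,
               CB_from_CA = 1.526),
      bang = c(N = 116.6, CA = 121.9, C = 111.1, O = 120.5, H = 119.0),
      q = c(N = -0.520, H = 0.248, CA = 0.246, C = 0.526, O = -0.500),
      q_pro = c(N = -0.272, CA = 0.246, C = 0.526, O = -0.500),
      cb_offset = -122.5  # dihedral offset of CB from phi about the N-CA axis
    )
  ), class = "topology_library")
}

#' Names of residues available in a topology library
#' @param topology a \code{topology_library}.
#' @return character vector of residue keys.
#' @export
topology_residues <- function(topology = default_topology()) {
  unique(c("GLY", "HIS", names(topology$residues)))
}

#' Serialize / read a topology library as JSON
#'
#' The schema is a JSON object with fields \code{lj} (class -> [rmin2, eps]),
#' \code{backbone} (geometry constants) and \code{residues} (residue ->
#' array of atom records with \code{name}, \code{element}, \code{lj},
#' \code{q}, \code{parent}, \code{blen}, \code{bang}, \code{tor},
#' \code{off}, \code{formal}, \code{ionized}).
#'
#' @param topology a \code{topology_library}.
#' @param path file path.
#' @return \code{read_topology_json} returns a \code{topology_library}.
#' @export
write_topology_json <- function(topology, path) {
  # named numeric vectors must become JSON objects so their names survive
  bb <- lapply(topology$backbone, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  obj <- list(lj = topology$lj, backbone = bb,
              residues = topology$residues)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- lapply(obj$residues, function(df) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) return(NULL)
    if (is.null(df$tor)) df$tor <- NA_character_  # all-NA columns drop in JSON
    df$tor[df$tor == ""] <- NA_character_
    df$formal <- as.integer(df$formal)
    df$off <- as.numeric(df$off)
    df
  })
  bb <- obj$backbone
  for (nm in c("blen", "bang", "q", "q_pro")) bb[[nm]] <- unlist(bb[[nm]])
  structure(list(residues = res, lj = lapply(obj$lj, unlist), backbone = bb),
            class = "topology_library")
}
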