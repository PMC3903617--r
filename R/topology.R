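# Heavy-atom side-chain topology for the 20 standard amino acids.
#
# Each side chain beyond the C-beta anchor is described as a small
# Z-matrix: every atom is placed from three previously known atoms by a
# bond length (A), bond angle (deg) and torsion (deg). Torsions are either
# a chi angle (chi index + fixed offset) or a constant (ring / sp2 group
# geometry). Values are ideal-geometry averages; rings do not close
# perfectly but closure bonds are restrained during minimization.

zrow <- function(name, a, b, c, bond, angle, chi = NA_integer_, offset = 0) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi, offset = offset)
}

zdf <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' @noRd
sidechain_topology <- local({
  topo <- list()

  topo$GLY <- list(zmat = NULL, nchi = 0L, closures = list(), rigid = list())
  topo$ALA <- list(zmat = NULL, nchi = 0L, closures = list(), rigid = list())

  topo$SER <- list(
    zmat = zdf(zrow("OG", "N", "CA", "CB", 1.417, 110.8, 1L)),
    nchi = 1L, closures = list(), rigid = list())

  topo$CYS <- list(
    zmat = zdf(zrow("SG", "N", "CA", "CB", 1.808, 113.8, 1L)),
    nchi = 1L, closures = list(), rigid = list())

  topo$THR <- list(
    zmat = zdf(zrow("OG1", "N", "CA", "CB", 1.433, 109.6, 1L),
               zrow("CG2", "N", "CA", "CB", 1.521, 111.5, 1L, -122)),
    nchi = 1L, closures = list(), rigid = list())

  topo$VAL <- list(
    zmat = zdf(zrow("CG1", "N", "CA", "CB", 1.527, 110.4, 1L),
               zrow("CG2", "N", "CA", "CB", 1.527, 110.4, 1L, 122.3)),
    nchi = 1L, closures = list(), rigid = list())

  topo$LEU <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.530, 116.3, 1L),
               zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, 2L),
               zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, 2L, 122.3)),
    nchi = 2L, closures = list(), rigid = list())

  topo$ILE <- list(
    zmat = zdf(zrow("CG1", "N",  "CA", "CB",  1.530, 110.4, 1L),
               zrow("CG2", "N",  "CA", "CB",  1.521, 110.5, 1L, -122),
               zrow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2L)),
    nchi = 2L, closures = list(), rigid = list())

  topo$MET <- list(
    zmat = zdf(zrow("CG", "N",  "CA", "CB", 1.520, 114.1, 1L),
               zrow("SD", "CA", "CB", "CG", 1.803, 112.7, 2L),
               zrow("CE", "CB", "CG", "SD", 1.791, 100.9, 3L)),
    nchi = 3L, closures = list(), rigid = list())

  topo$ASP <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.516, 112.6, 1L),
               zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2L),
               zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2L, 180)),
    nchi = 2L, closures = list(),
    rigid = list(c("CB", "CG", "OD1", "OD2")))

  topo$ASN <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.516, 112.6, 1L),
               zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2L),
               zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2L, 180)),
    nchi = 2L, closures = list(),
    rigid = list(c("CB", "CG", "OD1", "ND2")))

  topo$GLU <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.530, 114.1, 1L),
               zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
               zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3L),
               zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3L, 180)),
    nchi = 3L, closures = list(),
    rigid = list(c("CG", "CD", "OE1", "OE2")))

  topo$GLN <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.530, 114.1, 1L),
               zrow("CD",  "CA", "CB", "CG", 1.516, 112.6, 2L),
               zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3L),
               zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3L, 180)),
    nchi = 3L, closures = list(),
    rigid = list(c("CG", "CD", "OE1", "NE2")))

  topo$LYS <- list(
    zmat = zdf(zrow("CG", "N",  "CA", "CB", 1.520, 114.1, 1L),
               zrow("CD", "CA", "CB", "CG", 1.520, 111.3, 2L),
               zrow("CE", "CB", "CG", "CD", 1.520, 111.3, 3L),
               zrow("NZ", "CG", "CD", "CE", 1.470, 112.0, 4L)),
    nchi = 4L, closures = list(), rigid = list())

  topo$ARG <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB", 1.520, 114.1, 1L),
               zrow("CD",  "CA", "CB", "CG", 1.520, 111.3, 2L),
               zrow("NE",  "CB", "CG", "CD", 1.461, 112.0, 3L),
               zrow("CZ",  "CG", "CD", "NE", 1.329, 124.2, 4L),
               zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, NA, 0),
               zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, NA, 180)),
    nchi = 4L, closures = list(),
    rigid = list(c("CD", "NE", "CZ", "NH1", "NH2")))

  topo$HIS <- list(
    zmat = zdf(zrow("CG",  "N",  "CA", "CB",  1.497, 113.8, 1L),
               zrow("ND1", "CA", "CB", "CG",  1.378, 122.7, 2L),
               zrow("CD2", "CA", "CB", "CG",  1.356, 131.1, 2L, 180),
               zrow("CE1", "CB", "CG", "ND1", 1.323, 109.3, NA, 180),
               zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, NA, 180)),
    nchi = 2L, closures = list(c("CE1", "NE2")),
    rigid = list(c("CB", "CG", "ND1", "CD2", "CE1", "NE2")))

  topo$PHE <- list(
    zmat = zdf(zrow("CG",  "N",  "CA",  "CB",  1.502, 113.8, 1L),
               zrow("CD1", "CA", "CB",  "CG",  1.391, 120.7, 2L),
               zrow("CD2", "CA", "CB",  "CG",  1.391, 120.7, 2L, 180),
               zrow("CE1", "CB", "CG",  "CD1", 1.393, 120.7, NA, 180),
               zrow("CE2", "CB", "CG",  "CD2", 1.393, 120.7, NA, 180),
               zrow("CZ",  "CG", "CD1", "CE1", 1.384, 120.0, NA, 0)),
    nchi = 2L, closures = list(c("CE2", "CZ")),
    rigid = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")))

  topo$TYR <- list(
    zmat = zdf(zrow("CG",  "N",   "CA",  "CB",  1.502, 113.8, 1L),
               zrow("CD1", "CA",  "CB",  "CG",  1.391, 120.7, 2L),
               zrow("CD2", "CA",  "CB",  "CG",  1.391, 120.7, 2L, 180),
               zrow("CE1", "CB",  "CG",  "CD1", 1.393, 120.7, NA, 180),
               zrow("CE2", "CB",  "CG",  "CD2", 1.393, 120.7, NA, 180),
               zrow("CZ",  "CG",  "CD1", "CE1", 1.384, 120.0, NA, 0),
               zrow("OH",  "CD1", "CE1", "CZ",  1.376, 119.9, NA, 180)),
    nchi = 2L, closures = list(c("CE2", "CZ")),
    rigid = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")))

  topo$TRP <- list(
    zmat = zdf(zrow("CG",  "N",  "CA",  "CB",  1.498, 113.6, 1L),
               zrow("CD1", "CA", "CB",  "CG",  1.365, 126.9, 2L),
               zrow("CD2", "CA", "CB",  "CG",  1.433, 126.7, 2L, 180),
               zrow("NE1", "CB", "CG",  "CD1", 1.374, 110.2, NA, 180),
               zrow("CE2", "CB", "CG",  "CD2", 1.409, 107.2, NA, 180),
               zrow("CE3", "CB", "CG",  "CD2", 1.398, 133.9, NA, 0),
               zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, NA, 180),
               zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, NA, 180),
               zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, NA, 180)),
    nchi = 2L,
    closures = list(c("NE1", "CE2"), c("CZ3", "CH2")),
    rigid = list(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                   "CZ2", "CZ3", "CH2")))

  topo$PRO <- list(
    zmat = zdf(zrow("CG", "N",  "CA", "CB", 1.492, 104.5, 1L),
               zrow("CD", "CA", "CB", "CG", 1.503, 106.1, 2L)),
    nchi = 2L, closures = list(c("CD", "N")),
    rigid = list(c("CB", "CG", "CD")))

  topo
})

# chi dihedral atom quadruples (standard definitions, heavy atoms)
chi_atom_names <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  ASP = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  HIS = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"),  c("CA", "CB", "CG", "CD"))
)

aa_three <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
              "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
              "THR", "TRP", "TYR", "VAL")
aa_one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert between 1- and 3-letter amino-acid codes
#' @param aa character vector of 1- or 3-letter codes.
#' @return 3-letter codes, upper case.
#' @export
aa_to_three <- function(aa) {
  aa <- toupper(aa)
  out <- ifelse(nchar(aa) == 1, aa_three[match(aa, aa_one)], aa)
  if (anyNA(out) || !all(out %in% aa_three))
    stop("unknown amino-acid code(s): ", paste(aa[is.na(out) | !(out %in% aa_three)], collapse = ", "))
  out
}

# side-chain atom names beyond CB for a residue type
sidechain_atoms_beyond_cb <- function(res) {
  topo <- sidechain_topology[[res]]
  if (is.null(topo$zmat)) character(0) else topo$zmat$name
}
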