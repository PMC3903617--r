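# Nonbonded parameter table handling and atom parameterization.
#
# The bundled table is a functional-form stand-in for a full protein force
# field: AMBER-style 12-6 Lennard-Jones plus point-charge Coulomb terms on
# united heavy atoms (hydrogen charges folded into their bonded heavy
# atoms). It preserves the dominant signal of the screen -- charge
# complementarity across the interface -- at desk scale.

aa_formal_charge <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)

#' Load a nonbonded parameter table
#'
#' Reads a whitespace/tab-delimited table with columns
#' `residue, atom, charge, rmin2, eps, radius` and validates it: every
#' residue's charges must sum to its formal charge within 1e-3 e, and
#' every standard amino acid must be covered.
#'
#' @param path path to the parameter file; default is the bundled table.
#' @return A data frame of class `ff_params`.
#' @export
load_ff_params <- function(path = system.file("extdata", "ff_params.tsv",
                                              package = "abmature")) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ff <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge", "rmin2", "eps", "radius")
  if (!all(need %in% names(ff)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(ff$eps < 0) || any(ff$rmin2 <= 0) || any(ff$radius <= 0))
    stop("invalid LJ parameters (eps >= 0, rmin2 > 0, radius > 0 required)")
  missing_res <- setdiff(aa_three, unique(ff$residue))
  if (length(missing_res))
    stop("parameter table lacks residues: ", paste(missing_res, collapse = ", "))
  for (res in unique(ff$residue)) {
    qsum <- sum(ff$charge[ff$residue == res])
    formal <- if (res %in% names(aa_formal_charge)) aa_formal_charge[[res]] else 0
    if (abs(qsum - formal) > 1e-3)
      stop(sprintf("residue %s charge sum %.4f != formal charge %d", res, qsum, formal))
  }
  class(ff) <- c("ff_params", "data.frame")
  ff
}

default_ff_cache <- new.env(parent = emptyenv())

default_ff_params <- function() {
  if (is.null(default_ff_cache$ff)) default_ff_cache$ff <- load_ff_params()
  default_ff_cache$ff
}

#' Assign nonbonded parameters to every atom of a complex structure
#'
#' Joins the parameter table onto the structure's atoms by (residue name,
#' atom name). The default mode is united heavy-atom: hydrogens present in
#' the input are dropped (their charges are already folded into the heavy
#' atoms of the table).
#'
#' @param structure a `cstruct` object.
#' @param params an `ff_params` table (default: bundled table).
#' @param mode `"strict"` errors on any unresolved heavy atom;
#'   `"permissive"` assigns zero charge/eps and a carbon radius, with a
#'   warning listing the atoms.
#' @param drop_hydrogens drop hydrogen atoms first (default TRUE).
#' @return The structure with `charge`, `rmin2`, `eps`, `radius` filled in
#'   and the parameter table attached for later mutation building.
#' @export
parameterize <- function(structure, params = default_ff_params(),
                         mode = c("strict", "permissive"),
                         drop_hydrogens = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(structure, "cstruct"))
  if (drop_hydrogens) {
    keep <- structure$atoms$element != "H"
    if (!all(keep)) structure <- subset_cstruct(structure, keep)
  }
  at <- structure$atoms
  key <- paste(at$resid, at$elety)
  pkey <- paste(params$residue, params$atom)
  m <- match(key, pkey)
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    msg <- paste0("unparameterized atoms: ", paste(bad, collapse = ", "))
    if (mode == "strict") stop(msg) else warning(msg, "; assigned zero charge/eps")
  }
  at$charge <- ifelse(is.na(m), 0, params$charge[m])
  at$rmin2 <- ifelse(is.na(m), 1.908, params$rmin2[m])
  at$eps <- ifelse(is.na(m), 0, params$eps[m])
  at$radius <- ifelse(is.na(m), 1.7, params$radius[m])
  structure$atoms <- at
  structure$ff <- params
  structure$parameterized <- TRUE
  structure
}
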