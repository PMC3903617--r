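# Side-chain building and in-silico point mutation. Backbone atoms
# (N, CA, C, O) and the C-beta anchor are never moved; side chains beyond
# C-beta are (re)built from ideal internal coordinates plus chi angles.

backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Mutation specification
#'
#' @param chain chain id of the residue to mutate (must be on partner A
#'   for screening use).
#' @param resno author residue number.
#' @param target target amino acid, 1- or 3-letter code.
#' @param rotamer rotamer policy: `"most_probable"`, integer index
#'   (k-th most probable), or `"sample"`.
#' @return list of class `mutation_spec`.
#' @export
mutation_spec <- function(chain, resno, target, rotamer = "most_probable") {
  structure(list(chain = chain, resno = resno,
                 target = aa_to_three(target), rotamer = rotamer),
            class = "mutation_spec")
}

mutation_id <- function(structure, spec) {
  idx <- residue_index(structure, spec$chain, spec$resno)
  wt <- if (length(idx)) structure$atoms$resid[idx[1]] else "???"
  sprintf("%s-%s%d%s", spec$chain, aa_one[match(wt, aa_three)],
          spec$resno, aa_one[match(spec$target, aa_three)])
}

# coordinates (named matrix) of side-chain atoms beyond CB for residue
# type `res`, given backbone N/CA/CB positions and chi angles
build_sidechain_coords <- function(res, N, CA, CB, chis) {
  topo <- sidechain_topology[[res]]
  if (is.null(topo$zmat)) return(NULL)
  pos <- list(N = N, CA = CA, CB = CB)
  zm <- topo$zmat
  out <- matrix(NA_real_, nrow(zm), 3, dimnames = list(zm$name, NULL))
  for (i in seq_len(nrow(zm))) {
    tor <- if (is.na(zm$chi[i])) zm$offset[i] else chis[zm$chi[i]] + zm$offset[i]
    p <- place_atom(pos[[zm$a[i]]], pos[[zm$b[i]]], pos[[zm$c[i]]],
                    zm$bond[i], zm$angle[i], tor)
    pos[[zm$name[i]]] <- p
    out[i, ] <- p
  }
  out
}

# replace a residue's side chain (and identity) in a cstruct; backbone
# and CB are kept where present, CB is built from backbone when absent
replace_sidechain <- function(structure, chain, resno, new_res, chis) {
  idx <- residue_index(structure, chain, resno)
  if (length(idx) == 0) stop("residue ", chain, resno, " not found")
  at <- structure$atoms
  names_here <- at$elety[idx]
  bb_idx <- idx[names_here %in% backbone_names]
  need <- c("N", "CA", "C")
  if (!all(need %in% names_here)) stop("incomplete backbone at ", chain, resno)
  N <- structure$xyz[idx[names_here == "N"][1], ]
  CA <- structure$xyz[idx[names_here == "CA"][1], ]
  C <- structure$xyz[idx[names_here == "C"][1], ]
  keep_cb <- new_res != "GLY"
  if (keep_cb) {
    CB <- if ("CB" %in% names_here) structure$xyz[idx[names_here == "CB"][1], ]
          else ideal_cb(N, CA, C)
  }
  sc <- if (keep_cb) build_sidechain_coords(new_res, N, CA, CB, chis) else NULL

  keep_global <- setdiff(seq_len(nrow(at)), setdiff(idx, bb_idx))
  new_names <- c(if (keep_cb) "CB", if (!is.null(sc)) rownames(sc))
  n_new <- length(new_names)
  new_xyz <- if (n_new) rbind(if (keep_cb) matrix(CB, 1, 3), sc) else NULL

  insert_after <- max(bb_idx)
  pre <- keep_global[keep_global <= insert_after]
  post <- keep_global[keep_global > insert_after]
  tmpl <- at[idx[1], , drop = FALSE]
  new_rows <- tmpl[rep(1, n_new), , drop = FALSE]
  if (n_new) {
    new_rows$elety <- new_names
    new_rows$element <- element_from_name(new_names)
    new_rows$charge <- NA_real_; new_rows$rmin2 <- NA_real_
    new_rows$eps <- NA_real_; new_rows$radius <- NA_real_
  }
  atoms2 <- rbind(at[pre, , drop = FALSE],
                  if (n_new) new_rows,
                  at[post, , drop = FALSE])
  atoms2$resid[atoms2$chain == chain & atoms2$resno == resno] <- new_res
  xyz2 <- rbind(structure$xyz[pre, , drop = FALSE],
                new_xyz,
                structure$xyz[post, , drop = FALSE])
  dimnames(xyz2) <- NULL
  rownames(atoms2) <- NULL
  structure$atoms <- atoms2
  structure$xyz <- xyz2
  # re-parameterize the touched residue if the structure carries a table
  if (isTRUE(structure$parameterized) && !is.null(structure$ff)) {
    ridx <- residue_index(structure, chain, resno)
    ff <- structure$ff
    m <- match(paste(structure$atoms$resid[ridx], structure$atoms$elety[ridx]),
               paste(ff$residue, ff$atom))
    if (anyNA(m)) stop("no parameters for rebuilt atoms of ", new_res)
    structure$atoms$charge[ridx] <- ff$charge[m]
    structure$atoms$rmin2[ridx] <- ff$rmin2[m]
    structure$atoms$eps[ridx] <- ff$eps[m]
    structure$atoms$radius[ridx] <- ff$radius[m]
  }
  structure
}

#' Mutate a single residue via the rotamer library
#'
#' Replaces the side chain using ideal internal coordinates and the
#' selected rotamer's chi angles. Backbone and C-beta anchor geometry are
#' untouched (C-beta is constructed from the backbone only when the
#' wild-type lacks one, i.e. Gly sites).
#'
#' @param structure a `cstruct` (parameterized structures get the new
#'   atoms parameterized automatically).
#' @param spec a [mutation_spec()].
#' @param library rotamer library.
#' @param allow_risky allow Pro as a mutation target (off by default:
#'   its ring is not representable with a fixed backbone).
#' @return The mutated structure.
#' @export
mutate_residue <- function(structure, spec, library = default_rotamer_library(),
                           allow_risky = FALSE) {
  stopifnot(inherits(spec, "mutation_spec"))
  idx <- residue_index(structure, spec$chain, spec$resno)
  if (length(idx) == 0)
    stop("residue ", spec$chain, spec$resno, " not found")
  if (spec$target == "PRO" && !allow_risky)
    stop("Pro is rejected as a mutation target (fixed-backbone geometry); ",
         "set allow_risky = TRUE to override")
  chis <- pick_rotamer(spec$target, spec$rotamer, library)
  replace_sidechain(structure, spec$chain, spec$resno, spec$target, chis)
}

#' Measure the chi angles of a residue
#'
#' @param structure a `cstruct`.
#' @param chain,resno residue address.
#' @return numeric vector of chi angles in degrees (length 0 for Ala/Gly).
#' @export
measure_chis <- function(structure, chain, resno) {
  idx <- residue_index(structure, chain, resno)
  if (length(idx) == 0) stop("residue not found")
  res <- structure$atoms$resid[idx[1]]
  defs <- chi_atom_names[[res]]
  if (is.null(defs)) return(numeric(0))
  names_here <- structure$atoms$elety[idx]
  vapply(defs, function(quad) {
    j <- match(quad, names_here)
    if (anyNA(j)) return(NA_real_)
    dihedral(structure$xyz[idx[j[1]], ], structure$xyz[idx[j[2]], ],
             structure$xyz[idx[j[3]], ], structure$xyz[idx[j[4]], ])
  }, numeric(1))
}

# set a residue's side chain to the given chi angles (rebuild beyond CB)
set_sidechain_chis <- function(structure, chain, resno, chis) {
  idx <- residue_index(structure, chain, resno)
  res <- structure$atoms$resid[idx[1]]
  replace_sidechain(structure, chain, resno, res, chis)
}

#' Gaussian perturbation of side-chain chi angles
#'
#' Each chi angle receives an independent Gaussian perturbation of width
#' `sigma` degrees, and the side chain is rebuilt from ideal internal
#' coordinates at the perturbed angles. Deterministic under a fixed RNG
#' state.
#'
#' @param structure a `cstruct`.
#' @param chain,resno residue address; the residue must have at least
#'   one chi angle (Ala/Gly are returned unchanged).
#' @param sigma perturbation width, degrees; `sigma = 0` returns the
#'   structure unchanged.
#' @return The perturbed structure.
#' @export
perturb_sidechain <- function(structure, chain, resno, sigma) {
  if (sigma == 0) return(structure)
  chis <- measure_chis(structure, chain, resno)
  if (length(chis) == 0) return(structure)
  new_chis <- chis + stats::rnorm(length(chis), 0, sigma)
  new_chis <- ((new_chis + 180) %% 360) - 180
  set_sidechain_chis(structure, chain, resno, new_chis)
}
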