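# Complex-structure container and structural operations: PDB I/O (via
# bio3d), CDR selection, interface contacts, buried surface area.

#' Construct a complex structure
#'
#' @param atoms data frame with columns `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue name), `elety` (atom name), `element`.
#'   Parameter columns (`charge`, `rmin2`, `eps`, `radius`) are added by
#'   [parameterize()].
#' @param xyz numeric matrix, one row per atom, columns x/y/z (angstrom).
#' @param partition named character vector mapping every chain id to
#'   partner label `"A"` (antibody side) or `"B"` (antigen side).
#' @return An object of class `cstruct`.
#' @export
new_cstruct <- function(atoms, xyz, partition) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (!all(partition %in% c("A", "B")))
    stop("partition labels must be 'A' or 'B'")
  if (anyDuplicated(names(partition)))
    stop("chain assigned twice in partition")
  chains <- unique(atoms$chain)
  missing <- setdiff(chains, names(partition))
  if (length(missing))
    stop("chain(s) not in partition: ", paste(missing, collapse = ", "))
  if (!all(c("A", "B") %in% partition[chains]))
    stop("both partner labels A and B must be populated")
  for (col in c("charge", "rmin2", "eps", "radius"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  atoms$insert <- ifelse(is.na(atoms$insert) | atoms$insert == "", "", atoms$insert)
  atoms$partner <- unname(partition[atoms$chain])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  structure(list(atoms = atoms, xyz = unname(as.matrix(xyz)),
                 partition = partition, parameterized = FALSE),
            class = "cstruct")
}

#' @export
print.cstruct <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<cstruct> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(rt),
              paste(sprintf("%s(%s)", names(x$partition), x$partition),
                    collapse = " ")))
  invisible(x)
}

subset_cstruct <- function(structure, keep) {
  structure$atoms <- structure$atoms[keep, , drop = FALSE]
  rownames(structure$atoms) <- NULL
  structure$xyz <- structure$xyz[keep, , drop = FALSE]
  structure
}

#' Table of residues in a structure
#' @param structure a `cstruct`.
#' @return data frame with chain, resno, insert, resid, partner, n_atoms.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  key <- paste(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  out <- at[first, c("chain", "resno", "insert", "resid", "partner")]
  out$n_atoms <- as.integer(table(key)[paste(out$chain, out$resno, out$insert)])
  rownames(out) <- NULL
  out
}

residue_index <- function(structure, chain, resno, insert = "") {
  at <- structure$atoms
  which(at$chain == chain & at$resno == resno & at$insert == insert)
}

element_from_name <- function(elety) {
  e <- substr(gsub("[0-9'\"]", "", elety), 1, 1)
  ifelse(e %in% c("C", "N", "O", "S", "H", "P"), e, "X")
}

standard_residues <- function() aa_three

#' Read a PDB file into a complex structure
#'
#' Wraps `bio3d::read.pdb`. Keeps ATOM records of standard residues;
#' HETATM and waters are skipped unless `keep_het = TRUE`. Alternate
#' locations other than blank/"A" are dropped (count reported via a
#' message). Duplicate atom names within a residue keep the first
#' occurrence with a warning.
#'
#' @param path PDB file path.
#' @param partition named character vector chain -> "A"/"B"; must cover
#'   every polymer chain in the file.
#' @param keep_het keep non-water HETATM records (default FALSE).
#' @return A `cstruct`.
#' @export
read_pdb <- function(path, partition, keep_het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$resid %in% standard_residues()
  if (keep_het) keep <- keep | (at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT")))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atom records survive filtering in ", path)
  chains <- unique(at$chain)
  missing <- setdiff(chains, names(partition))
  if (length(missing))
    stop("chain(s) in file but not in partition: ", paste(missing, collapse = ", "))
  alt <- is.na(at$alt) | at$alt %in% c("", "A")
  n_alt <- sum(!alt)
  if (n_alt > 0) {
    message("dropped ", n_alt, " alternate-location atoms (kept blank/'A')")
    at <- at[alt, , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (anyDuplicated(key)) {
    warning("duplicate atom(s) within residue; kept first: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    at <- at[!duplicated(key), , drop = FALSE]
  }
  atoms <- data.frame(
    chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid, elety = at$elety,
    element = element_from_name(at$elety),
    stringsAsFactors = FALSE)
  new_cstruct(atoms, cbind(at$x, at$y, at$z), partition)
}

#' Write a complex structure to a PDB file
#'
#' Standard fixed-column ATOM records via `bio3d::write.pdb`; author
#' numbering and insertion codes preserved.
#'
#' @param structure a `cstruct` with at least one atom.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "cstruct"))
  at <- structure$atoms
  if (nrow(at) == 0) stop("cannot write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, insert = ifelse(at$insert == "", NA, at$insert),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Select CDR (mutable) residues
#'
#' @param structure a `cstruct`.
#' @param ranges data frame with columns `chain`, `start`, `end`
#'   (author numbering, inclusive on both ends), or NULL.
#' @param residues data frame with columns `chain`, `resno` (explicit
#'   list), or NULL. Exactly one of `ranges`/`residues` must be given.
#' @param scheme free-text provenance tag stored on the selection.
#' @return data frame of class `cdr_selection` with columns chain, resno,
#'   insert, resid.
#' @export
select_cdr <- function(structure, ranges = NULL, residues = NULL,
                       scheme = "user list") {
  rt <- residue_table(structure)
  if (is.null(ranges) == is.null(residues))
    stop("give exactly one of `ranges` or `residues`")
  if (!is.null(ranges)) {
    picks <- list()
    for (i in seq_len(nrow(ranges))) {
      ch <- ranges$chain[i]
      if (!ch %in% names(structure$partition))
        stop("range on unknown chain ", ch)
      if (structure$partition[[ch]] != "A")
        stop("range on chain ", ch, " which is not partner A")
      sel <- rt[rt$chain == ch & rt$resno >= ranges$start[i] &
                  rt$resno <= ranges$end[i], , drop = FALSE]
      picks[[i]] <- sel
    }
    out <- do.call(rbind, picks)
  } else {
    idx <- integer(nrow(residues))
    for (i in seq_len(nrow(residues))) {
      j <- which(rt$chain == residues$chain[i] & rt$resno == residues$resno[i])
      if (length(j) == 0)
        stop("residue ", residues$chain[i], residues$resno[i],
             " not present in structure")
      if (rt$partner[j[1]] != "A")
        stop("residue ", residues$chain[i], residues$resno[i],
             " is not on partner A")
      idx[i] <- j[1]
    }
    out <- rt[idx, , drop = FALSE]
  }
  if (anyDuplicated(paste(out$chain, out$resno, out$insert)))
    stop("duplicate residues in selection")
  out <- out[, c("chain", "resno", "insert", "resid")]
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  class(out) <- c("cdr_selection", "data.frame")
  out
}

#' Cross-partner residue contacts at the interface
#'
#' A residue pair is a contact iff any heavy-atom cross-partner distance
#' is at or below `cutoff`.
#'
#' @param structure a `cstruct` with both partners populated.
#' @param cutoff heavy-atom distance cutoff, angstrom (default 4.5).
#' @return list with `pairs` (data frame chain_a, resno_a, chain_b,
#'   resno_b, min_dist, ordered by chain/number) and `residues_a`,
#'   `residues_b` (induced residue sets).
#' @export
interface_residues <- function(structure, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  at <- structure$atoms
  heavy <- at$element != "H"
  ia <- which(at$partner == "A" & heavy)
  ib <- which(at$partner == "B" & heavy)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both partners must have heavy atoms")
  d2 <- cross_dist2(structure$xyz[ia, , drop = FALSE],
                    structure$xyz[ib, , drop = FALSE])
  keya <- paste(at$chain[ia], at$resno[ia], at$insert[ia], sep = "|")
  keyb <- paste(at$chain[ib], at$resno[ib], at$insert[ib], sep = "|")
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    pairs <- data.frame(chain_a = character(0), resno_a = integer(0),
                        chain_b = character(0), resno_b = integer(0),
                        min_dist = numeric(0))
  } else {
    pk <- paste(keya[hit[, 1]], keyb[hit[, 2]], sep = "~")
    mind <- tapply(sqrt(d2[hit]), pk, min)
    parts <- strsplit(names(mind), "~", fixed = TRUE)
    pa <- strsplit(vapply(parts, `[`, "", 1), "|", fixed = TRUE)
    pb <- strsplit(vapply(parts, `[`, "", 2), "|", fixed = TRUE)
    pairs <- data.frame(
      chain_a = vapply(pa, `[`, "", 1),
      resno_a = as.integer(vapply(pa, `[`, "", 2)),
      chain_b = vapply(pb, `[`, "", 1),
      resno_b = as.integer(vapply(pb, `[`, "", 2)),
      min_dist = as.numeric(mind))
    pairs <- pairs[order(pairs$chain_a, pairs$resno_a,
                         pairs$chain_b, pairs$resno_b), ]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       residues_a = unique(pairs[, c("chain_a", "resno_a")]),
       residues_b = unique(pairs[, c("chain_b", "resno_b")]))
}

# squared distances between two coordinate sets (n x 3, m x 3) -> n x m
cross_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
}

# deterministic golden-spiral points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Shrake-Rupley SASA for a set of atoms; returns per-atom areas (A^2)
shrake_rupley <- function(xyz, radius, probe = 1.4, n_points = 960) {
  if (anyNA(radius)) stop("missing atomic radii; parameterize the structure first")
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  r <- radius + probe
  area <- numeric(n)
  d2all <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    neigh <- which(d2all[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    test <- pts * r[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    if (length(neigh)) {
      d2 <- cross_dist2(test, xyz[neigh, , drop = FALSE])
      buried <- rowSums(d2 < matrix(r[neigh]^2, n_points, length(neigh),
                                    byrow = TRUE)) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    area[i] <- 4 * pi * r[i]^2 * acc / n_points
  }
  area
}

#' Buried surface area of the interface
#'
#' SASA(A) + SASA(B) - SASA(AB) by Shrake-Rupley sampling with a
#' deterministic golden-spiral point set.
#'
#' @param structure a parameterized `cstruct` (atoms carry radii).
#' @param probe probe radius, angstrom (default 1.4).
#' @param n_points sampling points per atom (default 960).
#' @param per_residue also return per-residue attribution.
#' @return The buried area in A^2 (with attribute `per_residue` if
#'   requested).
#' @export
buried_surface_area <- function(structure, probe = 1.4, n_points = 960,
                                per_residue = FALSE) {
  at <- structure$atoms
  heavy <- at$element != "H"
  ia <- which(at$partner == "A" & heavy)
  ib <- which(at$partner == "B" & heavy)
  if (length(ia) == 0 || length(ib) == 0) stop("both partners must be populated")
  rad <- at$radius
  a_ab <- shrake_rupley(structure$xyz[c(ia, ib), , drop = FALSE],
                        rad[c(ia, ib)], probe, n_points)
  a_a <- shrake_rupley(structure$xyz[ia, , drop = FALSE], rad[ia], probe, n_points)
  a_b <- shrake_rupley(structure$xyz[ib, , drop = FALSE], rad[ib], probe, n_points)
  bsa <- sum(a_a) + sum(a_b) - sum(a_ab)
  if (per_residue) {
    datom <- c(a_a, a_b) - a_ab
    key <- paste(at$chain[c(ia, ib)], at$resno[c(ia, ib)])
    attr(bsa, "per_residue") <- tapply(datom, key, sum)
  }
  bsa
}
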