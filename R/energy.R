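# Cross-partner nonbonded interaction energy: point-charge Coulomb with a
# uniform dielectric plus 12-6 Lennard-Jones, summed over all
# antibody-antigen atom pairs. This sum is the affinity surrogate that
# scores every model in the screen.

#' Energy model configuration
#'
#' @param dielectric uniform relative dielectric constant (default 80.0,
#'   mimicking bulk water).
#' @param cutoff nonbonded distance cutoff in angstrom, or NULL for the
#'   exact all-pairs sum (default). No switching function is applied.
#' @return list of class `energy_config`.
#' @export
energy_config <- function(dielectric = 80.0, cutoff = NULL) {
  stopifnot(dielectric > 0, is.null(cutoff) || cutoff > 0)
  structure(list(dielectric = dielectric, cutoff = cutoff,
                 coulomb_k = ab_constants$coulomb_k),
            class = "energy_config")
}

check_parameterized <- function(structure) {
  if (anyNA(structure$atoms$charge) || anyNA(structure$atoms$eps))
    stop("structure is not parameterized; call parameterize() first")
}

# cross-partner pair distances; errors on a zero-distance clash
cross_pair_dists <- function(structure, config) {
  at <- structure$atoms
  ia <- which(at$partner == "A")
  ib <- which(at$partner == "B")
  if (length(ia) == 0 || length(ib) == 0)
    stop("both partners must be non-empty")
  d2 <- cross_dist2(structure$xyz[ia, , drop = FALSE],
                    structure$xyz[ib, , drop = FALSE])
  if (any(d2 < 1e-12)) {
    w <- which(d2 < 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("zero interatomic distance (clash) between atoms %s/%s%d:%s and %s/%s%d:%s",
                 at$chain[ia[w[1]]], at$resid[ia[w[1]]], at$resno[ia[w[1]]], at$elety[ia[w[1]]],
                 at$chain[ib[w[2]]], at$resid[ib[w[2]]], at$resno[ib[w[2]]], at$elety[ib[w[2]]]))
  }
  keep <- if (is.null(config$cutoff)) NULL else d2 <= config$cutoff^2
  list(ia = ia, ib = ib, d2 = d2, keep = keep)
}

#' Cross-partner electrostatic interaction energy
#'
#' Sum over pairs i in A, j in B of k_C q_i q_j / (eps_r r_ij), kcal/mol.
#'
#' @param structure a parameterized `cstruct`.
#' @param config an [energy_config()].
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(structure, config = energy_config()) {
  check_parameterized(structure)
  pd <- cross_pair_dists(structure, config)
  q <- structure$atoms$charge
  e <- config$coulomb_k * outer(q[pd$ia], q[pd$ib]) /
    (config$dielectric * sqrt(pd$d2))
  if (!is.null(pd$keep)) e <- e * pd$keep
  sum(e)
}

#' Cross-partner Lennard-Jones interaction energy
#'
#' 12-6 form eps_ij ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6) with
#' rmin_ij = rmin2_i + rmin2_j and eps_ij = sqrt(eps_i eps_j), kcal/mol.
#'
#' @inheritParams coulomb_energy
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(structure, config = energy_config()) {
  check_parameterized(structure)
  pd <- cross_pair_dists(structure, config)
  at <- structure$atoms
  rmin <- outer(at$rmin2[pd$ia], at$rmin2[pd$ib], "+")
  epsij <- sqrt(outer(at$eps[pd$ia], at$eps[pd$ib]))
  s6 <- (rmin^2 / pd$d2)^3
  e <- epsij * (s6^2 - 2 * s6)
  if (!is.null(pd$keep)) e <- e * pd$keep
  sum(e)
}

#' Antibody-antigen interaction energy breakdown
#'
#' Electrostatic and van der Waals cross-partner energies and their sum,
#' the affinity surrogate. Intra-partner pairs never contribute.
#'
#' @inheritParams coulomb_energy
#' @return list of class `energy_breakdown` with `e_elec`, `e_vdw`,
#'   `e_total` (kcal/mol).
#' @export
interaction_energy <- function(structure, config = energy_config()) {
  check_parameterized(structure)
  pd <- cross_pair_dists(structure, config)
  at <- structure$atoms
  r <- sqrt(pd$d2)
  ee <- config$coulomb_k * outer(at$charge[pd$ia], at$charge[pd$ib]) /
    (config$dielectric * r)
  rmin <- outer(at$rmin2[pd$ia], at$rmin2[pd$ib], "+")
  epsij <- sqrt(outer(at$eps[pd$ia], at$eps[pd$ib]))
  s6 <- (rmin^2 / pd$d2)^3
  ev <- epsij * (s6^2 - 2 * s6)
  if (!is.null(pd$keep)) { ee <- ee * pd$keep; ev <- ev * pd$keep }
  e_elec <- sum(ee); e_vdw <- sum(ev)
  structure(list(e_elec = e_elec, e_vdw = e_vdw, e_total = e_elec + e_vdw),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("interaction energy: elec %.3f + vdw %.3f = %.3f kcal/mol\n",
              x$e_elec, x$e_vdw, x$e_total))
  invisible(x)
}

# minimum cross-partner heavy-atom distance (used by the contact filter)
min_cross_distance <- function(structure) {
  at <- structure$atoms
  heavy <- at$element != "H"
  ia <- which(at$partner == "A" & heavy)
  ib <- which(at$partner == "B" & heavy)
  if (length(ia) == 0 || length(ib) == 0) return(Inf)
  sqrt(min(cross_dist2(structure$xyz[ia, , drop = FALSE],
                       structure$xyz[ib, , drop = FALSE])))
}
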