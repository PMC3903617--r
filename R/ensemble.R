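# Randomized model ensembles for one mutation: rotamer prior sampling,
# Gaussian chi perturbation, cooled accept-if-lower annealing, Cartesian
# minimization, and interaction-energy scoring. All models share the
# template's backbone coordinates.

# derive a per-model / per-mutation seed from a master seed and a tag;
# kept below 2^31 - 1
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483587)
}

# fast side-chain rebuild context: global rows of beyond-CB atoms in
# z-matrix order plus the backbone anchors
sidechain_ctx <- function(structure, chain, resno) {
  idx <- residue_index(structure, chain, resno)
  at <- structure$atoms
  res <- at$resid[idx[1]]
  topo <- sidechain_topology[[res]]
  nm <- at$elety[idx]
  get1 <- function(a) structure$xyz[idx[match(a, nm)], ]
  rows <- if (is.null(topo$zmat)) integer(0) else idx[match(topo$zmat$name, nm)]
  if (anyNA(rows)) stop("incomplete side chain at ", chain, resno)
  list(res = res, rows = rows, nchi = topo$nchi,
       N = get1("N"), CA = get1("CA"),
       CB = if (res != "GLY") get1("CB") else NULL)
}

fast_set_chis <- function(xyz, ctx, chis) {
  if (length(ctx$rows) == 0) return(xyz)
  xyz[ctx$rows, ] <- build_sidechain_coords(ctx$res, ctx$N, ctx$CA, ctx$CB, chis)
  xyz
}

# annealing stage for one side chain: an accept-if-lower rotamer scan
# (the barrier-crossing move the simulated-annealing protocol provides)
# followed by cooled Gaussian chi refinement; returns the updated
# coordinates and chi angles
anneal_sidechain <- function(xyz, sc, mctx, rot_rows, chis, config,
                             dielectric) {
  if (sc$nchi == 0) return(list(xyz = xyz, chis = chis))
  cur <- min_objective(xyz, mctx, dielectric)$E
  sig <- config$anneal_sigma
  for (k in seq_len(nrow(rot_rows))) {
    prop <- rot_chis(rot_rows[k, , drop = FALSE], sc$nchi)
    xyz_p <- fast_set_chis(xyz, sc, prop)
    ep <- min_objective(xyz_p, mctx, dielectric)$E
    if (is.finite(ep) && ep < cur) { xyz <- xyz_p; cur <- ep; chis <- prop }
  }
  for (cyc in seq_len(config$n_anneal)) {
    prop <- chis + stats::rnorm(sc$nchi, 0, sig)
    xyz_p <- fast_set_chis(xyz, sc, prop)
    ep <- min_objective(xyz_p, mctx, dielectric)$E
    if (is.finite(ep) && ep < cur) { xyz <- xyz_p; cur <- ep; chis <- prop }
    sig <- sig * config$cool
  }
  list(xyz = xyz, chis = chis)
}

#' Build a randomized, relaxed model ensemble for one mutation
#'
#' For each model: a rotamer is drawn from the library prior, its chi
#' angles are Gaussian-perturbed, an accept-if-lower annealing loop with
#' geometric cooling refines the chi angles, the neighbourhood is relaxed
#' by Cartesian minimization, and the full antibody-antigen interaction
#' energy is recorded. Deterministic under `seed`.
#'
#' @param structure parameterized template `cstruct`.
#' @param spec a [mutation_spec()]; the wild-type identity is allowed
#'   (used for reference/control ensembles).
#' @param n_models number of models (>= 1).
#' @param config a [min_config()].
#' @param seed master seed for this ensemble.
#' @param library rotamer library.
#' @param keep_models keep the per-model structures (memory-heavy).
#' @param dielectric dielectric constant for scoring and objective.
#' @param allow_risky passed to [mutate_residue()].
#' @return list of class `model_ensemble`: `id`, `models` data frame
#'   (model, e_elec, e_vdw, e_total, converged, n_steps, min_cross_dist,
#'   ok, reason), optional `structures`, and the seed.
#' @export
build_ensemble <- function(structure, spec, n_models = 100,
                           config = min_config(), seed = 1,
                           library = default_rotamer_library(),
                           keep_models = FALSE, dielectric = 80,
                           allow_risky = FALSE) {
  stopifnot(n_models >= 1)
  id <- mutation_id(structure, spec)
  base <- mutate_residue(structure, mutation_spec(spec$chain, spec$resno,
                                                  spec$target, "most_probable"),
                         library, allow_risky = allow_risky)
  sctx <- sidechain_ctx(base, spec$chain, spec$resno)
  neigh <- residues_near_sidechain(base, spec$chain, spec$resno,
                                   config$movable_radius)
  movable <- movable_selection(base, neigh)
  if (length(movable) == 0)
    stop("no movable atoms around ", id, " (all-Gly/Ala neighbourhood)")
  mctx <- min_context(base, movable, config)
  rot_rows <- library[library$residue == spec$target, , drop = FALSE]
  # every residue of the movable set gets the same perturb+anneal
  # treatment as in the wild-type reference and in the same (chain,
  # residue) order; only the focal residue starts from a prior-sampled
  # rotamer instead of its current chi angles. Identity mutations then
  # reproduce the reference distribution.
  neigh <- neigh[order(neigh$chain, neigh$resno), ]
  octx <- list(); orot <- list(); ofocal <- logical(0)
  for (i in seq_len(nrow(neigh))) {
    sc <- sidechain_ctx(base, neigh$chain[i], neigh$resno[i])
    if (sc$nchi > 0) {
      octx[[length(octx) + 1]] <- sc
      orot[[length(orot) + 1]] <- library[library$residue == sc$res, , drop = FALSE]
      ofocal <- c(ofocal, neigh$chain[i] == spec$chain &
                            neigh$resno[i] == spec$resno)
    }
  }

  rows <- vector("list", n_models)
  structures <- if (keep_models) vector("list", n_models) else NULL
  for (m in seq_len(n_models)) {
    set.seed(derive_seed(seed, paste0(id, ":", m)))
    xyz <- base$xyz
    ok <- TRUE
    for (k in seq_along(octx)) {
      sc <- octx[[k]]
      if (ofocal[k]) {
        placed <- FALSE
        for (attempt in seq_len(config$retry_limit)) {
          kk <- sample.int(nrow(orot[[k]]), 1, prob = orot[[k]]$prob)
          ch <- rot_chis(orot[[k]][kk, , drop = FALSE], sc$nchi) +
            stats::rnorm(sc$nchi, 0, config$anneal_sigma)
          xyz2 <- fast_set_chis(xyz, sc, ch)
          if (is.finite(min_objective(xyz2, mctx, dielectric)$E)) {
            xyz <- xyz2; placed <- TRUE; break
          }
        }
        if (!placed &&
            !is.finite(min_objective(xyz, mctx, dielectric)$E)) {
          ok <- FALSE
          break
        }
      } else {
        ch <- measure_chis_xyz(xyz, sc) +
          stats::rnorm(sc$nchi, 0, config$anneal_sigma)
        xyz2 <- fast_set_chis(xyz, sc, ch)
        if (is.finite(min_objective(xyz2, mctx, dielectric)$E)) xyz <- xyz2
      }
      ann <- anneal_sidechain(xyz, sc, mctx, orot[[k]],
                              measure_chis_xyz(xyz, sc), config, dielectric)
      xyz <- ann$xyz
    }
    if (!ok) {
      rows[[m]] <- data.frame(model = m, e_elec = NA_real_, e_vdw = NA_real_,
                              e_total = NA_real_, converged = FALSE,
                              n_steps = 0L, min_cross_dist = NA_real_,
                              ok = FALSE, reason = "non-finite start")
      next
    }
    mres <- minimize_xyz(xyz, mctx, config, dielectric)
    mod <- base
    mod$xyz <- mres$xyz
    eb <- interaction_energy(mod, energy_config(dielectric = dielectric))
    rows[[m]] <- data.frame(model = m, e_elec = eb$e_elec, e_vdw = eb$e_vdw,
                            e_total = eb$e_total, converged = mres$converged,
                            n_steps = mres$n_steps,
                            min_cross_dist = min_cross_distance(mod),
                            ok = TRUE, reason = NA_character_)
    if (keep_models) structures[[m]] <- mod
  }
  models <- do.call(rbind, rows)
  if (all(!models$ok))
    stop("all models failed for ", id, ": ",
         paste(unique(models$reason), collapse = "; "))
  structure(list(id = id, spec = spec, models = models,
                 structures = structures, seed = seed),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  ok <- x$models$ok
  cat(sprintf("<model_ensemble> %s: %d models (%d ok, %d converged), median E = %.3f kcal/mol\n",
              x$id, nrow(x$models), sum(ok), sum(x$models$converged),
              stats::median(x$models$e_total[ok])))
  invisible(x)
}
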