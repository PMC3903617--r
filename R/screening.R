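# Saturation-screen orchestration: mutation library enumeration,
# wild-type reference ensemble, contact filtering, median energy shifts
# (delta E) and candidate ranking/selection.

#' Screening configuration
#'
#' @param n_models_per_mutation models per mutation ensemble (default 100).
#' @param n_wt_models wild-type reference models (default 1000).
#' @param contact_cutoff heavy-atom contact cutoff (A) for the
#'   no-contact model filter and the interface definition (default 4.5).
#' @param delta_threshold selection rule: delta E at or below this value
#'   (kcal/mol, default -1.0).
#' @param min_valid_fraction selection rule: minimum fraction of valid
#'   (contact-bearing, scored) models (default 0.5).
#' @param seed master seed; per-mutation seeds are derived from it and
#'   the mutation id so results are independent of execution order.
#' @param min_cfg a [min_config()].
#' @param dielectric dielectric constant.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(n_models_per_mutation = 100, n_wt_models = 1000,
                          contact_cutoff = 4.5, delta_threshold = -1.0,
                          min_valid_fraction = 0.5, seed = 1,
                          min_cfg = min_config(), dielectric = 80) {
  stopifnot(n_models_per_mutation >= 2, is.finite(delta_threshold))
  structure(as.list(environment()), class = "screen_config")
}

#' Enumerate the saturation mutation library
#'
#' For each selected position, exactly 19 specs: every standard amino
#' acid except the wild-type identity, in fixed alphabetical (3-letter)
#' order.
#'
#' @param structure a `cstruct`.
#' @param selection a `cdr_selection` (or data frame with chain, resno).
#' @return list of [mutation_spec()] objects, length 19 x positions.
#' @export
enumerate_library <- function(structure, selection) {
  if (nrow(selection) == 0) stop("selection is empty")
  key <- paste(selection$chain, selection$resno)
  if (anyDuplicated(key)) stop("duplicate position(s) in selection: ",
                               paste(unique(key[duplicated(key)]), collapse = ", "))
  specs <- list()
  for (i in seq_len(nrow(selection))) {
    idx <- residue_index(structure, selection$chain[i], selection$resno[i])
    if (length(idx) == 0)
      stop("position ", key[i], " absent from structure")
    wt <- structure$atoms$resid[idx[1]]
    if (!wt %in% aa_three) stop("unknown wild-type identity at ", key[i])
    for (aa in setdiff(aa_three, wt))
      specs[[length(specs) + 1]] <- mutation_spec(selection$chain[i],
                                                  selection$resno[i], aa)
  }
  specs
}

#' Wild-type reference ensemble
#'
#' Models of the unmutated complex: the side chains of all interface
#' residues are Gaussian-perturbed in their chi angles and the
#' neighbourhood is relaxed by minimization; the interaction-energy
#' distribution and its median are the reference against which every
#' mutation is compared.
#'
#' @param structure parameterized `cstruct`.
#' @param config a [screen_config()].
#' @return list of class `wt_reference`: `energies`, `median`,
#'   `histogram` (hist object), `models` data frame.
#' @export
wt_reference <- function(structure, config = screen_config()) {
  iface <- interface_residues(structure, config$contact_cutoff)
  resl <- unique(rbind(
    stats::setNames(iface$residues_a, c("chain", "resno")),
    stats::setNames(iface$residues_b, c("chain", "resno"))))
  if (nrow(resl) == 0) stop("no interface residues at cutoff ",
                            config$contact_cutoff)
  # relax the same neighbourhood a mutation ensemble would: interface
  # side chains plus residues within the movable radius of them
  nb <- lapply(seq_len(nrow(resl)), function(i)
    residues_near_sidechain(structure, resl$chain[i], resl$resno[i],
                            config$min_cfg$movable_radius))
  relax <- unique(do.call(rbind, c(list(resl), nb)))
  relax <- relax[order(relax$chain, relax$resno), ]
  movable <- movable_selection(structure, relax)
  ctxs <- list()
  for (i in seq_len(nrow(relax))) {
    sc <- sidechain_ctx(structure, relax$chain[i], relax$resno[i])
    if (sc$nchi > 0) ctxs[[length(ctxs) + 1]] <- sc
  }
  if (length(movable) == 0) {
    # rigid interface: a zero-width distribution at the static energy
    e <- interaction_energy(structure,
                            energy_config(dielectric = config$dielectric))$e_total
    energies <- rep(e, config$n_wt_models)
    models <- data.frame(model = seq_len(config$n_wt_models), e_total = energies,
                         converged = TRUE, n_steps = 0L)
  } else {
    mctx <- min_context(structure, movable, config$min_cfg)
    library <- default_rotamer_library()
    rotl <- lapply(ctxs, function(sc)
      library[library$residue == sc$res, , drop = FALSE])
    rows <- vector("list", config$n_wt_models)
    for (m in seq_len(config$n_wt_models)) {
      set.seed(derive_seed(config$seed, paste0("wtref:", m)))
      xyz <- structure$xyz
      for (k in seq_along(ctxs)) {
        sc <- ctxs[[k]]
        chis <- measure_chis_xyz(xyz, sc) +
          stats::rnorm(sc$nchi, 0, config$min_cfg$anneal_sigma)
        xyz2 <- fast_set_chis(xyz, sc, chis)
        if (is.finite(min_objective(xyz2, mctx, config$dielectric)$E))
          xyz <- xyz2
        ann <- anneal_sidechain(xyz, sc, mctx, rotl[[k]],
                                measure_chis_xyz(xyz, sc),
                                config$min_cfg, config$dielectric)
        xyz <- ann$xyz
      }
      mres <- minimize_xyz(xyz, mctx, config$min_cfg, config$dielectric)
      mod <- structure
      mod$xyz <- mres$xyz
      eb <- interaction_energy(mod, energy_config(dielectric = config$dielectric))
      rows[[m]] <- data.frame(model = m, e_total = eb$e_total,
                              converged = mres$converged, n_steps = mres$n_steps)
    }
    models <- do.call(rbind, rows)
    energies <- models$e_total
  }
  structure(list(energies = energies, median = stats::median(energies),
                 histogram = graphics::hist(energies, plot = FALSE),
                 models = models),
            class = "wt_reference")
}

# measure chis from a coordinate matrix using a sidechain_ctx (wild-type
# template geometry; ctx rows are in z-matrix order)
measure_chis_xyz <- function(xyz, sc) {
  defs <- chi_atom_names[[sc$res]]
  if (is.null(defs)) return(numeric(0))
  anchor <- list(N = sc$N, CA = sc$CA, CB = sc$CB)
  topo <- sidechain_topology[[sc$res]]
  getp <- function(a) {
    if (a %in% names(anchor)) return(anchor[[a]])
    xyz[sc$rows[match(a, topo$zmat$name)], ]
  }
  vapply(defs[seq_len(sc$nchi)], function(quad)
    dihedral(getp(quad[1]), getp(quad[2]), getp(quad[3]), getp(quad[4])),
    numeric(1))
}

#' Drop ensemble models lacking antibody-antigen contact
#'
#' Models whose minimum cross-partner heavy-atom distance exceeds the
#' cutoff carry no non-covalent interaction and are excluded from the
#' energy statistics.
#'
#' @param ensemble a `model_ensemble`.
#' @param cutoff heavy-atom contact cutoff, A.
#' @return The ensemble with non-contact models marked invalid; the count
#'   removed is in `$n_filtered`.
#' @export
filter_no_contact <- function(ensemble, cutoff = 4.5) {
  md <- ensemble$models
  drop <- md$ok & (is.na(md$min_cross_dist) | md$min_cross_dist > cutoff)
  md$ok[drop] <- FALSE
  md$reason[drop] <- "no-contact"
  ensemble$models <- md
  ensemble$n_filtered <- sum(drop)
  ensemble
}

#' Median energy shift of a mutation ensemble vs the wild-type reference
#'
#' delta E = median(mutant model energies) - median(wild-type reference);
#' negative values favor binding.
#'
#' @param energies numeric vector of valid model energies (kcal/mol).
#' @param wt_median wild-type reference median (kcal/mol).
#' @return delta E in kcal/mol.
#' @export
delta_energy <- function(energies, wt_median) {
  energies <- energies[is.finite(energies)]
  if (length(energies) == 0) stop("no valid model energies")
  stats::median(energies) - wt_median
}

#' Rank screening results and apply the selection rule
#'
#' Sorts ascending by delta E (NA last) and flags mutations selected by
#' the rule: delta E <= threshold AND valid-model fraction >= minimum.
#' Ties break deterministically by (chain, position, target) order.
#'
#' @param results data frame with one row per mutation (columns id,
#'   chain, resno, wt, target, n_models, n_valid, n_filtered, median,
#'   delta_e).
#' @param config a [screen_config()].
#' @return The ranked data frame with `valid_fraction`, `selected`, `rank`.
#' @export
rank_and_select <- function(results, config = screen_config()) {
  if (nrow(results) == 0) stop("no results to rank")
  results$valid_fraction <- results$n_valid / results$n_models
  results$selected <- !is.na(results$delta_e) &
    results$delta_e <= config$delta_threshold &
    results$valid_fraction >= config$min_valid_fraction
  ord <- order(is.na(results$delta_e), results$delta_e,
               results$chain, results$resno, results$target)
  results <- results[ord, ]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  results
}

#' Run the full saturation screen
#'
#' Orchestrates: wild-type reference ensemble, per-mutation ensembles
#' (seeds derived from the master seed and the mutation id, so results
#' are byte-identical regardless of execution order), no-contact
#' filtering, delta E, and ranking/selection.
#'
#' @param structure parameterized `cstruct`.
#' @param selection a `cdr_selection` (or data frame chain/resno) of
#'   mutable positions.
#' @param config a [screen_config()].
#' @return list of class `screen_report`: `report` (ranked data frame),
#'   `wt` (reference), `excluded` (all-no-contact mutations), `config`.
#' @export
run_screen <- function(structure, selection, config = screen_config()) {
  check_parameterized(structure)
  specs <- enumerate_library(structure, selection)
  wt <- wt_reference(structure, config)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    idx <- residue_index(structure, spec$chain, spec$resno)
    wt_aa <- structure$atoms$resid[idx[1]]
    id <- mutation_id(structure, spec)
    row <- data.frame(id = id, chain = spec$chain, resno = spec$resno,
                      wt = wt_aa, target = spec$target,
                      n_models = config$n_models_per_mutation,
                      n_valid = 0L, n_filtered = 0L,
                      median = NA_real_, delta_e = NA_real_,
                      reason = NA_character_, stringsAsFactors = FALSE)
    ens <- tryCatch(
      build_ensemble(structure, spec,
                     n_models = config$n_models_per_mutation,
                     config = config$min_cfg,
                     seed = derive_seed(config$seed, id),
                     dielectric = config$dielectric),
      error = function(e) e)
    if (inherits(ens, "error")) {
      row$reason <- conditionMessage(ens)
    } else {
      ens <- filter_no_contact(ens, config$contact_cutoff)
      ok <- ens$models$ok
      row$n_valid <- sum(ok)
      row$n_filtered <- ens$n_filtered
      if (any(ok)) {
        row$median <- stats::median(ens$models$e_total[ok])
        row$delta_e <- delta_energy(ens$models$e_total[ok], wt$median)
      } else {
        row$reason <- "no-contact"
      }
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  excluded <- results[results$n_valid == 0, , drop = FALSE]
  report <- rank_and_select(results, config)
  structure(list(report = report, wt = wt, excluded = excluded,
                 config = config), class = "screen_report")
}

#' Write a screening report to disk
#'
#' Emits `report.tsv` (full precision) and `histogram_wt.tsv` under
#' `out_dir`.
#'
#' @param screen a `screen_report` from [run_screen()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_report <- function(screen, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(screen$report, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  h <- screen$wt$histogram
  utils::write.table(data.frame(bin_left = h$breaks[-length(h$breaks)],
                                bin_right = h$breaks[-1], count = h$counts),
                     file.path(out_dir, "histogram_wt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
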