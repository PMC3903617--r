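# Seeded synthetic generators: toy helical complexes with controllable
# charge complementarity at the interface (test bed for the screen), and
# simulated kinetics / sensorgrams with known ground truth (test bed for
# the fitting stages).

#' Specification of a toy two-helix complex
#'
#' Two ideal alpha-helices (rise 1.5 A/residue, 100 deg/residue, C-alpha
#' radius 2.3 A) face each other across `separation` angstrom of axis
#' spacing. The planted site on chain A points straight at a fixed
#' facing residue on chain B, giving a controllable electrostatic
#' complementarity test bed.
#'
#' @param n_res residues per chain (default 11).
#' @param separation axis-to-axis distance, A (default 13.5).
#' @param site planted position index on both chains (default middle).
#' @param site_res wild-type identity at the planted site on A.
#' @param facing_res residue planted opposite on B (default "GLU").
#' @param seq_a,seq_b optional explicit 3-letter sequences (overridden at
#'   the planted positions by `site_res`/`facing_res`).
#' @param rotamer rotamer policy for side-chain building.
#' @param seed RNG seed (used only when `rotamer = "sample"`).
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_res = 11, separation = 13.5,
                             site = (n_res + 1) %/% 2,
                             site_res = "GLN", facing_res = "GLU",
                             seq_a = NULL, seq_b = NULL,
                             rotamer = "most_probable", seed = 1) {
  stopifnot(separation > 0, n_res >= 3, site >= 1, site <= n_res)
  base <- rep(c("ALA", "SER", "LEU", "THR"), length.out = n_res)
  if (is.null(seq_a)) seq_a <- base
  if (is.null(seq_b)) seq_b <- base
  seq_a <- aa_to_three(seq_a); seq_b <- aa_to_three(seq_b)
  if (length(seq_a) != n_res || length(seq_b) != n_res)
    stop("sequences must have n_res residues")
  seq_a[site] <- aa_to_three(site_res)
  seq_b[site] <- aa_to_three(facing_res)
  structure(list(n_res = n_res, separation = separation, site = site,
                 seq_a = seq_a, seq_b = seq_b, rotamer = rotamer,
                 seed = seed), class = "toy_complex_spec")
}

# one ideal helix chain as (atoms df, xyz); phase chosen so residue
# `point_at` faces direction `face_deg`
build_helix_chain <- function(chain_id, seqs, cx, phase_deg, rotamer,
                              library) {
  rise <- 1.5; turn <- 100; radius <- 2.3
  ca_at <- function(t) c(cx + radius * cos((phase_deg + turn * (t - 1)) * pi / 180),
                         radius * sin((phase_deg + turn * (t - 1)) * pi / 180),
                         rise * (t - 1))
  atoms <- list(); xyz <- list()
  for (i in seq_along(seqs)) {
    res <- seqs[i]
    N <- ca_at(i - 0.38); CA <- ca_at(i); C <- ca_at(i + 0.37)
    rad_u <- unit(c(C[1] - cx, C[2], 0))
    O <- C + 1.23 * rad_u
    nm <- c("N", "CA", "C", "O")
    crd <- rbind(N, CA, C, O)
    if (res != "GLY") {
      CB <- ideal_cb(N, CA, C)
      nm <- c(nm, "CB")
      crd <- rbind(crd, CB)
      chis <- pick_rotamer(res, rotamer, library)
      sc <- build_sidechain_coords(res, N, CA, CB, chis)
      if (!is.null(sc)) { nm <- c(nm, rownames(sc)); crd <- rbind(crd, sc) }
    }
    atoms[[i]] <- data.frame(chain = chain_id, resno = i, insert = "",
                             resid = res, elety = nm,
                             element = element_from_name(nm),
                             stringsAsFactors = FALSE)
    xyz[[i]] <- crd
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

#' Build a toy two-helix complex
#'
#' @param spec a [toy_complex_spec()].
#' @param library rotamer library.
#' @param path optional path: also write the structure as PDB.
#' @return a `cstruct` (partition A/B), not yet parameterized.
#' @export
make_toy_complex <- function(spec = toy_complex_spec(),
                             library = default_rotamer_library(),
                             path = NULL) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  turn <- 100
  phase_a <- -turn * (spec$site - 1)          # site points toward +x (B)
  phase_b <- 180 - turn * (spec$site - 1)     # facing residue points -x (A)
  a <- build_helix_chain("A", spec$seq_a, 0, phase_a, spec$rotamer, library)
  b <- build_helix_chain("B", spec$seq_b, spec$separation, phase_b,
                         spec$rotamer, library)
  s <- new_cstruct(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz),
                   c(A = "A", B = "B"))
  s <- pack_rotamers(s, library)
  if (!is.null(path)) write_pdb(s, path)
  s
}

# deterministic greedy rotamer packing: per residue (in chain order),
# keep the rotamer whose static nonbonded energy (Coulomb + LJ, eps_r 80)
# against the rest of the structure is lowest (prior order breaks ties).
# Puts the generated template into its native side-chain basin, the way a
# crystal structure would be -- clash-free and contact-optimal.
pack_rotamers <- function(structure, library = default_rotamer_library()) {
  ps <- parameterize(structure)
  at <- ps$atoms
  rt <- residue_table(ps)
  kC <- ab_constants$coulomb_k / 80
  for (i in seq_len(nrow(rt))) {
    res <- rt$resid[i]
    nchi <- sidechain_topology[[res]]$nchi
    if (is.null(nchi) || nchi == 0) next
    sc <- sidechain_ctx(ps, rt$chain[i], rt$resno[i])
    ridx <- residue_index(ps, rt$chain[i], rt$resno[i])
    env <- setdiff(seq_len(nrow(at)), ridx)  # own residue excluded
    rows <- library[library$residue == res, , drop = FALSE]
    qq <- kC * outer(at$charge[sc$rows], at$charge[env])
    rmin <- outer(at$rmin2[sc$rows], at$rmin2[env], "+")
    epsij <- sqrt(outer(at$eps[sc$rows], at$eps[env]))
    best_e <- Inf; best_xyz <- NULL
    for (k in seq_len(nrow(rows))) {
      chis <- rot_chis(rows[k, , drop = FALSE], nchi)
      xyz_k <- fast_set_chis(ps$xyz, sc, chis)
      d2 <- cross_dist2(xyz_k[sc$rows, , drop = FALSE],
                        xyz_k[env, , drop = FALSE])
      s6 <- (rmin^2 / d2)^3
      e <- sum(qq / sqrt(d2)) + sum(epsij * (s6^2 - 2 * s6))
      if (is.finite(e) && e < best_e - 1e-9) { best_e <- e; best_xyz <- xyz_k }
    }
    if (!is.null(best_xyz)) ps$xyz <- best_xyz
  }
  structure$xyz <- ps$xyz
  structure
}

#' Planted charge-complementarity mutation benchmark
#'
#' Builds a toy complex whose planted site on the antibody side faces a
#' fixed charged residue (Glu) on the antigen side, and computes an
#' exact oracle: for every substitution at the site, the best (minimum)
#' interaction energy over an exhaustive rotamer enumeration in a static
#' environment (no minimization), expressed as a shift against the
#' wild-type identity. The oracle is the brute-force reference for the
#' screening pipeline: complementary charges (Arg/Lys) come out
#' favorable, like charges (Asp/Glu) unfavorable.
#'
#' @param seed RNG seed for the generator.
#' @param spec optional [toy_complex_spec()] override.
#' @param dielectric dielectric constant for the oracle energies.
#' @return list: `complex` (parameterized `cstruct`), `site` (chain,
#'   resno, wt), `facing`, `oracle` (data frame aa, e_best, delta_e),
#'   `favorable`, `unfavorable` (character vectors of 3-letter codes).
#' @export
plant_mutation_benchmark <- function(seed = 1, spec = NULL, dielectric = 80) {
  if (is.null(spec)) spec <- toy_complex_spec(seed = seed)
  cs <- parameterize(make_toy_complex(spec))
  site <- spec$site
  wt <- cs$atoms$resid[residue_index(cs, "A", site)][1]
  library <- default_rotamer_library()
  best <- numeric(0)
  for (aa in aa_three) {
    rows <- library[library$residue == aa, , drop = FALSE]
    nchi <- sidechain_topology[[aa]]$nchi
    e_aa <- Inf
    for (k in seq_len(nrow(rows))) {
      chis <- rot_chis(rows[k, , drop = FALSE], nchi)
      st <- replace_sidechain(cs, "A", site, aa, chis)
      e <- tryCatch(
        interaction_energy(st, energy_config(dielectric = dielectric))$e_total,
        error = function(e) Inf)
      if (is.finite(e) && e < e_aa) e_aa <- e
    }
    best[aa] <- e_aa
  }
  oracle <- data.frame(aa = names(best), e_best = unname(best),
                       delta_e = unname(best - best[wt]))
  oracle <- oracle[oracle$aa != wt, , drop = FALSE]
  rownames(oracle) <- NULL
  list(complex = cs,
       site = list(chain = "A", resno = site, wt = wt),
       facing = list(chain = "B", resno = site,
                     res = cs$atoms$resid[residue_index(cs, "B", site)][1]),
       oracle = oracle,
       favorable = oracle$aa[oracle$delta_e < 0],
       unfavorable = oracle$aa[oracle$delta_e > 0])
}

#' Simulate temperature-series binding kinetics
#'
#' Generative counterpart of the van't Hoff / Eyring models:
#' k_on(T) = (kB T/h) exp(-(dHa - T dSa)/(R T)),
#' K_D(T) = exp((dH - T dS)/(R T)), k_off = K_D k_on, with independent
#' multiplicative lognormal noise (median 1) of coefficient of variation
#' `cv` on k_on and k_off.
#'
#' @param params data frame with columns `variant, dH, dS, dHa, dSa`
#'   (kcal/mol and kcal/mol/K, binding and activation).
#' @param T_grid temperatures, K (>= 3 points).
#' @param cv noise coefficient of variation (>= 0; 0 = noiseless).
#' @param seed RNG seed.
#' @return data frame: variant, T_K, kon, koff, KD.
#' @export
simulate_kinetics <- function(params, T_grid = seq(283, 313, by = 5),
                              cv = 0, seed = 1) {
  stopifnot(length(T_grid) >= 3, cv >= 0)
  need <- c("variant", "dH", "dS", "dHa", "dSa")
  if (!all(need %in% names(params)))
    stop("params must have columns: ", paste(need, collapse = ", "))
  set.seed(seed)
  R <- ab_constants$R_kcal
  sdlog <- sqrt(log(1 + cv^2))
  out <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    kon <- eyring_prefactor(T_grid) * exp(-(p$dHa - T_grid * p$dSa) / (R * T_grid))
    kd <- exp((p$dH - T_grid * p$dS) / (R * T_grid))
    koff <- kd * kon
    if (!all(is.finite(kon) & is.finite(koff)))
      stop("overflow in simulated rates for ", p$variant, " at T = ",
           paste(T_grid[!is.finite(kon * koff)], collapse = ", "), " K")
    if (cv > 0) {
      kon <- kon * exp(stats::rnorm(length(T_grid), 0, sdlog))
      koff <- koff * exp(stats::rnorm(length(T_grid), 0, sdlog))
    }
    out[[i]] <- data.frame(variant = p$variant, T_K = T_grid,
                           kon = kon, koff = koff, KD = koff / kon)
  }
  do.call(rbind, out)
}

#' Simulate a Langmuir 1:1 sensorgram set
#'
#' @param kon,koff,rmax generating parameters (1/(M s), 1/s, RU).
#' @param concs analyte concentrations, M.
#' @param t_assoc_end association phase length, s (default 300).
#' @param t_end total trace length, s (default 1200).
#' @param dt sampling interval, s.
#' @param noise_sd additive Gaussian RU noise (absolute, default 0).
#' @param seed RNG seed.
#' @return data frame: t, RU, conc, t_assoc_end.
#' @export
simulate_sensorgram <- function(kon, koff, rmax, concs,
                                t_assoc_end = 300, t_end = 1200, dt = 2,
                                noise_sd = 0, seed = 1) {
  stopifnot(kon > 0, koff > 0, rmax > 0)
  set.seed(seed)
  t <- seq(0, t_end, by = dt)
  out <- list()
  for (cc in concs) {
    ru <- langmuir_response(t, cc, kon, koff, rmax, t_assoc_end)
    if (noise_sd > 0) ru <- ru + stats::rnorm(length(t), 0, noise_sd)
    out[[length(out) + 1]] <- data.frame(t = t, RU = ru, conc = cc,
                                         t_assoc_end = t_assoc_end)
  }
  do.call(rbind, out)
}
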