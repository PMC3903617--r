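# Cartesian relaxation of side chains. The objective is the cross-partner
# nonbonded energy plus nonbonded terms within the movable selection plus
# harmonic ideal-geometry restraints (bonds, 1-3 distances, and rigid
# sp2/ring groups, all as distance harmonics whose equilibria are the
# ideal-build geometry). Minimized by BFGS with Armijo backtracking; the
# accepted-step energy trace is monotone non-increasing by construction.

#' Minimization configuration
#'
#' @param rms_gradient_threshold convergence threshold on the RMS
#'   Cartesian gradient over movable atoms, kcal/mol/A (default 0.01).
#' @param max_steps maximum accepted steps (default 2000).
#' @param movable_radius neighbourhood radius (A) used when deriving the
#'   movable selection around a mutated side chain (default 6).
#' @param n_anneal annealed chi-perturbation cycles before minimization.
#' @param anneal_sigma initial chi perturbation width, degrees.
#' @param cool geometric cooling factor per annealing cycle.
#' @param retry_limit perturb-and-retry attempts on a non-finite start.
#' @param k_bond,k_13,k_rigid harmonic force constants, kcal/mol/A^2.
#' @return list of class `min_config`.
#' @export
min_config <- function(rms_gradient_threshold = 0.01, max_steps = 2000,
                       movable_radius = 6.0, n_anneal = 3,
                       anneal_sigma = 15, cool = 0.6, retry_limit = 3,
                       k_bond = 100, k_13 = 40, k_rigid = 40) {
  stopifnot(rms_gradient_threshold > 0, max_steps >= 1)
  structure(as.list(environment()), class = "min_config")
}

# residue-internal bonded adjacency (heavy atoms), as a list of name pairs
residue_bond_pairs <- function(res) {
  pairs <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (res != "GLY") pairs <- c(pairs, list(c("CA", "CB")))
  topo <- sidechain_topology[[res]]
  if (!is.null(topo$zmat))
    for (i in seq_len(nrow(topo$zmat)))
      pairs <- c(pairs, list(c(topo$zmat$c[i], topo$zmat$name[i])))
  c(pairs, topo$closures)
}

# all 1-3 name pairs induced by the adjacency
residue_13_pairs <- function(bonds) {
  adj <- list()
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  out <- list()
  for (mid in names(adj)) {
    nb <- unique(adj[[mid]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb))) out <- c(out, list(cmb[, k]))
    }
  }
  out
}

#' Derive the movable atom selection around a set of residues
#'
#' Movable atoms are the side-chain atoms beyond the C-beta anchor of the
#' given residues. Backbone and C-beta never move.
#'
#' @param structure a `cstruct`.
#' @param residues data frame with columns `chain`, `resno`.
#' @return integer vector of atom row indices.
#' @export
movable_selection <- function(structure, residues) {
  at <- structure$atoms
  out <- integer(0)
  for (i in seq_len(nrow(residues))) {
    idx <- residue_index(structure, residues$chain[i], residues$resno[i])
    out <- c(out, idx[!(at$elety[idx] %in% c(backbone_names, "CB"))])
  }
  sort(unique(out))
}

#' Residues with a heavy atom near a residue's side chain
#'
#' @param structure a `cstruct`.
#' @param chain,resno the focal residue.
#' @param radius distance cutoff, A.
#' @return data frame chain, resno (includes the focal residue itself).
#' @export
residues_near_sidechain <- function(structure, chain, resno, radius = 6.0) {
  at <- structure$atoms
  idx <- residue_index(structure, chain, resno)
  sc <- idx[!(at$elety[idx] %in% backbone_names)]
  if (length(sc) == 0) sc <- idx
  heavy <- which(at$element != "H")
  d2 <- cross_dist2(structure$xyz[heavy, , drop = FALSE],
                    structure$xyz[sc, , drop = FALSE])
  near <- heavy[apply(d2 <= radius^2, 1, any)]
  rt <- unique(data.frame(chain = at$chain[near], resno = at$resno[near]))
  rt <- rt[order(rt$chain, rt$resno), ]
  rownames(rt) <- NULL
  rt
}

# Precompute the minimization context: restrained pairs, nonbonded pairs
# and their parameters. `movable` = integer atom indices.
min_context <- function(structure, movable, config = min_config()) {
  check_parameterized(structure)
  at <- structure$atoms
  n <- nrow(at)
  if (length(movable) == 0) stop("movable selection is empty")
  is_mov <- rep(FALSE, n); is_mov[movable] <- TRUE

  # residues owning movable atoms
  rkey <- paste(at$chain, at$resno, at$insert)
  res_mov <- unique(rkey[movable])

  ri <- integer(0); rj <- integer(0); rk <- numeric(0)
  excl <- character(0)
  for (key in res_mov) {
    idx <- which(rkey == key)
    res <- at$resid[idx[1]]
    nm <- at$elety[idx]
    gmap <- function(a) idx[match(a, nm)]
    bonds <- residue_bond_pairs(res)
    b13 <- residue_13_pairs(bonds)
    rigid <- sidechain_topology[[res]]$rigid
    add <- function(prs, k) {
      for (p in prs) {
        gi <- gmap(p[1]); gj <- gmap(p[2])
        if (is.na(gi) || is.na(gj)) next
        if (!is_mov[gi] && !is_mov[gj]) next
        ri <<- c(ri, gi); rj <<- c(rj, gj); rk <<- c(rk, k)
      }
    }
    add(bonds, config$k_bond)
    add(b13, config$k_13)
    for (g in rigid) {
      if (length(g) >= 2) {
        cmb <- utils::combn(g, 2)
        add(lapply(seq_len(ncol(cmb)), function(k) cmb[, k]), config$k_rigid)
      }
    }
    # exclusion set for nonbonded: bonded + 1-3 within the residue
    for (p in c(bonds, b13))
      excl <- c(excl, paste(sort(c(gmap(p[1]), gmap(p[2]))), collapse = "_"))
  }
  # dedupe restraints (bond precedence by order of addition)
  rpk <- paste(pmin(ri, rj), pmax(ri, rj), sep = "_")
  dup <- duplicated(rpk)
  ri <- ri[!dup]; rj <- rj[!dup]; rk <- rk[!dup]
  r0 <- sqrt(rowSums((structure$xyz[ri, , drop = FALSE] -
                      structure$xyz[rj, , drop = FALSE])^2))

  # nonbonded pairs: at least one movable atom, and either cross-partner
  # or both within the movable selection; excluded: restrained/1-3 pairs
  part <- at$partner
  cand_i <- integer(0); cand_j <- integer(0)
  others <- seq_len(n)
  for (m in movable) {
    js <- others[(part[others] != part[m]) | (is_mov[others] & others > m)]
    js <- js[!(is_mov[js] & part[js] != part[m] & js < m)]  # avoid cross double-count
    cand_i <- c(cand_i, rep(m, length(js)))
    cand_j <- c(cand_j, js)
  }
  # drop duplicates and self
  pk <- paste(pmin(cand_i, cand_j), pmax(cand_i, cand_j), sep = "_")
  keep <- !duplicated(pk) & cand_i != cand_j & !(pk %in% c(excl, rpk))
  # drop same-residue backbone/CB vs own side chain (anchored by restraints)
  same_res <- rkey[cand_i] == rkey[cand_j]
  keep <- keep & !(same_res & !(is_mov[cand_i] & is_mov[cand_j]))
  ni <- cand_i[keep]; nj <- cand_j[keep]

  # diagonal curvature estimate per movable atom (restraint stiffness),
  # used to precondition the minimizer
  stiff <- rep(1, n)
  for (p in seq_along(ri)) {
    stiff[ri[p]] <- stiff[ri[p]] + 2 * rk[p]
    stiff[rj[p]] <- stiff[rj[p]] + 2 * rk[p]
  }
  list(
    movable = movable, n = n, pdiag = rep(1 / stiff[movable], 3),
    ri = ri, rj = rj, rk = rk, r0 = r0,
    ni = ni, nj = nj,
    qq = ab_constants$coulomb_k * at$charge[ni] * at$charge[nj],
    epsij = sqrt(at$eps[ni] * at$eps[nj]),
    rmin = at$rmin2[ni] + at$rmin2[nj],
    config = config
  )
}

# objective and gradient over the full coordinate matrix; gradient is
# returned only for movable atoms (fixed atoms contribute no freedom).
# Compiled kernel; min_objective_ref is the plain-R reference it mirrors.
min_objective <- function(xyz, ctx, dielectric = 80) {
  .obj_grad_cpp(xyz, ctx$ni, ctx$nj, ctx$qq, ctx$epsij, ctx$rmin,
                ctx$ri, ctx$rj, ctx$rk, ctx$r0, ctx$movable, dielectric)
}

min_objective_ref <- function(xyz, ctx, dielectric = 80) {
  di <- xyz[ctx$ni, , drop = FALSE] - xyz[ctx$nj, , drop = FALSE]
  r2 <- rowSums(di^2)
  if (any(r2 < 1e-12)) return(list(E = Inf, G = NULL))
  r <- sqrt(r2)
  s6 <- (ctx$rmin^2 / r2)^3
  e_nb <- sum(ctx$qq / (dielectric * r)) + sum(ctx$epsij * (s6^2 - 2 * s6))
  dr <- xyz[ctx$ri, , drop = FALSE] - xyz[ctx$rj, , drop = FALSE]
  rr <- sqrt(rowSums(dr^2))
  e_res <- sum(ctx$rk * (rr - ctx$r0)^2)
  dEdr_nb <- -ctx$qq / (dielectric * r2) - ctx$epsij * (12 / r) * (s6^2 - s6)
  dEdr_res <- 2 * ctx$rk * (rr - ctx$r0)
  G <- matrix(0, ctx$n, 3)
  fu <- di * (dEdr_nb / r)
  fr <- dr * (dEdr_res / rr)
  gidx <- c(ctx$ni, ctx$nj, ctx$ri, ctx$rj)
  for (col in 1:3) {
    vals <- c(fu[, col], -fu[, col], fr[, col], -fr[, col])
    sums <- rowsum(vals, gidx)
    G[as.integer(rownames(sums)), col] <- sums[, 1]
  }
  list(E = e_nb + e_res, G = G[ctx$movable, , drop = FALSE])
}

#' Relax movable atoms by quasi-Newton minimization
#'
#' BFGS with Armijo backtracking on the Cartesian coordinates of the
#' movable atoms; stops when the RMS gradient falls below the threshold
#' or `max_steps` is reached. The energy trace over accepted steps is
#' monotone non-increasing.
#'
#' @param structure a parameterized `cstruct`.
#' @param movable integer atom indices (see [movable_selection()]).
#' @param config a [min_config()].
#' @param dielectric dielectric constant for the objective's Coulomb term.
#' @param ctx precomputed context from an earlier call (internal reuse).
#' @return list with `structure` (relaxed), `trace` (energies at accepted
#'   steps), `converged`, `n_steps`, `rms_grad`.
#' @export
minimize <- function(structure, movable, config = min_config(),
                     dielectric = 80, ctx = NULL) {
  if (is.null(ctx)) ctx <- min_context(structure, movable, config)
  res <- minimize_xyz(structure$xyz, ctx, config, dielectric)
  structure$xyz <- res$xyz
  list(structure = structure, trace = res$trace, converged = res$converged,
       n_steps = res$n_steps, rms_grad = res$rms_grad)
}

minimize_xyz <- function(xyz, ctx, config = ctx$config, dielectric = 80) {
  res <- .lbfgs_cpp(xyz, ctx$ni, ctx$nj, ctx$qq, ctx$epsij, ctx$rmin,
                    ctx$ri, ctx$rj, ctx$rk, ctx$r0, ctx$movable, ctx$pdiag,
                    dielectric, config$rms_gradient_threshold,
                    as.integer(config$max_steps))
  res
}

# plain-R reference of the same preconditioned L-BFGS descent; kept as the
# independent check of the compiled path
minimize_xyz_ref <- function(xyz, ctx, config = ctx$config, dielectric = 80) {
  mov <- ctx$movable
  m <- length(mov)
  x <- as.vector(xyz[mov, , drop = FALSE])
  setx <- function(x) { xyz[mov, ] <- matrix(x, m, 3); xyz }
  ob <- min_objective_ref(setx(x), ctx, dielectric)
  f <- ob$E
  if (!is.finite(f))
    return(list(xyz = xyz, trace = f, converged = FALSE, n_steps = 0L,
                rms_grad = Inf))
  g <- as.vector(ob$G)
  trace <- f
  n_steps <- 0L
  rms <- sqrt(mean(g^2))
  # L-BFGS memory (two-loop recursion)
  mem <- 10L
  S <- list(); Y <- list(); RHO <- numeric(0)
  gamma <- 1
  pdiag <- if (is.null(ctx$pdiag)) rep(1, length(x)) else ctx$pdiag
  while (rms >= config$rms_gradient_threshold && n_steps < config$max_steps) {
    # two-loop recursion for p = -H g
    q <- g
    k <- length(S)
    alpha <- numeric(k)
    if (k > 0) for (i in k:1) {
      alpha[i] <- RHO[i] * sum(S[[i]] * q)
      q <- q - alpha[i] * Y[[i]]
    }
    r <- gamma * pdiag * q
    if (k > 0) for (i in 1:k) {
      beta <- RHO[i] * sum(Y[[i]] * r)
      r <- r + S[[i]] * (alpha[i] - beta)
    }
    p <- -r
    if (sum(p * g) >= 0) p <- -g
    # cap the first trial step so a clash start cannot explode
    t <- min(1, 0.5 / max(sqrt(max(p^2)), 1e-12))
    gp <- sum(g * p)
    ok <- FALSE
    for (ls in 1:40) {
      xn <- x + t * p
      obn <- min_objective_ref(setx(xn), ctx, dielectric)
      if (is.finite(obn$E) && obn$E <= f + 1e-4 * t * gp) { ok <- TRUE; break }
      t <- t / 2
    }
    if (!ok) break
    gn <- as.vector(obn$G)
    s <- xn - x
    y <- gn - g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      S[[length(S) + 1]] <- s
      Y[[length(Y) + 1]] <- y
      RHO <- c(RHO, 1 / sy)
      if (length(S) > mem) { S <- S[-1]; Y <- Y[-1]; RHO <- RHO[-1] }
      gamma <- sy / sum(y * pdiag * y)
    }
    x <- xn; f <- obn$E; g <- gn
    trace <- c(trace, f)
    rms <- sqrt(mean(g^2))
    n_steps <- n_steps + 1L
  }
  list(xyz = setx(x), trace = trace,
       converged = rms < config$rms_gradient_threshold,
       n_steps = n_steps, rms_grad = rms)
}
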