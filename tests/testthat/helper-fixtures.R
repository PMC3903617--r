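# Shared fixtures and independent oracles.

# random complex with residue structure and random nonbonded parameters:
# scaffold for brute-force comparisons (not chemically meaningful)
random_complex <- function(n_res_per_chain = 5, atoms_per_res = 3, seed = 1,
                           spread = 8) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else spread
    for (r in seq_len(n_res_per_chain)) {
      for (a in seq_len(atoms_per_res)) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = ch, resno = r, insert = "", resid = "ALA",
          elety = paste0("X", a), element = sample(c("C", "N", "O"), 1),
          stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1]] <- runif(3, 0, spread) + c(off, 0, 0)
      }
    }
  }
  s <- new_cstruct(do.call(rbind, rows), do.call(rbind, xyz),
                   c(A = "A", B = "B"))
  n <- nrow(s$atoms)
  s$atoms$charge <- round(runif(n, -0.7, 0.7), 3)
  s$atoms$rmin2 <- runif(n, 1.5, 2.1)
  s$atoms$eps <- runif(n, 0.05, 0.3)
  s$atoms$radius <- runif(n, 1.4, 1.9)
  s$parameterized <- TRUE
  s
}

# independent O(n^2) double-loop reference for the interaction energy
brute_force_energy <- function(s, dielectric = 80, cutoff = NULL) {
  at <- s$atoms
  ia <- which(at$partner == "A")
  ib <- which(at$partner == "B")
  ee <- 0; ev <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
    if (!is.null(cutoff) && r > cutoff) next
    ee <- ee + 332.0637 * at$charge[i] * at$charge[j] / (dielectric * r)
    rm <- at$rmin2[i] + at$rmin2[j]
    ev <- ev + sqrt(at$eps[i] * at$eps[j]) * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  list(e_elec = ee, e_vdw = ev, e_total = ee + ev)
}

# independent all-pairs contact scan at residue level
brute_force_contacts <- function(s, cutoff) {
  at <- s$atoms
  ia <- which(at$partner == "A" & at$element != "H")
  ib <- which(at$partner == "B" & at$element != "H")
  out <- character(0)
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((s$xyz[i, ] - s$xyz[j, ])^2))
    if (r <= cutoff)
      out <- c(out, paste(at$chain[i], at$resno[i], at$chain[j], at$resno[j]))
  }
  sort(unique(out))
}

bootstrap_se_median <- function(x, n_boot = 500, seed = 1) {
  set.seed(seed)
  stats::sd(replicate(n_boot, stats::median(sample(x, replace = TRUE))))
}

# two-atom LJ dimer (one atom movable), for analytic minimization checks
lj_dimer <- function(start_frac = 0.9, rmin2 = 1.908, eps = 0.1094) {
  at <- data.frame(chain = c("A", "B"), resno = 1L, insert = "",
                   resid = "ALA", elety = "CB", element = "C",
                   stringsAsFactors = FALSE)
  s <- new_cstruct(at, rbind(c(0, 0, 0), c(start_frac * 2 * rmin2, 0, 0)),
                   c(A = "A", B = "B"))
  s$atoms$charge <- 0
  s$atoms$rmin2 <- rmin2
  s$atoms$eps <- eps
  s$atoms$radius <- 1.7
  s$parameterized <- TRUE
  s
}

# published measurement tables (bundled)
published_kinetics <- function() load_published_tables("kinetics")
published_thermo <- function() load_published_tables("thermo")
published_activation <- function() load_published_tables("activation")
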