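# Parameter assignment and the Coulomb + Lennard-Jones interaction energy.

test_that("parameterize assigns charges that sum to the formal residue charge", {
  seqs <- c("GLY", "ARG", "ASP", "HIS", "LYS", "GLU", "TRP", "SER", "THR",
            "CYS", "MET")
  cs <- make_toy_complex(toy_complex_spec(n_res = 11, seq_a = seqs,
                                          seq_b = rev(seqs),
                                          separation = 20))
  csp <- parameterize(cs)
  at <- csp$atoms
  formal <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)
  for (key in unique(paste(at$chain, at$resno))) {
    rows <- at[paste(at$chain, at$resno) == key, ]
    want <- if (rows$resid[1] %in% names(formal)) formal[[rows$resid[1]]] else 0
    expect_lt(abs(sum(rows$charge) - want), 1e-3)
  }
})

test_that("strict mode names unknown residues; permissive zeroes them", {
  cs <- make_toy_complex()
  cs$atoms$resid[cs$atoms$resno == 2 & cs$atoms$chain == "A"] <- "MSE"
  expect_error(parameterize(cs, mode = "strict"), "MSE")
  expect_warning(csp <- parameterize(cs, mode = "permissive"), "MSE")
  expect_true(all(csp$atoms$charge[csp$atoms$resid == "MSE"] == 0))
})

test_that("coulomb energy matches the closed form and its scalings", {
  s <- lj_dimer()
  s$xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  s$atoms$charge <- c(0.5, -0.5)
  s$atoms$eps <- 0
  e <- coulomb_energy(s, energy_config(dielectric = 80))
  expect_equal(e, 332.0637 * (-0.25) / (80 * 5), tolerance = 1e-10)
  # halving the dielectric doubles the energy exactly
  expect_equal(coulomb_energy(s, energy_config(dielectric = 40)), 2 * e,
               tolerance = 1e-12)
  # linear in any single charge
  s2 <- s; s2$atoms$charge[1] <- 1.0
  expect_equal(coulomb_energy(s2), 2 * e, tolerance = 1e-12)
  # all partner-B charges zero -> 0
  s3 <- s; s3$atoms$charge[2] <- 0
  expect_identical(coulomb_energy(s3), 0)
})

test_that("LJ energy has its minimum at rmin and a finite repulsive wall", {
  s <- lj_dimer()
  rmin <- 2 * 1.908
  s$xyz <- rbind(c(0, 0, 0), c(rmin, 0, 0))
  expect_equal(lj_energy(s), -0.1094, tolerance = 1e-12)
  # closed form at r = 2 rmin
  s$xyz[2, 1] <- 2 * rmin
  expect_equal(lj_energy(s), 0.1094 * (2^-12 - 2 * 2^-6), tolerance = 1e-12)
  # near-contact: large positive but finite
  s$xyz[2, 1] <- 0.1
  e <- lj_energy(s)
  expect_true(is.finite(e) && e > 1e6)
  # exactly zero distance is a clash error
  s$xyz[2, ] <- s$xyz[1, ]
  expect_error(lj_energy(s), "clash")
})

test_that("interaction energy equals the brute-force double loop to 1e-10", {
  for (seed in 1:20) {
    s <- random_complex(n_res_per_chain = 5, atoms_per_res = 3, seed = seed)
    got <- interaction_energy(s)
    ref <- brute_force_energy(s)
    expect_lt(abs(got$e_total - ref$e_total) / max(abs(ref$e_total), 1e-8),
              1e-10)
    expect_equal(got$e_total, got$e_elec + got$e_vdw)
    # with a cutoff
    gotc <- interaction_energy(s, energy_config(cutoff = 6))
    refc <- brute_force_energy(s, cutoff = 6)
    expect_lt(abs(gotc$e_total - refc$e_total) / max(abs(refc$e_total), 1e-8),
              1e-10)
  }
})

test_that("interaction energy is partner-symmetric and rigid-motion invariant", {
  s <- random_complex(seed = 99)
  e1 <- interaction_energy(s)
  swapped <- s
  swapped$atoms$partner <- ifelse(s$atoms$partner == "A", "B", "A")
  e2 <- interaction_energy(swapped)
  expect_identical(e1$e_total, e2$e_total)

  rot <- abmature:::rotation_matrix(c(0.3, -1, 2), 63)
  e3 <- interaction_energy(transform_structure(s, rot, c(10, -4, 7)))
  expect_lt(abs(e3$e_total - e1$e_total) / abs(e1$e_total), 1e-9)

  # distant partners under a short cutoff: exactly zero
  far <- s
  far$xyz[far$atoms$partner == "B", 1] <- far$xyz[far$atoms$partner == "B", 1] + 500
  e4 <- interaction_energy(far, energy_config(cutoff = 12))
  expect_identical(unlist(e4[c("e_elec", "e_vdw", "e_total")], use.names = FALSE),
                   c(0, 0, 0))
})
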