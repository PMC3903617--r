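# Rotamer-based mutation building, chi perturbation, and minimization.

ang_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

test_that("mutation rebuilds side chains with the requested composition", {
  cs <- make_toy_complex()
  # Ala site -> Gly loses exactly CB and beyond
  cs2 <- mutate_residue(cs, mutation_spec("A", 1, "GLY"))
  idx <- abmature:::residue_index(cs2, "A", 1)
  expect_identical(sort(cs2$atoms$elety[idx]), sort(c("N", "CA", "C", "O")))
  expect_identical(cs2$atoms$resid[idx][1], "GLY")

  # identity rebuild: backbone untouched, chis at library values
  cs3 <- mutate_residue(cs, mutation_spec("A", 6, "GLN", "most_probable"))
  bb <- cs$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  bb3 <- cs3$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  expect_identical(cs$xyz[bb, ], cs3$xyz[bb3, ])
  lib <- load_rotamer_library()
  want <- as.numeric(lib[lib$residue == "GLN", ][1, c("chi1", "chi2", "chi3")])
  expect_true(all(ang_diff(measure_chis(cs3, "A", 6), want) < 0.1))

  # Asn -> Arg with the second most probable rotamer: chis match entry 2
  cs4 <- mutate_residue(cs, mutation_spec("A", 6, "ASN"))
  cs5 <- mutate_residue(cs4, mutation_spec("A", 6, "ARG", rotamer = 2))
  want2 <- as.numeric(lib[lib$residue == "ARG", ][2, paste0("chi", 1:4)])
  expect_true(all(ang_diff(measure_chis(cs5, "A", 6), want2) < 0.1))

  # Pro target rejected by default, allowed with the override
  expect_error(mutate_residue(cs, mutation_spec("A", 6, "PRO")), "Pro")
  expect_silent(mutate_residue(cs, mutation_spec("A", 6, "PRO"),
                               allow_risky = TRUE))
})

test_that("chi perturbation is seeded, null at sigma 0, and wraps uniformly", {
  cs <- make_toy_complex()
  expect_identical(perturb_sidechain(cs, "A", 6, 0)$xyz, cs$xyz)

  set.seed(11); p1 <- perturb_sidechain(cs, "A", 6, 15)
  set.seed(11); p2 <- perturb_sidechain(cs, "A", 6, 15)
  expect_identical(p1$xyz, p2$xyz)
  expect_false(identical(p1$xyz, cs$xyz))

  # sigma = 180: resulting chi1 is approximately uniform on (-180, 180]
  set.seed(42)
  draws <- replicate(1000, measure_chis(perturb_sidechain(cs, "A", 2, 180),
                                        "A", 2)[1])
  ks <- suppressWarnings(stats::ks.test(draws, "punif", -180, 180))
  expect_gt(ks$p.value, 0.01)
})

test_that("minimization reaches the analytic LJ dimer minimum", {
  s <- lj_dimer(start_frac = 0.9)
  res <- minimize(s, movable = 2L,
                  config = min_config(rms_gradient_threshold = 1e-6,
                                      max_steps = 500))
  expect_true(res$converged)
  sep <- sqrt(sum((res$structure$xyz[1, ] - res$structure$xyz[2, ])^2))
  expect_lt(abs(sep - 2 * 1.908), 1e-3)
  expect_true(all(diff(res$trace) <= 1e-12))

  # started beyond the minimum it walks back in
  s2 <- lj_dimer(start_frac = 1.3)
  res2 <- minimize(s2, movable = 2L,
                   config = min_config(rms_gradient_threshold = 1e-6,
                                       max_steps = 500))
  sep2 <- sqrt(sum((res2$structure$xyz[1, ] - res2$structure$xyz[2, ])^2))
  expect_lt(abs(sep2 - 2 * 1.908), 1e-3)
})

test_that("a system already below the gradient threshold returns unchanged", {
  s <- lj_dimer()
  s$xyz <- rbind(c(0, 0, 0), c(2 * 1.908, 0, 0))  # exactly at the minimum
  res <- minimize(s, movable = 2L, config = min_config())
  expect_identical(res$n_steps, 0L)
  expect_identical(res$structure$xyz, s$xyz)
  expect_true(res$converged)
})

test_that("minimization traces are monotone non-increasing on perturbed toys", {
  cs <- parameterize(make_toy_complex())
  for (seed in c(3, 14, 27)) {
    set.seed(seed)
    p <- perturb_sidechain(cs, "A", 6, 25)
    mov <- movable_selection(p, residues_near_sidechain(p, "A", 6, 6))
    res <- minimize(p, mov)
    expect_true(all(diff(res$trace) <= 1e-9), info = paste("seed", seed))
    expect_true(res$converged, info = paste("seed", seed))
  }
})

test_that("compiled objective/descent agree with the plain-R reference", {
  cs <- parameterize(make_toy_complex())
  base <- mutate_residue(cs, mutation_spec("A", 6, "ARG"))
  mov <- movable_selection(base, residues_near_sidechain(base, "A", 6, 6))
  ctx <- abmature:::min_context(base, mov, min_config())
  oc <- abmature:::min_objective(base$xyz, ctx)
  or <- abmature:::min_objective_ref(base$xyz, ctx)
  expect_lt(abs(oc$E - or$E), 1e-9)
  expect_lt(max(abs(oc$G - or$G)), 1e-9)
  # numerical gradient spot check
  eps <- 1e-6
  for (k in c(1, 5)) {
    for (col in 1:3) {
      xp <- base$xyz; xp[mov[k], col] <- xp[mov[k], col] + eps
      xm <- base$xyz; xm[mov[k], col] <- xm[mov[k], col] - eps
      num <- (abmature:::min_objective(xp, ctx)$E -
                abmature:::min_objective(xm, ctx)$E) / (2 * eps)
      expect_lt(abs(oc$G[k, col] - num), 1e-4 * max(1, abs(num)))
    }
  }
  # descent paths: identical early trace; both converge monotonically
  # (endpoints may differ across near-degenerate soft-mode minima)
  ctx5 <- abmature:::min_context(base, mov, min_config(max_steps = 10))
  t_c <- abmature:::minimize_xyz(base$xyz, ctx5)$trace
  t_r <- abmature:::minimize_xyz_ref(base$xyz, ctx5)$trace
  expect_equal(t_c, t_r, tolerance = 1e-9)
  full_c <- abmature:::minimize_xyz(base$xyz, ctx)
  full_r <- abmature:::minimize_xyz_ref(base$xyz, ctx)
  expect_true(full_c$converged && full_r$converged)
  expect_true(all(diff(full_r$trace) <= 1e-9))
  expect_lt(abs(utils::tail(full_c$trace, 1) - utils::tail(full_r$trace, 1)), 1)
})

test_that("ensembles are seed-reproducible, convergent, and backbone-rigid", {
  cs <- parameterize(make_toy_complex())
  e1 <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 5, seed = 8)
  e2 <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 5, seed = 8)
  expect_identical(e1$models$e_total, e2$models$e_total)

  e3 <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 100,
                       seed = 3, keep_models = TRUE)
  expect_gte(sum(e3$models$converged), 95)

  # backbone and C-beta anchors never move, exactly
  bb <- e3$structures[[1]]$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  bb0 <- cs$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  for (m in c(1, 50, 100))
    expect_identical(e3$structures[[m]]$xyz[bb, ], cs$xyz[bb0, ])
})

test_that("ensemble medians are stable across seeds within bootstrap error", {
  cs <- parameterize(make_toy_complex())
  ea <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 60, seed = 1)
  eb <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 60, seed = 2)
  ma <- stats::median(ea$models$e_total)
  mb <- stats::median(eb$models$e_total)
  pooled <- sqrt(bootstrap_se_median(ea$models$e_total)^2 +
                   bootstrap_se_median(eb$models$e_total)^2)
  expect_lt(abs(ma - mb), 2 * max(pooled, 1e-3))
})
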