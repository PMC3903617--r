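# SPR kinetics and thermodynamics: K_D, van't Hoff, Eyring, delta-delta
# tables, compensation, Langmuir sensorgram fitting.

test_that("K_D from rates reproduces the published table at 2 s.f.", {
  kt <- published_kinetics()
  kd_nM <- signif(kd_from_rates(kt$kon, kt$koff) * 1e9, 2)
  expect_equal(kd_nM[kt$variant == "L-N31R"], 0.17)
  expect_equal(kd_nM[kt$variant == "L-S53E"], 0.19)
  expect_equal(kd_nM[kt$variant == "L-T56D"], 0.39)
  # internally inconsistent rows are flagged, not matched
  flags <- flag_kd_inconsistency(kt$kon, kt$koff, kt$KD)
  expect_identical(sort(kt$variant[flags]), c("H-N28D", "WT"))
  expect_identical(kd_from_rates(2.5, 2.5), 1)
  expect_error(kd_from_rates(-1, 1), "positive")
})

test_that("Gibbs energy from K_D is zero at 1 M and monotone", {
  expect_identical(gibbs_from_kd(1), 0)
  expect_equal(gibbs_from_kd(0.8e-9, 298.15),
               1.9872e-3 * 298.15 * log(0.8e-9), tolerance = 1e-12)
  expect_equal(round(gibbs_from_kd(0.8e-9, 298.15), 1), -12.4)
  kds <- 10^seq(-12, 0, by = 1)
  expect_true(all(diff(gibbs_from_kd(kds)) > 0))
  expect_error(gibbs_from_kd(-1), "positive")
})

test_that("van't Hoff fit recovers noiseless generating parameters exactly", {
  # generating values: the published L-N31R equilibrium components
  dH <- -25.6; mTdS <- 12.3
  dS <- -mTdS / 298.15
  p <- data.frame(variant = "L-N31R", dH = dH, dS = dS, dHa = 5, dSa = 0)
  sim <- simulate_kinetics(p, cv = 0)
  fit <- vant_hoff_fit(sim$T_K, sim$KD)
  expect_lt(abs(fit$dH - dH) / abs(dH), 1e-6)
  expect_lt(abs(fit$mTdS - mTdS) / abs(mTdS), 1e-6)
  expect_equal(fit$dG, fit$dH - 298.15 * fit$dS)

  # temperature-independent K_D -> dH = 0
  flat <- vant_hoff_fit(c(283, 298, 313), rep(1e-9, 3))
  expect_lt(abs(flat$dH), 1e-9)
  expect_error(vant_hoff_fit(c(283, 298), c(1e-9, 1e-9)), ">= 3")
})

test_that("Eyring fit recovers noiseless activation parameters exactly", {
  dHa <- 11.4; mTdSa <- -0.8
  dSa <- -mTdSa / 298.15
  p <- data.frame(variant = "WT", dH = -7.3, dS = 5.0 / 298.15,
                  dHa = dHa, dSa = dSa)
  sim <- simulate_kinetics(p, cv = 0)
  fit <- eyring_fit(sim$T_K, sim$kon)
  expect_lt(abs(fit$dH - dHa) / abs(dHa), 1e-6)
  expect_lt(abs(fit$mTdS - mTdSa) / abs(mTdSa), 1e-6)

  # k_on proportional to T: enthalpy vanishes (prefactor-only limit)
  T <- seq(283, 313, 5)
  fit2 <- eyring_fit(T, 1e5 * T / 298.15)
  expect_lt(abs(fit2$dH), 0.05)
})

test_that("noisy temperature series recover parameters with small bias", {
  dH <- -7.3; dS <- 5.0 / 298.15; dHa <- 11.4; dSa <- 0.8 / 298.15
  p <- data.frame(variant = "WT", dH = dH, dS = dS, dHa = dHa, dSa = dSa)
  n_seeds <- 100
  est <- t(vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_kinetics(p, T_grid = seq(283, 313, by = 5), cv = 0.05,
                             seed = s)
    c(vant_hoff_fit(sim$T_K, sim$KD)$dH, eyring_fit(sim$T_K, sim$kon)$dH)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1]) - dH) / abs(dH), 0.10)
  expect_lt(abs(stats::median(est[, 2]) - dHa) / abs(dHa), 0.10)
})

test_that("delta tables reproduce the published energetics identities", {
  kt <- published_kinetics()
  kd <- stats::setNames(kt$KD, kt$variant)
  td <- delta_table(published_thermo(), "WT", kd = kd)
  expect_equal(td$dG[td$variant == "WT"], -12.3)
  expect_equal(td$ddH[td$variant == "L-N31R"], -18.3)
  expect_equal(td$ddG[td$variant == "L-N31R"], -1.0)
  expect_equal(td$ddG, td$ddH + td$mTddS)
  expect_equal(round(td$fold[td$variant == "L-N31R"], 1), 4.7)

  ad <- delta_table(published_activation(), "WT")
  expect_equal(ad$dG[ad$variant == "WT"], 10.6)
  expect_equal(ad$ddH[ad$variant == "L-T56E"], -10.7)

  # reference against itself: all deltas zero
  self <- delta_table(published_thermo()[1, ], "WT")
  expect_true(all(self[, c("ddH", "mTddS", "ddG")] == 0))
  expect_error(delta_table(published_thermo(), "NOPE"), "not present")
})

test_that("compensation summary matches the published panel behavior", {
  td <- delta_table(published_thermo(), "WT")
  comp <- compensation_summary(td, "WT")
  eff <- comp$efficiencies
  expect_true(all(eff$efficiency > 0 & eff$efficiency < 0.12))
  expect_equal(round(eff$efficiency[eff$variant == "L-N31R"], 2), 0.05)

  # perfectly compensating set: slope -1 and zero efficiency
  perf <- data.frame(variant = c("WT", "a", "b", "c"),
                     dH = c(0, -5, -10, -15), mTdS = c(0, 5, 10, 15))
  pd <- delta_table(perf, "WT")
  pc <- compensation_summary(pd, "WT")
  expect_equal(pc$slope, -1, tolerance = 1e-12)
  expect_true(all(pc$efficiencies$efficiency == 0))

  expect_error(compensation_summary(pd[1:2, ], "WT"), ">= 2")
  degen <- delta_table(data.frame(variant = c("WT", "a", "b"),
                                  dH = c(0, -5, -5), mTdS = c(0, 1, 2)), "WT")
  expect_error(compensation_summary(degen, "WT"), "degenerate")
})

test_that("sensorgram global fit round-trips the generator", {
  kon <- 1.4e5; koff <- 1.0e-4; rmax <- 120
  concs <- c(2, 5, 10, 20, 50) * 1e-9
  sg <- simulate_sensorgram(kon, koff, rmax, concs)
  fit <- fit_sensorgram(sg)
  expect_lt(abs(fit$kon - kon) / kon, 1e-3)
  expect_lt(abs(fit$koff - koff) / koff, 1e-3)
  expect_equal(fit$kd, fit$koff / fit$kon)

  # scale equivariance: doubling R_max doubles rmax, leaves rates alone
  sg2 <- sg; sg2$RU <- 2 * sg2$RU
  fit2 <- fit_sensorgram(sg2)
  expect_lt(abs(fit2$rmax - 2 * fit$rmax) / (2 * fit$rmax), 1e-6)
  expect_lt(abs(fit2$kon - fit$kon) / fit$kon, 1e-8)
  expect_lt(abs(fit2$koff - fit$koff) / fit$koff, 1e-8)

  zero <- sg; zero$RU <- 0
  expect_error(fit_sensorgram(zero), "all-zero")
  expect_error(fit_sensorgram(sg[sg$conc == concs[1], ]), ">= 2")
})

test_that("noisy sensorgram recovery stays within 10% (median over seeds)", {
  kon <- 1.4e5; koff <- 1.0e-4; rmax <- 120
  concs <- c(2, 5, 10, 20, 50) * 1e-9
  errs <- t(vapply(1:40, function(s) {
    sg <- simulate_sensorgram(kon, koff, rmax, concs, noise_sd = 0.02 * rmax,
                              seed = s)
    f <- fit_sensorgram(sg)
    c(abs(f$kon - kon) / kon, abs(f$koff - koff) / koff)
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.10)
  expect_lt(stats::median(errs[, 2]), 0.10)
})

test_that("run_characterize reproduces the published panel summary", {
  ch <- run_characterize(published_kinetics(), published_thermo(),
                         published_activation())
  kt <- ch$kinetics
  expect_equal(sum(kt$improved), 5)
  expect_equal(nrow(kt), 13)
  vl <- grepl("^L-", kt$variant)
  expect_equal(sum(kt$improved & vl), 5)
  expect_equal(sum(vl), 7)
  expect_identical(sort(kt$variant[kt$kd_inconsistent]), c("H-N28D", "WT"))
  expect_equal(round(kt$fold[kt$variant == "L-N31R"], 1), 4.7)
  expect_error(run_characterize(published_kinetics()[0, ]), "empty")

  out <- tempfile()
  write_characterization(ch, out)
  expect_true(all(file.exists(file.path(out, c("kinetics.tsv",
                                               "thermo_deltas.tsv",
                                               "compensation.tsv")))))
})
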