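# Saturation-screen orchestration: library enumeration, reference
# ensemble, contact filter, delta E, ranking, determinism.

test_that("library enumeration gives exactly 19 specs per position", {
  cs <- make_toy_complex(toy_complex_spec(n_res = 70))
  sel <- select_cdr(cs, ranges = data.frame(chain = "A", start = 5, end = 66))
  expect_equal(nrow(sel), 62)
  specs <- enumerate_library(cs, sel)
  expect_length(specs, 62 * 19)

  one <- enumerate_library(cs, sel[1, , drop = FALSE])
  expect_length(one, 19)
  wt <- cs$atoms$resid[abmature:::residue_index(cs, sel$chain[1], sel$resno[1])][1]
  expect_false(wt %in% vapply(one, function(s) s$target, ""))

  dup <- rbind(sel[1, ], sel[1, ])
  expect_error(enumerate_library(cs, dup), "duplicate")
})

test_that("no-contact filter drops exactly the contactless models", {
  cs <- parameterize(make_toy_complex())
  ens <- build_ensemble(cs, mutation_spec("A", 6, "LYS"), n_models = 12,
                        seed = 4, keep_models = TRUE)
  f <- filter_no_contact(ens, 4.5)
  # oracle recount from the stored model structures
  recount <- sum(vapply(f$structures, function(s)
    abmature:::min_cross_distance(s) <= 4.5, logical(1)))
  expect_equal(sum(f$models$ok), recount)
  expect_equal(f$n_filtered, 12 - recount)

  # a model pushed 100 A away is always dropped
  ens2 <- ens
  ens2$models$min_cross_dist[1] <- 100
  f2 <- filter_no_contact(ens2, 4.5)
  expect_false(f2$models$ok[1])
  # a 4.0 A contact survives a 4.5 A cutoff
  ens2$models$min_cross_dist[2] <- 4.0
  expect_true(filter_no_contact(ens2, 4.5)$models$ok[2])
})

test_that("delta energy and ranking follow the selection rule", {
  expect_identical(delta_energy(c(1, 2, 3), 2), 0)
  expect_error(delta_energy(numeric(0), 0), "no valid")

  res <- data.frame(
    id = c("m1", "m2", "m3", "m4"), chain = "A", resno = c(1, 1, 2, 2),
    wt = "SER", target = c("ARG", "ASP", "GLU", "LYS"),
    n_models = 20, n_valid = c(20, 20, 5, 20), n_filtered = 0,
    median = 0, delta_e = c(-2, 0.5, -2, -2), stringsAsFactors = FALSE)
  cfg <- screen_config(n_models_per_mutation = 20, n_wt_models = 10)
  ranked <- rank_and_select(res, cfg)
  # m3 fails the valid-fraction rule despite a good delta E
  expect_identical(ranked$selected[ranked$id == "m3"], FALSE)
  expect_identical(sort(ranked$id[ranked$selected]), c("m1", "m4"))
  # equal delta E: deterministic (chain, position, target) tie-break
  tied <- ranked[ranked$delta_e == -2, ]
  expect_identical(tied$id, c("m1", "m3", "m4"))

  res$delta_e <- abs(res$delta_e)  # all unfavorable -> empty selection
  expect_false(any(rank_and_select(res, cfg)$selected))
})

test_that("wild-type reference is seeded and subsample-consistent", {
  b <- plant_mutation_benchmark(seed = 1)
  cfg1 <- screen_config(n_models_per_mutation = 5, n_wt_models = 20, seed = 3)
  w1 <- wt_reference(b$complex, cfg1)
  w2 <- wt_reference(b$complex, cfg1)
  expect_identical(w1$median, w2$median)
  expect_equal(sum(w1$histogram$counts), length(w1$energies))

  cfg2 <- screen_config(n_models_per_mutation = 5, n_wt_models = 80, seed = 3)
  w3 <- wt_reference(b$complex, cfg2)
  se <- bootstrap_se_median(w1$energies)
  expect_lt(abs(w1$median - w3$median), 3 * max(se, 1e-3))
})

test_that("a rigid (chi-less) interface yields a zero-width reference", {
  spec <- toy_complex_spec(n_res = 7, separation = 9.5, site = 4,
                           site_res = "ALA", facing_res = "ALA",
                           seq_a = rep("ALA", 7), seq_b = rep("ALA", 7))
  cs <- parameterize(make_toy_complex(spec))
  cfg <- screen_config(n_models_per_mutation = 5, n_wt_models = 12,
                       contact_cutoff = 8)
  w <- wt_reference(cs, cfg)
  expect_equal(stats::sd(w$energies), 0)
  expect_equal(w$median, interaction_energy(cs)$e_total)
})

test_that("wild-type identity control distributes around zero", {
  b <- plant_mutation_benchmark(seed = 1)
  cfg <- screen_config(n_models_per_mutation = 20, n_wt_models = 40, seed = 7)
  wt <- wt_reference(b$complex, cfg)
  ens <- build_ensemble(b$complex,
                        mutation_spec(b$site$chain, b$site$resno, b$site$wt),
                        n_models = 20, seed = 99)
  de <- delta_energy(ens$models$e_total[ens$models$ok], wt$median)
  se <- sqrt(bootstrap_se_median(ens$models$e_total[ens$models$ok])^2 +
               bootstrap_se_median(wt$energies)^2)
  expect_lt(abs(de), 2 * max(se, 0.02))
})

test_that("planted benchmark: oracle signs and pipeline agreement", {
  b <- plant_mutation_benchmark(seed = 1)
  expect_true(all(c("ARG", "LYS") %in% b$favorable))
  expect_true(all(c("ASP", "GLU") %in% b$unfavorable))
  expect_equal(b$oracle$delta_e[b$oracle$aa == b$site$wt], numeric(0))

  cfg <- screen_config(n_models_per_mutation = 10, n_wt_models = 20, seed = 5)
  sc <- run_screen(b$complex, data.frame(chain = "A", resno = b$site$resno), cfg)
  rep <- sc$report
  expect_equal(nrow(rep), 19)
  # complementary charge ranks first with negative delta E
  expect_identical(rep$target[1], "ARG")
  expect_lt(rep$delta_e[rep$target == "ARG"], 0)
  expect_lt(rep$delta_e[rep$target == "LYS"], 0)
  # like charges are unfavorable
  expect_gt(rep$delta_e[rep$target == "GLU"], 0)
  expect_gt(rep$delta_e[rep$target == "ASP"], 0)
})

test_that("full screens are deterministic under the master seed", {
  b <- plant_mutation_benchmark(seed = 1)
  cfg <- screen_config(n_models_per_mutation = 6, n_wt_models = 10, seed = 31)
  s1 <- run_screen(b$complex, data.frame(chain = "A", resno = 6), cfg)
  s2 <- run_screen(b$complex, data.frame(chain = "A", resno = 6), cfg)
  expect_identical(s1$report, s2$report)
  d1 <- tempfile(); d2 <- tempfile()
  write_screen_report(s1, d1); write_screen_report(s2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "report.tsv"))),
                   unname(tools::md5sum(file.path(d2, "report.tsv"))))
})
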