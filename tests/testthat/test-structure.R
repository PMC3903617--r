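# Structure container, PDB I/O, CDR selection, interface geometry, SASA.

test_that("PDB round-trip preserves coordinates, numbering and insertion codes", {
  cs <- make_toy_complex()
  f <- tempfile(fileext = ".pdb")
  write_pdb(cs, f)
  cs2 <- read_pdb(f, c(A = "A", B = "B"))
  expect_equal(nrow(cs2$atoms), nrow(cs$atoms))
  expect_lte(max(abs(cs2$xyz - cs$xyz)), 1e-3)
  expect_identical(cs2$atoms$resno, cs$atoms$resno)
  expect_identical(cs2$atoms$elety, cs$atoms$elety)

  # insertion codes survive verbatim
  cs3 <- cs
  cs3$atoms$insert[cs3$atoms$resno == 4 & cs3$atoms$chain == "A"] <- "A"
  f3 <- tempfile(fileext = ".pdb")
  write_pdb(cs3, f3)
  cs4 <- read_pdb(f3, c(A = "A", B = "B"))
  expect_identical(cs4$atoms$insert, cs3$atoms$insert)

  empty <- cs
  empty$atoms <- cs$atoms[0, ]
  empty$xyz <- cs$xyz[0, , drop = FALSE]
  expect_error(write_pdb(empty, tempfile()), "empty")
})

test_that("read_pdb enforces the chain partition and filters waters/HETATM", {
  cs <- make_toy_complex()
  f <- tempfile(fileext = ".pdb")
  write_pdb(cs, f)
  expect_error(read_pdb(f, c(A = "A")), "partition")
  expect_error(read_pdb(tempfile(), c(A = "A", B = "B")), "not found")

  # append a waters-only chain and a HETATM record by hand
  lines <- readLines(f)
  endi <- grep("^END", lines)[1]
  wat <- c(
    sprintf("ATOM  %5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            9001L, 1L, 50.0, 50.0, 50.0),
    sprintf("HETATM%5d ZN    ZN H%4d    %8.3f%8.3f%8.3f  1.00  0.00          ZN",
            9002L, 1L, 60.0, 60.0, 60.0))
  writeLines(append(lines, wat, after = endi - 1), f)
  cs2 <- read_pdb(f, c(A = "A", B = "B", W = "B", H = "B"))
  # neither the water chain nor the metal survives the standard filter
  expect_false(any(cs2$atoms$chain %in% c("W", "H")))
  expect_equal(nrow(cs2$atoms), nrow(cs$atoms))
})

test_that("select_cdr handles inclusive ranges and explicit lists with checks", {
  cs <- make_toy_complex(toy_complex_spec(n_res = 41))
  sel <- select_cdr(cs, ranges = data.frame(chain = "A", start = 24, end = 34))
  expect_equal(nrow(sel), 11)  # inclusive on both ends
  sel2 <- select_cdr(cs, residues = data.frame(chain = "A", resno = c(3, 7)))
  expect_equal(nrow(sel2), 2)
  expect_error(select_cdr(cs, residues = data.frame(chain = "A", resno = 99)),
               "not present")
  expect_error(select_cdr(cs, ranges = data.frame(chain = "B", start = 1, end = 5)),
               "not partner A")
  expect_error(select_cdr(cs), "exactly one")
})

test_that("interface contacts respect the cutoff boundary exactly", {
  at <- data.frame(chain = c("A", "B"), resno = 1L, insert = "",
                   resid = "ALA", elety = "CB", element = "C",
                   stringsAsFactors = FALSE)
  mk <- function(d) {
    s <- new_cstruct(at, rbind(c(0, 0, 0), c(d, 0, 0)), c(A = "A", B = "B"))
    s
  }
  expect_equal(nrow(interface_residues(mk(4.4), 4.5)$pairs), 1)
  expect_equal(nrow(interface_residues(mk(4.6), 4.5)$pairs), 0)
  expect_error(interface_residues(mk(4.4), -1))
})

test_that("interface pair list equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    s <- random_complex(n_res_per_chain = 4, seed = seed, spread = 7)
    got <- interface_residues(s, 4.5)$pairs
    got_keys <- sort(paste(got$chain_a, got$resno_a, got$chain_b, got$resno_b))
    expect_identical(got_keys, brute_force_contacts(s, 4.5), info = paste("seed", seed))
  }
})

test_that("buried surface area: separation, analytic caps, convergence, rigidity", {
  csp <- parameterize(make_toy_complex())
  bsa <- buried_surface_area(csp)
  expect_gt(bsa, 0)

  far <- csp
  far$xyz[far$atoms$partner == "B", 1] <- far$xyz[far$atoms$partner == "B", 1] + 100
  expect_lt(abs(buried_surface_area(far)), 1)

  # identical overlapping spheres, probe 0: BSA = 2 x spherical cap area
  r <- 1.7; d <- 1.5
  dim2 <- lj_dimer()
  dim2$xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  dim2$atoms$radius <- r
  cap2 <- 2 * (2 * pi * r * (r - d / 2))
  expect_lt(abs(buried_surface_area(dim2, probe = 0, n_points = 4096) - cap2) / cap2,
            0.02)

  # sampling convergence: doubling the point count moves BSA by < 1%
  b1 <- buried_surface_area(csp, n_points = 960)
  b2 <- buried_surface_area(csp, n_points = 1920)
  expect_lt(abs(b1 - b2) / b1, 0.01)

  # rigid-body invariance within sampling tolerance
  rot <- abmature:::rotation_matrix(c(1, 2, 3), 37)
  b3 <- buried_surface_area(transform_structure(csp, rot, c(5, -3, 2)),
                            n_points = 2048)
  b4 <- buried_surface_area(csp, n_points = 2048)
  expect_lt(abs(b3 - b4) / b4, 0.01)

  bad <- csp
  bad$atoms$radius <- NA_real_
  expect_error(buried_surface_area(bad), "radii")
})
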