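test_that("PDB round-trip preserves residues, chain selection works", {
  s <- build_backbone(c("A", "A", "A"), phi = rep(-57, 3), psi = rep(-47, 3),
                      id = "tri")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  parsed <- read_structure(path, chain = "A", id = "tri")
  expect_equal(n_residues(parsed), 3)
  expect_equal(parsed$residues$aa, c("A", "A", "A"))
  expect_error(read_structure(path, chain = "B"), "chain 'B' not found")
})

test_that("two-chain file yields only the requested chain", {
  s1 <- build_backbone(rep("L", 4), rep(-57, 4), rep(-47, 4), chain = "A")
  s2 <- build_backbone(rep("V", 6), rep(-139, 6), rep(135, 6), chain = "B")
  path <- withr::local_tempfile(fileext = ".pdb")
  # concatenate the two chains into one file
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s1, p1)
  write_structure_pdb(s2, p2)
  l1 <- grep("^ATOM", readLines(p1), value = TRUE)
  l2 <- grep("^ATOM", readLines(p2), value = TRUE)
  writeLines(c(l1, l2, "END"), path)
  b <- suppressWarnings(read_structure(path, chain = "B"))
  expect_equal(n_residues(b), 6)
  expect_true(all(b$residues$aa == "V"))
})

test_that("a residue missing its C atom is kept but torsion-undefined", {
  s <- build_backbone(rep("A", 5), rep(-57, 5), rep(-47, 5))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  lines <- readLines(path)
  # drop the C atom of residue 3
  drop <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " C  " &
    substr(lines, 23, 26) == "   3"
  expect_equal(sum(drop), 1)
  writeLines(lines[!drop], path)
  parsed <- read_structure(path, chain = "A")
  expect_equal(n_residues(parsed), 5)
  expect_false(parsed$residues$has_backbone[3])
  d <- residue_descriptors(parsed)
  expect_equal(d$torsion_domain[3], "undefined")
})

test_that("torsion domains follow the configured partition", {
  # ideal helix interior
  helix <- build_backbone(rep("A", 5), rep(-60, 5), rep(-45, 5))
  d <- residue_descriptors(helix)
  expect_equal(d$torsion_domain, c("undefined", rep("helical", 3), "undefined"))
  # ideal extended strand interior
  strand <- build_backbone(rep("V", 5), rep(-139, 5), rep(135, 5))
  expect_equal(residue_descriptors(strand)$torsion_domain[3], "extended")
  # direct assignment checks including the catch-all
  expect_equal(meltshift:::assign_torsion_domain(-60, -45), "helical")
  expect_equal(meltshift:::assign_torsion_domain(-75, 145), "ppii")
  expect_equal(meltshift:::assign_torsion_domain(60, 45), "helical_L")
  expect_equal(meltshift:::assign_torsion_domain(170, 0), "other")
  expect_equal(meltshift:::assign_torsion_domain(NA, 10), "undefined")
})

test_that("own dihedrals match bio3d on a jittered chain", {
  set.seed(4)
  n <- 8
  s <- build_backbone(sample(aa_codes(), n, replace = TRUE),
                      phi = -100 + rnorm(n, 0, 40),
                      psi = 120 + rnorm(n, 0, 40))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  # recompute with the package's own dihedral code
  phi <- psi <- rep(NA_real_, n)
  for (k in 2:(n - 1)) {
    phi[k] <- meltshift:::dihedral_angle(
      meltshift:::bb_atom(s, k - 2L, "C"), meltshift:::bb_atom(s, k - 1L, "N"),
      meltshift:::bb_atom(s, k - 1L, "CA"), meltshift:::bb_atom(s, k - 1L, "C"))
    psi[k] <- meltshift:::dihedral_angle(
      meltshift:::bb_atom(s, k - 1L, "N"), meltshift:::bb_atom(s, k - 1L, "CA"),
      meltshift:::bb_atom(s, k - 1L, "C"), meltshift:::bb_atom(s, k, "N"))
  }
  expect_equal(phi[2:(n - 1)], unname(tor$tbl[2:(n - 1), "phi"]),
               tolerance = 1e-3)
  expect_equal(psi[2:(n - 1)], unname(tor$tbl[2:(n - 1), "psi"]),
               tolerance = 1e-3)
})

test_that("relative accessibility is 100% on its own reference conformation", {
  cfg <- ms_config(max_asa = "computed")
  for (aa in c("G", "L", "W")) {
    s <- build_backbone(c("G", aa, "G"), rep(-139, 3), rep(135, 3))
    d <- residue_descriptors(s, cfg)
    expect_equal(d$rsa[2], 100, tolerance = 0.02)
  }
  # with the published reference table the extended Gly is mostly exposed
  d_tien <- residue_descriptors(
    build_backbone(rep("G", 3), rep(-139, 3), rep(135, 3)), ms_config())
  expect_gt(d_tien$rsa[2], 50)
})

test_that("a fully buried-ish interior residue is less accessible than termini", {
  s <- fixture_structure()
  d <- residue_descriptors(s, fixture_config())
  expect_true(all(d$rsa >= 0 & d$rsa <= 100))
  expect_gt(mean(d$rsa[c(1, nrow(d))]), min(d$rsa))
})

test_that("distance binning is a half-open partition of [d_min, d_max)", {
  cfg <- ms_config()
  expect_equal(meltshift:::distance_bin(5.0, cfg), 10L)
  expect_equal(meltshift:::distance_bin(3.0, cfg), 0L)
  expect_equal(meltshift:::distance_bin(7.999, cfg), 24L)
  expect_true(is.na(meltshift:::distance_bin(8.0, cfg)))
  expect_true(is.na(meltshift:::distance_bin(2.99, cfg)))
  # every in-range distance maps to exactly one bin
  d <- seq(3, 8 - 1e-9, by = 0.01)
  bins <- meltshift:::distance_bin(d, cfg)
  expect_true(all(bins >= 0 & bins < cfg$n_d_bins))
  expect_equal(bins, pmin(floor((d - 3) / 0.2), cfg$n_d_bins - 1))
})

test_that("residue pairs respect separation and range filters", {
  s <- fixture_structure()
  cfg <- ms_config()
  pr <- residue_pairs(s, cfg)
  expect_true(all(pr$j - pr$i >= cfg$min_separation))
  expect_true(all(pr$distance >= cfg$d_min & pr$distance < cfg$d_max))
  # raising the separation cut removes adjacent pairs
  cfg2 <- ms_config(min_separation = 2)
  pr2 <- residue_pairs(s, cfg2)
  expect_true(all(pr2$j - pr2$i >= 2))
  expect_true(nrow(pr2) < nrow(pr))
})

test_that("descriptors are deterministic", {
  s <- fixture_structure()
  cfg <- fixture_config()
  d1 <- residue_descriptors(s, cfg)
  d2 <- residue_descriptors(s, cfg)
  expect_identical(d1, d2)
})
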