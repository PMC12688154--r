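# PDB parsing, mutant building, spatial shells, solvent accessibility,
# secondary structure and GNM fluctuations.

test_that("PDB parsing applies the altloc/HETATM/model rules", {
  s <- read_pdb(make_helix_structure("AKDLV"))
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(structure_residues(s)), 5L)
  expect_equal(structure_residues(s)$aa1, c("A", "K", "D", "L", "V"))

  # altloc: highest occupancy wins; ties go to 'A'
  altloc_txt <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.400   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  sa <- read_pdb(altloc_txt)
  ca <- sa$atoms[sa$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.4)

  het_only <- paste(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), collapse = "\n")
  expect_error(read_pdb(het_only), "no ATOM records")
  expect_error(read_pdb("REMARK nothing\nEND"), "no ATOM records")

  bad_coord <- paste(c(
    "ATOM      1  N   ALA A   1       xx.xxx   0.000   0.000  1.00  0.00           N",
    "END"), collapse = "\n")
  expect_error(read_pdb(bad_coord), "line 1")
})

test_that("baseline mutant truncates the side chain and preserves the rest", {
  s <- read_pdb(make_helix_structure("ALKVG"))
  m <- build_mutant_baseline(s, "A", 3, "K", "Q")
  expect_false(m$sidechain_complete)
  site <- m$atoms[m$atoms$res_key == "A:3", ]
  expect_setequal(site$atom, c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(site$resname), "GLN")
  # mutation to glycine drops the C-beta
  g <- build_mutant_baseline(s, "A", 3, "K", "G")
  expect_setequal(g$atoms$atom[g$atoms$res_key == "A:3"],
                  c("N", "CA", "C", "O"))
  # all other residues bit-exact
  expect_identical(m$atoms[m$atoms$res_key != "A:3", ],
                   s$atoms[s$atoms$res_key != "A:3", ])
  expect_error(build_mutant_baseline(s, "A", 3, "M", "Q"), "mismatch")
  expect_error(build_mutant_baseline(s, "A", 99, "K", "Q"), "not found")
})

test_that("shell membership matches a brute-force distance oracle", {
  # site at origin, residue B nearest atom at 5 A, residue C at 12 A
  atoms <- rbind(
    atom_row("CA", "GLY", 1, 0, 0, 0),
    atom_row("CA", "GLY", 2, 5, 0, 0),
    atom_row("CB", "ALA", 2, 6, 0, 0),
    atom_row("CA", "GLY", 3, 12, 0, 0)
  )
  s <- read_pdb(pdb_fixture(atoms))
  # brute force: residue is in shell iff min pairwise atom distance <= r
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  brute <- function(r) {
    site_at <- which(s$atoms$res_key == "A:1")
    keep <- vapply(unique(s$atoms$res_key), function(k) {
      idx <- which(s$atoms$res_key == k)
      dmin <- min(sqrt(outer(rowSums(xyz[site_at, , drop = FALSE]^2),
                             rowSums(xyz[idx, , drop = FALSE]^2), `+`) -
                         2 * xyz[site_at, , drop = FALSE] %*%
                         t(xyz[idx, , drop = FALSE])))
      dmin <= r
    }, TRUE)
    names(keep)[keep]
  }
  expect_setequal(residues_within_radius(s, "A:1", 7), brute(7))
  expect_equal(residues_within_radius(s, "A:1", 7), c("A:1", "A:2"))
  expect_equal(residues_within_radius(s, "A:1", 13), c("A:1", "A:2", "A:3"))
  expect_equal(residues_within_radius(s, "A:1", Inf),
               unique(s$atoms$res_key))
  expect_error(residues_within_radius(s, "B:1", 7), "not found")
})

test_that("shells nest and contain the site on random structures", {
  for (seed in 1:5) {
    seq_aa <- withr::with_seed(seed, paste(
      sample(aa_alphabet(), 15, replace = TRUE), collapse = ""))
    s <- read_pdb(make_helix_structure(seq_aa))
    site <- paste0("A:", withr::with_seed(seed + 100, sample(15, 1)))
    sh <- lapply(c(7, 10, 13), function(r) residues_within_radius(s, site, r))
    expect_true(site %in% sh[[1]])
    expect_true(all(sh[[1]] %in% sh[[2]]))
    expect_true(all(sh[[2]] %in% sh[[3]]))
  }
})

test_that("solvent accessibility matches analytic sphere areas", {
  lone <- read_pdb(pdb_fixture(atom_row("CA", "GLY", 1, 0, 0, 0)))
  got <- shrake_rupley_sasa(lone)$sasa
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # quadrature converges: doubling the point count moves the area < 1%
  hi <- shrake_rupley_sasa(lone, n_points = 1920)$sasa
  expect_lt(abs(hi - got) / got, 0.01)

  # two atoms far apart: no occlusion, areas add
  pair <- read_pdb(pdb_fixture(rbind(
    atom_row("CA", "GLY", 1, 0, 0, 0),
    atom_row("CA", "GLY", 2, 100, 0, 0))))
  expect_equal(sum(shrake_rupley_sasa(pair)$sasa), 2 * got, tolerance = 1e-6)

  # an atom caged by 12 icosahedral neighbours at 2 A is fully occluded
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    expand.grid(x = 0, y = c(-1, 1), z = c(-phi, phi)),
    expand.grid(x = c(-1, 1), y = c(-phi, phi), z = 0),
    expand.grid(x = c(-phi, phi), y = 0, z = c(-1, 1))
  )
  ico <- 2 * as.matrix(ico) / sqrt(1 + phi^2)
  cage <- rbind(
    atom_row("CA", "GLY", 1, 0, 0, 0),
    do.call(rbind, lapply(seq_len(12), function(i) {
      atom_row("CA", "GLY", i + 1, ico[i, 1], ico[i, 2], ico[i, 3])
    }))
  )
  caged <- shrake_rupley_sasa(read_pdb(pdb_fixture(cage)))
  expect_equal(caged$sasa[caged$res_key == "A:1"], 0)
})

test_that("relative accessibility applies the burial threshold", {
  r0 <- relative_accessibility(0, "A")
  expect_equal(r0$rsa, 0)
  expect_equal(r0$burial, "buried")
  rmax <- relative_accessibility(unname(max_asa_table()["L"]), "L")
  expect_equal(rmax$rsa, 1)
  expect_equal(rmax$burial, "exposed")
  expect_equal(relative_accessibility(0.249 * 129, "A")$burial, "buried")
  expect_equal(relative_accessibility(0.251 * 129, "A")$burial, "exposed")
  # clipped at 1.2
  expect_equal(relative_accessibility(1e4, "G")$rsa, 1.2)
  expect_error(relative_accessibility(10, "X"), "unknown residue")
})

test_that("dihedral classifier labels ideal helices and strands", {
  helix <- read_pdb(make_helix_structure("AAAAAAAAAA"))
  ss <- assign_secondary_structure(helix)
  expect_equal(as.character(ss$ss[2:9]), rep("alpha_helix", 8))
  # chain termini have undefined dihedrals
  expect_equal(as.character(ss$ss[c(1, 10)]), c("loop", "loop"))
  strand <- read_pdb(make_helix_structure("AAAAAAAA", phi = -120, psi = 130))
  ss_b <- assign_secondary_structure(strand)
  expect_equal(as.character(ss_b$ss[2:7]), rep("beta_strand", 6))
})

test_that("GNM fluctuations match the two-node pseudo-inverse and are rigid-motion invariant", {
  two <- read_pdb(pdb_fixture(rbind(
    atom_row("CA", "GLY", 1, 0, 0, 0),
    atom_row("CA", "GLY", 2, 3, 0, 0))))
  g <- gnm_fluctuations(two)
  # Kirchhoff [[1,-1],[-1,1]] has pseudo-inverse diagonal (0.25, 0.25)
  expect_equal(g$msf_raw, c(0.25, 0.25))
  expect_equal(g$msf, c(1, 1))  # unit-mean normalization

  s <- read_pdb(make_helix_structure("ADKLVNERTY"))
  g1 <- gnm_fluctuations(s)
  expect_true(all(g1$msf_raw >= 0))
  expect_equal(mean(g1$msf), 1)
  # rigid translation leaves the output unchanged
  s2 <- s
  s2$atoms$x <- s2$atoms$x + 50
  s2$atoms$y <- s2$atoms$y - 12
  expect_equal(gnm_fluctuations(s2)$msf, g1$msf)
  # rotation about z
  th <- 0.7
  s3 <- s
  s3$atoms$x <- cos(th) * s$atoms$x - sin(th) * s$atoms$y
  s3$atoms$y <- sin(th) * s$atoms$x + cos(th) * s$atoms$y
  expect_equal(gnm_fluctuations(s3)$msf, g1$msf, tolerance = 1e-9)
  # disconnected contact graph warns
  far <- read_pdb(pdb_fixture(rbind(
    atom_row("CA", "GLY", 1, 0, 0, 0),
    atom_row("CA", "GLY", 2, 3, 0, 0),
    atom_row("CA", "GLY", 3, 100, 0, 0),
    atom_row("CA", "GLY", 4, 103, 0, 0))))
  expect_warning(gnm_fluctuations(far), "disconnected")
})
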