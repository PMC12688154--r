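# Structural descriptors: category proportions, interaction detection,
# pharmacophore counts, hydrophobic clusters and disorder.

test_that("category proportions follow the shipped membership table", {
  p <- aa_category_proportions(c("K", "D", "G", "F"))
  expect_equal(unname(p["prop_cat_positively_charged"]), 0.25)
  expect_equal(unname(p["prop_cat_negatively_charged"]), 0.25)
  expect_equal(unname(p["prop_cat_uncharged_polar"]), 0)
  expect_equal(unname(p["prop_cat_nonpolar"]), 0.5)
  expect_equal(unname(p["prop_cat_aromatic"]), 0.25)

  ala <- aa_category_proportions(rep("A", 4))
  expect_equal(unname(ala["prop_cat_nonpolar"]), 1)
  expect_equal(unname(ala["prop_cat_aliphatic"]), 1)
  expect_equal(unname(ala["prop_aa_A"]), 1)

  expect_true(all(aa_category_proportions(character()) == 0))
})

test_that("per-amino-acid proportions sum to 1 and charge categories partition", {
  for (seed in 1:10) {
    set_aa <- withr::with_seed(seed, sample(aa_alphabet(), 30, replace = TRUE))
    p <- aa_category_proportions(set_aa)
    expect_equal(sum(p[paste0("prop_aa_", aa_alphabet())]), 1)
    four <- c("prop_cat_uncharged_polar", "prop_cat_positively_charged",
              "prop_cat_negatively_charged", "prop_cat_nonpolar")
    expect_equal(sum(p[four]), 1)
  }
})

test_that("interaction criteria fire on constructed geometries", {
  # two CYS with SG-SG at 2.03 A (residues 1 and 3: non-adjacent)
  cys2 <- rbind(
    atom_row("CA", "CYS", 1, 0, 0, 0),
    atom_row("SG", "CYS", 1, 1.8, 0, 0, element = "S"),
    atom_row("CA", "GLY", 2, 0, 30, 0),
    atom_row("CA", "CYS", 3, 5.5, 0, 0),
    atom_row("SG", "CYS", 3, 3.83, 0, 0, element = "S")
  )
  e <- interaction_network(read_pdb(pdb_fixture(cys2)))
  ss_edge <- e[e$type == "disulfide", ]
  expect_equal(nrow(ss_edge), 1L)
  expect_equal(ss_edge$distance, 2.03, tolerance = 1e-6)

  # LYS NZ at 3.0 A from ASP OD1: ionic AND hydrogen bond
  salt <- rbind(
    atom_row("CA", "LYS", 1, 0, 0, 0),
    atom_row("NZ", "LYS", 1, 2, 0, 0, element = "N"),
    atom_row("CA", "ASP", 3, 7, 0, 0),
    atom_row("OD1", "ASP", 3, 5, 0, 0, element = "O")
  )
  es <- interaction_network(read_pdb(pdb_fixture(salt)))
  pair_types <- es$type[es$res_a == "A:1" & es$res_b == "A:3"]
  expect_true(all(c("ionic", "hydrogen_bond") %in% pair_types))

  # everything >= 50 A apart: no edges
  far <- rbind(backbone_res("GLY", 1, 0), backbone_res("GLY", 2, 60),
               backbone_res("GLY", 3, 120))
  expect_equal(nrow(interaction_network(read_pdb(pdb_fixture(far)))), 0L)
})

test_that("interaction counts are invariant under rigid motion", {
  s <- read_pdb(make_helix_structure("AKDLVNERTY"))
  e1 <- interaction_counts(interaction_network(s))
  s2 <- s
  th <- 1.1
  x <- s$atoms$x; y <- s$atoms$y
  s2$atoms$x <- cos(th) * x - sin(th) * y + 20
  s2$atoms$y <- sin(th) * x + cos(th) * y - 5
  e2 <- interaction_counts(interaction_network(s2))
  expect_equal(e1, e2)
})

test_that("pharmacophore typing counts ARG and GLY atoms as documented", {
  arg <- rbind(
    atom_row("N", "ARG", 1, 0, 1, 0), atom_row("CA", "ARG", 1, 1.2, 0, 0),
    atom_row("C", "ARG", 1, 2, 1, 0), atom_row("O", "ARG", 1, 3, 1.2, 0),
    atom_row("CB", "ARG", 1, 1.2, -1.5, 0),
    atom_row("NE", "ARG", 1, 1.2, -3, 0, element = "N"),
    atom_row("NH1", "ARG", 1, 0.2, -4, 0, element = "N"),
    atom_row("NH2", "ARG", 1, 2.2, -4, 0, element = "N")
  )
  p <- pharmacophore_counts(read_pdb(pdb_fixture(arg)))
  expect_equal(unname(p["n_pharm_positive"]), 3)
  expect_gte(unname(p["n_pharm_donor"]), 4)  # NE, NH1, NH2 + backbone N

  gly <- backbone_res("GLY", 1, 0)
  pg <- pharmacophore_counts(read_pdb(pdb_fixture(gly)))
  expect_equal(unname(pg["n_pharm_donor"]), 1)
  expect_equal(unname(pg["n_pharm_acceptor"]), 1)

  s <- read_pdb(pdb_fixture(gly))
  empty <- pharmacophore_counts(s, scope = character())
  expect_true(all(empty == 0))
})

test_that("hydrophobic clusters are connected components of size >= 2", {
  # three LEU with CB atoms mutually within 4.5 A
  tri <- rbind(
    atom_row("CA", "LEU", 1, 0, 0, 5), atom_row("CB", "LEU", 1, 0, 0, 0),
    atom_row("CA", "LEU", 2, 3, 0, 5), atom_row("CB", "LEU", 2, 3, 0, 0),
    atom_row("CA", "LEU", 3, 1.5, 2.5, 5), atom_row("CB", "LEU", 3, 1.5, 2.5, 0)
  )
  cl <- hydrophobic_clusters(read_pdb(pdb_fixture(tri)))
  expect_equal(unname(cl$summary["n_hyd_clusters"]), 1)
  expect_equal(unname(cl$summary["hyd_cluster_max_size"]), 3)

  # two contact groups 50 A apart: two clusters, disjoint membership
  two_groups <- rbind(tri, within(tri, {x <- x + 50; resno <- resno + 3}))
  cl2 <- hydrophobic_clusters(read_pdb(pdb_fixture(two_groups)))
  expect_equal(unname(cl2$summary["n_hyd_clusters"]), 2)
  expect_length(intersect(cl2$clusters[[1]], cl2$clusters[[2]]), 0L)

  # all-serine protein: no hydrophobic nodes
  ser <- rbind(backbone_res("SER", 1, 0), backbone_res("SER", 2, 4))
  expect_equal(unname(hydrophobic_clusters(
    read_pdb(pdb_fixture(ser)))$summary["n_hyd_clusters"]), 0)
})

test_that("disorder proportion is report-driven with an ordered baseline", {
  s <- read_pdb(make_helix_structure("ACDEFGHIKL"))
  base <- disorder_proportion(s)
  expect_equal(base$proportion, 0)
  expect_true(base$baseline)

  rep3 <- tibble::tibble(resno = 1:10, disordered = c(rep(TRUE, 3), rep(FALSE, 7)))
  got <- disorder_proportion(s, rep3)
  expect_equal(got$proportion, 0.3)
  expect_false(got$baseline)

  bad <- tibble::tibble(resno = c(1, 99), disordered = c(TRUE, TRUE))
  expect_error(disorder_proportion(s, bad), "absent from the structure")
})

test_that("descriptor counts are monotone as the scope grows", {
  s <- read_pdb(make_helix_structure("AKDLVNERTYWFMIHC"))
  site <- "A:8"
  shells <- lapply(c(7, 13, Inf), function(r) residues_within_radius(s, site, r))
  edges <- interaction_network(s)
  n_edges <- vapply(shells, function(m) {
    sum(edges$res_a %in% m & edges$res_b %in% m)
  }, 1)
  expect_true(all(diff(n_edges) >= 0))
  pharm <- vapply(shells, function(m) sum(pharmacophore_counts(s, scope = m)), 1)
  expect_true(all(diff(pharm) >= 0))
})
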