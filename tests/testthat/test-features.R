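# Feature engine: group composition, diffs, mutation-type encodings,
# evolutionary window, and table assembly.

helix_setup <- function(seq_aa = "AKDLVNERTYGG", seed = 13) {
  s <- read_pdb(make_helix_structure(seq_aa), id = "SYN1")
  fx <- make_profile_fixtures(seq_aa, seed = seed, n_aaindex = 2)
  list(
    struct = s,
    pssm = parse_pssm_ascii(fx$pssm_text),
    aaindex = parse_aaindex1(fx$aaindex1_text),
    matrix = parse_aaindex_matrix(fx$matrix_text)
  )
}

test_that("registry bookkeeping matches its own manifest and is deterministic", {
  reg <- feature_registry(aaindex_accessions = c("SYN001", "SYN002"),
                          matrix_accessions = "SYNMAT1", window = 5)
  man <- registry_manifest(reg)
  counts <- stats::setNames(man$n_features, man$group)
  expect_equal(unname(counts["total"]), nrow(reg))
  expect_equal(sum(counts[c("G1_wt_struct_env", "G2_diff", "G3_mutation_type",
                            "G4_evolutionary")]),
               unname(counts["total"]))
  expect_equal(unname(counts["G4_evolutionary"]), 26L)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_identical(reg, feature_registry(c("SYN001", "SYN002"), "SYNMAT1", 5))
  # group 1 carries no profile-derived columns
  g1 <- reg$name[reg$group == "G1_wt_struct_env"]
  expect_false(any(grepl("PSSM", g1)))
})

test_that("group 1 shell features equal their standalone primitives", {
  env <- helix_setup()
  g1 <- compute_group1(env$struct, "A:6", wt_aa = "N", ph = 7,
                       temperature_c = 25, aaindex = env$aaindex)
  members <- residues_within_radius(env$struct, "A:6", 13)
  res <- structure_residues(env$struct)
  manual <- aa_category_proportions(res$aa1[res$res_key %in% members])
  got <- g1$values[paste0("wt_sh13_", names(manual))]
  expect_equal(unname(got), unname(manual))
  expect_equal(unname(g1$values["cond_ph"]), 7)
  expect_equal(unname(g1$values["cond_temperature"]), 25)
  # FoldX features are masked without a report, present with one
  expect_true(is.na(g1$values["wt_foldx_cis_bond"]))
  fx_vec <- stats::setNames(seq_len(20) / 10, foldx_term_names())
  g1fx <- compute_group1(env$struct, "A:6", wt_aa = "N", ph = 7,
                         temperature_c = 25, foldx = fx_vec)
  expect_equal(unname(g1fx$values["wt_foldx_cis_bond"]),
               unname(fx_vec["cis_bond"]))
  # aaindex lookup of the wild-type residue
  expect_equal(unname(g1$values["wt_aaindex_SYN001"]),
               unname(env$aaindex[["SYN001"]]$values[["N"]]))
})

test_that("group 2 diffs subtract exactly and exclude the documented columns", {
  env <- helix_setup()
  wt <- compute_group1(env$struct, "A:4", wt_aa = "L", ph = 7,
                       temperature_c = 25, aaindex = env$aaindex)
  mut_struct <- build_mutant_baseline(env$struct, "A", 4, "L", "A")
  mut <- compute_group1(mut_struct, "A:4", wt_aa = "A", ph = 7,
                        temperature_c = 25, aaindex = env$aaindex)
  d <- compute_group2_diff(wt, mut, aaindex = env$aaindex,
                           wt_aa = "L", mut_aa = "A")
  expect_false(any(grepl("disorder|buried|exposed", names(d))))
  expect_equal(unname(d["diff_sh7_prop_aa_A"]),
               unname(mut$values["wt_sh7_prop_aa_A"] -
                        wt$values["wt_sh7_prop_aa_A"]))
  # identical structures give all-zero internal diffs
  d0 <- compute_group2_diff(wt, wt, aaindex = env$aaindex,
                            wt_aa = "L", mut_aa = "L")
  internal <- d0[!grepl("foldx|aaindex|bfactor", names(d0))]
  expect_true(all(internal == 0))
  expect_equal(unname(d["diff_aaindex_SYN001"]),
               unname(env$aaindex[["SYN001"]]$values[["A"]] -
                        env$aaindex[["SYN001"]]$values[["L"]]))
})

test_that("mutation-type encodings flag the substitution and swap under reversal", {
  env <- helix_setup()
  int0 <- stats::setNames(rep(0, 6), paste0("n_int_", c(
    "hydrogen_bond", "disulfide", "ionic", "vdw", "pi_cation", "pi_pi")))
  g3 <- compute_group3_mutation_type("K", "Q", "alpha_helix", "alpha_helix",
                                     int0, int0,
                                     matrices = list(SYNMAT1 = env$matrix))
  expect_equal(unname(g3["mt_wt_is_K"]), 1)
  expect_equal(sum(g3[paste0("mt_wt_is_", aa_alphabet())]), 1)
  expect_equal(unname(g3["mt_mut_is_Q"]), 1)
  expect_equal(unname(g3["mt_wt_cat_positively_charged"]), 1)
  expect_equal(unname(g3["mt_wt_cat_uncharged_polar"]), 0)
  expect_equal(unname(g3["mt_mut_cat_uncharged_polar"]), 1)
  expect_equal(unname(g3["mt_ss_wt_alpha_helix"]), 1)
  # symmetric-completed matrix: M[wt][mut] == M[mut][wt]
  expect_equal(unname(g3["mt_submat_SYNMAT1"]),
               substitution_value(env$matrix, "Q", "K"))
  expect_true(is.na(g3["mt_sift_score"]))
  # reversal swaps the wt/mut one-hot blocks
  g3r <- compute_group3_mutation_type("Q", "K", "alpha_helix", "alpha_helix",
                                      int0, int0,
                                      matrices = list(SYNMAT1 = env$matrix))
  expect_equal(unname(g3r[paste0("mt_wt_is_", aa_alphabet())]),
               unname(g3[paste0("mt_mut_is_", aa_alphabet())]))
  expect_equal(unname(g3r[paste0("mt_mut_cat_", names(aa_categories()$aa))]),
               unname(g3[paste0("mt_wt_cat_", names(aa_categories()$aa))]),
               ignore_attr = TRUE)
})

test_that("evolutionary features implement the windowed profile arithmetic", {
  env <- helix_setup("KQREVNDSTY")
  pssm <- env$pssm
  g4 <- compute_group4_evolutionary(pssm, 6, wt_aa = "N", mut_aa = "A",
                                    window = 5)
  expect_length(g4, 26L)
  expect_equal(unname(g4["wt_PSSM_score_0"]), pssm$scores[6, "N"])
  expect_equal(unname(g4["mut_PSSM_score_0"]), pssm$scores[6, "A"])
  expect_equal(unname(g4["diff_PSSM_score"]),
               pssm$scores[6, "A"] - pssm$scores[6, "N"])
  # positions beyond the end are masked and dropped from the averages
  expect_true(is.na(g4["wt_PSSM_score_p5"]))  # position 11 > L = 10
  wt_window <- vapply(1:10, function(p) {
    pssm$scores[p, substr(pssm$sequence, p, p)]
  }, 1)
  wt_window[6] <- pssm$scores[6, "N"]
  expect_equal(unname(g4["wt_PSSM_score_aver"]), mean(wt_window))
  # antisymmetry of the site diff under reversal
  g4r <- compute_group4_evolutionary(pssm, 6, wt_aa = "A", mut_aa = "N",
                                     window = 5)
  expect_equal(unname(g4r["diff_PSSM_score"]), -unname(g4["diff_PSSM_score"]))
  expect_error(compute_group4_evolutionary(pssm, 40, "N", "A"), "outside")
})

test_that("table assembly is deterministic, antisymmetric and failure-tolerant", {
  env <- helix_setup()
  ds <- tibble::tibble(
    pdb_id = "SYN1", chain_id = c("A", "A", "B"), position = c(6, 4, 2),
    icode = "", wt_aa = c("N", "L", "K"), mut_aa = c("A", "A", "Q"),
    ph = 7, temperature_c = 25, ddg = c(1.2, -0.5, 0.3))
  aug <- augment_reverse(ds)
  ft <- suppressWarnings(assemble_feature_table(
    aug, list(SYN1 = env$struct), profiles = list(SYN1 = env$pssm),
    aaindex = env$aaindex, matrices = list(SYNMAT1 = env$matrix)))
  # the chain-B record fails atomically, its twin too; others proceed
  expect_equal(nrow(ft$failures), 2L)
  expect_equal(nrow(ft$table), 4L)
  expect_identical(names(ft$table)[-(1:4)], ft$registry$name)
  # rerun is identical
  ft2 <- suppressWarnings(assemble_feature_table(
    aug, list(SYN1 = env$struct), profiles = list(SYN1 = env$pssm),
    aaindex = env$aaindex, matrices = list(SYNMAT1 = env$matrix)))
  expect_identical(ft$table, ft2$table)
  # group 2 diffs of a direct/reverse pair negate exactly
  tb <- ft$table
  diff_cols <- grep("^diff_sh", names(tb), value = TRUE)
  p1 <- tb[tb$pair_id == tb$pair_id[1], ]
  expect_equal(as.numeric(p1[1, diff_cols]), -as.numeric(p1[2, diff_cols]))
  expect_equal(p1$ddg[1], -p1$ddg[2])
})
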