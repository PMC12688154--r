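# The feature engine: assembles the four feature groups into a
# stable-ordered feature table.
#
# Group 1: structural and environmental information of the wild-type
#   protein over four spatial regions (7/10/13 A shells and the whole
#   structure), site-level properties, energy terms and measuring
#   conditions. Group 2: mutant-minus-wild-type differences of the same
#   descriptors (minus a documented exclusion list). Group 3: mutation-type
#   encodings. Group 4: evolutionary (profile) scores around the site.
#
# Column order is fixed by the registry, never by input order; the
# registry manifest is the bookkeeping source of truth for group sizes.

.shell_radii <- c("7" = 7, "10" = 10, "13" = 13)
.shell_names <- c("7", "10", "13", "global")

# per-shell descriptor block (56 values, unprefixed)
.shell_block_names <- function() {
  c(paste0("prop_aa_", aa_alphabet()),
    paste0("prop_cat_", names(.aa_category_members)),
    paste0("ss_prop_", ss_classes()),
    "prop_buried", "prop_exposed",
    paste0("n_int_", .interaction_types),
    paste0("n_pharm_", .pharm_classes),
    "n_hyd_clusters", "hyd_cluster_max_size", "hyd_clustered_fraction",
    "prop_disordered")
}

# features dropped from the group-2 diff: structure proportions that do not
# change meaningfully under a single point mutation
.diff_exclusions <- function() {
  nm <- .shell_block_names()
  nm[grepl("^(prop_buried|prop_exposed|prop_disordered)$", nm)]
}

#' Default feature registry
#'
#' Enumerates every feature column the engine produces, in canonical
#' order, for a given configuration. The registry (not any printed total)
#' is the source of truth for per-group bookkeeping; tests assert the
#' engine's output matches the registry exactly.
#'
#' @param aaindex_accessions Character vector of AAindex1 property
#'   accessions registered for site-level lookups.
#' @param matrix_accessions Character vector of substitution-matrix
#'   accessions registered for group 3.
#' @param window Half-width of the evolutionary window (default 5, giving
#'   `2*(2*window+1) + 2 + 2` group-4 features).
#' @return A tibble with columns `name`, `group` (`G1_wt_struct_env`,
#'   `G2_diff`, `G3_mutation_type`, `G4_evolutionary`), `shell`, `source`.
#' @export
feature_registry <- function(aaindex_accessions = character(),
                             matrix_accessions = character(),
                             window = 5) {
  blk <- .shell_block_names()
  g1 <- dplyr::bind_rows(
    purrr::map(.shell_names, function(sh) {
      tibble::tibble(name = paste0("wt_sh", sh, "_", blk),
                     group = "G1_wt_struct_env", shell = sh, source = "internal")
    })
  )
  g1_site <- tibble::tibble(
    name = c("wt_site_rsa", "wt_site_fluctuation", "wt_site_bfactor",
             if (length(aaindex_accessions))
               paste0("wt_aaindex_", aaindex_accessions)),
    group = "G1_wt_struct_env", shell = "site",
    source = c("internal", "internal", "adapter",
               rep("internal", length(aaindex_accessions)))
  )
  g1_foldx <- tibble::tibble(name = paste0("wt_foldx_", .foldx_terms),
                             group = "G1_wt_struct_env", shell = "none",
                             source = "adapter")
  g1_cond <- tibble::tibble(name = c("cond_ph", "cond_temperature"),
                            group = "G1_wt_struct_env", shell = "none",
                            source = "condition")
  diff_blk <- setdiff(blk, .diff_exclusions())
  g2 <- dplyr::bind_rows(
    purrr::map(.shell_names, function(sh) {
      tibble::tibble(name = paste0("diff_sh", sh, "_", diff_blk),
                     group = "G2_diff", shell = sh, source = "internal")
    }),
    tibble::tibble(
      name = c("diff_site_rsa", "diff_site_fluctuation", "diff_site_bfactor",
               if (length(aaindex_accessions))
                 paste0("diff_aaindex_", aaindex_accessions)),
      group = "G2_diff", shell = "site",
      source = c("internal", "internal", "adapter",
                 rep("internal", length(aaindex_accessions)))
    ),
    tibble::tibble(name = paste0("diff_foldx_", .foldx_terms),
                   group = "G2_diff", shell = "none", source = "adapter")
  )
  g3 <- tibble::tibble(
    name = c(paste0("mt_wt_is_", aa_alphabet()),
             paste0("mt_mut_is_", aa_alphabet()),
             paste0("mt_wt_cat_", names(.aa_category_members)),
             paste0("mt_mut_cat_", names(.aa_category_members)),
             paste0("mt_ss_wt_", ss_classes()),
             paste0("mt_ss_mut_", ss_classes()),
             paste0("mt_int_delta_", .interaction_types),
             if (length(matrix_accessions))
               paste0("mt_submat_", matrix_accessions),
             "mt_sift_score", "mt_sift_deleterious"),
    group = "G3_mutation_type", shell = "site", source = "internal"
  )
  g3$source[g3$name %in% c("mt_sift_score", "mt_sift_deleterious")] <- "adapter"
  offs <- c(paste0("m", rev(seq_len(window))), "0", paste0("p", seq_len(window)))
  g4 <- tibble::tibble(
    name = c(paste0("wt_PSSM_score_", offs), paste0("mut_PSSM_score_", offs),
             "wt_PSSM_score_aver", "mut_PSSM_score_aver",
             "diff_PSSM_score", "diff_PSSM_score_aver"),
    group = "G4_evolutionary", shell = "site", source = "internal"
  )
  reg <- dplyr::bind_rows(g1, g1_site, g1_foldx, g1_cond, g2, g3, g4)
  stopifnot(!anyDuplicated(reg$name))
  reg
}

#' Registry manifest
#'
#' @param registry A registry tibble from [feature_registry()].
#' @return A tibble with per-group feature counts and the total.
#' @export
registry_manifest <- function(registry) {
  registry |>
    dplyr::count(.data$group, name = "n_features") |>
    dplyr::bind_rows(tibble::tibble(group = "total",
                                    n_features = nrow(registry)))
}

# full structural/environmental profile of one structure around one site.
# Returns list(values = named vector over shells+site, site_ss, site_int)
.structure_profile <- function(struct, site_key, disorder_report = NULL,
                               bfactor_report = NULL) {
  res <- structure_residues(struct)
  sasa <- shrake_rupley_sasa(struct)
  acc <- relative_accessibility(sasa$sasa, res$aa1[match(sasa$res_key, res$res_key)])
  per_res <- res |>
    dplyr::left_join(
      tibble::tibble(res_key = sasa$res_key, rsa = acc$rsa, burial = acc$burial),
      by = "res_key") |>
    dplyr::left_join(suppressWarnings(assign_secondary_structure(struct)),
                     by = "res_key")
  dis <- disorder_proportion(struct, disorder_report)
  per_res$disordered <- if (is.null(disorder_report)) FALSE else {
    flags <- dplyr::left_join(res, disorder_report, by = "resno")
    tidyr::replace_na(flags$disordered, FALSE)
  }
  edges <- interaction_network(struct)
  pharm_by_res <- lapply(stats::setNames(res$res_key, res$res_key),
                         function(k) pharmacophore_counts(struct, scope = k))
  shells <- lapply(.shell_radii, function(r) residues_within_radius(struct, site_key, r))
  shells$global <- res$res_key
  vals <- unlist(purrr::imap(shells[c(names(.shell_radii), "global")],
                             function(members, sh) {
    sub <- per_res[per_res$res_key %in% members, ]
    in_scope <- edges$res_a %in% members & edges$res_b %in% members
    cl <- hydrophobic_clusters(struct, scope = members)
    v <- c(
      aa_category_proportions(sub$aa1),
      stats::setNames(as.numeric(table(sub$ss) / nrow(sub)),
                      paste0("ss_prop_", ss_classes())),
      prop_buried = mean(sub$burial == "buried"),
      prop_exposed = mean(sub$burial == "exposed"),
      interaction_counts(edges[in_scope, ]),
      colSums(do.call(rbind, pharm_by_res[members])),
      cl$summary,
      prop_disordered = mean(sub$disordered)
    )
    stats::setNames(v, paste0("wt_sh", sh, "_", .shell_block_names()))
  }))
  names(vals) <- sub("^[0-9]+\\.|^global\\.", "", names(vals))
  gnm <- gnm_fluctuations(struct)
  site_b <- if (!is.null(bfactor_report)) {
    resno_site <- res$resno[res$res_key == site_key]
    hit <- bfactor_report$bfactor[bfactor_report$resno == resno_site]
    if (length(hit)) hit[1] else NA_real_
  } else {
    b <- struct$atoms$b_factor[struct$atoms$res_key == site_key]
    if (all(b == 0)) NA_real_ else mean(b)
  }
  site_vals <- c(
    wt_site_rsa = per_res$rsa[per_res$res_key == site_key],
    wt_site_fluctuation = gnm$msf[gnm$res_key == site_key],
    wt_site_bfactor = site_b
  )
  site_edges <- edges[edges$res_a == site_key | edges$res_b == site_key, ]
  list(
    values = c(vals, site_vals),
    site_ss = as.character(per_res$ss[per_res$res_key == site_key]),
    site_int = interaction_counts(site_edges),
    site_aa = per_res$aa1[per_res$res_key == site_key]
  )
}

#' Compute group 1: wild-type structural and environmental features
#'
#' @param struct Wild-type `protein_structure`.
#' @param site Residue address of the mutation site.
#' @param wt_aa Wild-type one-letter amino acid (for AAindex lookups).
#' @param ph,temperature_c Measuring conditions, passed through as plain
#'   numeric features.
#' @param aaindex Named list of AAindex1 entries registered for site
#'   lookups.
#' @param foldx Optional named FoldX energy vector for the wild-type
#'   structure (masked `NA` when absent).
#' @param disorder,bfactor Optional tool-report tibbles.
#' @return A list: `values` (named numeric vector in registry order for
#'   the group), plus `site_ss`/`site_int` context for group 3.
#' @export
compute_group1 <- function(struct, site, wt_aa, ph, temperature_c,
                           aaindex = list(), foldx = NULL,
                           disorder = NULL, bfactor = NULL) {
  site_key <- resolve_site(struct, site)
  prof <- .structure_profile(struct, site_key, disorder_report = disorder,
                             bfactor_report = bfactor)
  aa_vals <- if (length(aaindex)) {
    stats::setNames(
      vapply(aaindex, function(e) {
        v <- e$values[[toupper(wt_aa)]]
        if (is.null(v)) NA_real_ else v
      }, numeric(1)),
      paste0("wt_aaindex_", vapply(aaindex, `[[`, "", "accession"))
    )
  } else numeric()
  fx <- stats::setNames(rep(NA_real_, length(.foldx_terms)),
                        paste0("wt_foldx_", .foldx_terms))
  if (!is.null(foldx)) fx[paste0("wt_foldx_", names(foldx))] <- foldx
  prof$values <- c(prof$values, aa_vals, fx,
                   cond_ph = ph, cond_temperature = temperature_c)
  prof
}

#' Compute group 2: mutant-minus-wild-type differences
#'
#' Differences `mutant - wild-type` for every shared internally computed
#' feature except the documented exclusions (disorder proportion and
#' buried/exposed proportions, which do not change meaningfully under a
#' point mutation), plus site-level and FoldX energy differences.
#'
#' @param wt_profile,mut_profile Profiles from [compute_group1()] (the
#'   mutant profile is computed on the mutant structure at the same site).
#' @param wt_foldx,mut_foldx Optional named FoldX energy vectors.
#' @param aaindex Named list of AAindex1 entries (difference of the
#'   property values of mutant vs wild-type amino acid).
#' @param wt_aa,mut_aa One-letter amino acids of the substitution.
#' @return Named numeric vector of `diff_*` features.
#' @export
compute_group2_diff <- function(wt_profile, mut_profile,
                                wt_foldx = NULL, mut_foldx = NULL,
                                aaindex = list(), wt_aa, mut_aa) {
  excl <- .diff_exclusions()
  diff_blk <- setdiff(.shell_block_names(), excl)
  out <- numeric()
  for (sh in .shell_names) {
    wt_nm <- paste0("wt_sh", sh, "_", diff_blk)
    stopifnot(all(wt_nm %in% names(wt_profile$values)),
              all(wt_nm %in% names(mut_profile$values)))
    d <- mut_profile$values[wt_nm] - wt_profile$values[wt_nm]
    out <- c(out, stats::setNames(d, paste0("diff_sh", sh, "_", diff_blk)))
  }
  site_nm <- c("wt_site_rsa", "wt_site_fluctuation", "wt_site_bfactor")
  d_site <- mut_profile$values[site_nm] - wt_profile$values[site_nm]
  names(d_site) <- c("diff_site_rsa", "diff_site_fluctuation", "diff_site_bfactor")
  out <- c(out, d_site)
  if (length(aaindex)) {
    d_aa <- vapply(aaindex, function(e) {
      w <- e$values[[toupper(wt_aa)]]; m <- e$values[[toupper(mut_aa)]]
      if (is.null(w) || is.null(m)) NA_real_ else m - w
    }, numeric(1))
    out <- c(out, stats::setNames(
      d_aa, paste0("diff_aaindex_", vapply(aaindex, `[[`, "", "accession"))))
  }
  d_fx <- stats::setNames(rep(NA_real_, length(.foldx_terms)),
                          paste0("diff_foldx_", .foldx_terms))
  if (!is.null(wt_foldx) && !is.null(mut_foldx)) {
    d_fx[paste0("diff_foldx_", .foldx_terms)] <-
      mut_foldx[.foldx_terms] - wt_foldx[.foldx_terms]
  }
  c(out, d_fx)
}

#' Compute group 3: mutation-type encodings
#'
#' One-hot encodings of the wild-type and mutant amino acids, category
#' membership flags before/after, site secondary structure before/after,
#' per-type site interaction-count deltas, substitution-matrix lookups,
#' and SIFT score/flag when a report is supplied (masked otherwise).
#'
#' @param wt_aa,mut_aa One-letter amino acids.
#' @param wt_site_ss,mut_site_ss Site secondary-structure class names.
#' @param wt_site_int,mut_site_int Named site interaction counts
#'   (`n_int_*`, from the structure profiles).
#' @param matrices Named list of substitution matrices
#'   ([parse_aaindex_matrix()]).
#' @param sift Optional SIFT report tibble; looked up by substitution.
#' @param substitution Substitution string for the SIFT lookup.
#' @return Named numeric vector of `mt_*` features.
#' @export
compute_group3_mutation_type <- function(wt_aa, mut_aa, wt_site_ss, mut_site_ss,
                                         wt_site_int, mut_site_int,
                                         matrices = list(), sift = NULL,
                                         substitution = NULL) {
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  onehot <- function(x, levels, prefix) {
    stats::setNames(as.numeric(levels == x), paste0(prefix, levels))
  }
  cat_flags <- function(aa, prefix) {
    stats::setNames(
      vapply(.aa_category_members, function(m) as.numeric(aa %in% m), numeric(1)),
      paste0(prefix, names(.aa_category_members)))
  }
  int_delta <- stats::setNames(
    as.numeric(mut_site_int[paste0("n_int_", .interaction_types)] -
                 wt_site_int[paste0("n_int_", .interaction_types)]),
    paste0("mt_int_delta_", .interaction_types))
  sub_vals <- if (length(matrices)) {
    stats::setNames(
      vapply(matrices, function(sm) substitution_value(sm, wt_aa, mut_aa),
             numeric(1)),
      paste0("mt_submat_", vapply(matrices, `[[`, "", "accession")))
  } else numeric()
  sift_vals <- c(mt_sift_score = NA_real_, mt_sift_deleterious = NA_real_)
  if (!is.null(sift) && !is.null(substitution)) {
    hit <- sift[sift$substitution == substitution, ]
    if (nrow(hit)) {
      sift_vals <- c(mt_sift_score = hit$score[1],
                     mt_sift_deleterious =
                       as.numeric(hit$prediction[1] == "DELETERIOUS"))
    }
  }
  c(onehot(wt_aa, aa_alphabet(), "mt_wt_is_"),
    onehot(mut_aa, aa_alphabet(), "mt_mut_is_"),
    cat_flags(wt_aa, "mt_wt_cat_"),
    cat_flags(mut_aa, "mt_mut_cat_"),
    onehot(wt_site_ss, ss_classes(), "mt_ss_wt_"),
    onehot(mut_site_ss, ss_classes(), "mt_ss_mut_"),
    int_delta, sub_vals, sift_vals)
}

#' Compute group 4: evolutionary profile features
#'
#' Profile log-odds at the mutation site and the `window` surrounding
#' positions on each side, for the wild-type residue column and for the
#' mutant (the wild-type matrix with the mutant's column read at the
#' site, the standard practice when no mutant profile is re-computed; a
#' genuine mutant profile can be supplied via `mut_pssm`). Window
#' averages include the site; positions beyond the sequence ends are
#' masked `NA` and excluded from averages. The two headline features are
#' `diff_PSSM_score` (mutant minus wild-type score at the site) and
#' `diff_PSSM_score_aver` (difference of the window averages).
#'
#' @param pssm Profile from [parse_pssm_ascii()].
#' @param position 1-based site position in the profile.
#' @param wt_aa,mut_aa One-letter amino acids.
#' @param window Half-width of the surrounding window (default 5).
#' @param mut_pssm Optional genuine mutant profile.
#' @return Named numeric vector of `2*(2*window+1) + 4` features (26 for
#'   the default window).
#' @export
compute_group4_evolutionary <- function(pssm, position, wt_aa, mut_aa,
                                        window = 5, mut_pssm = NULL) {
  L <- nrow(pssm$scores)
  if (position < 1 || position > L) {
    stop("site position ", position, " outside profile length ", L, call. = FALSE)
  }
  offsets <- seq(-window, window)
  offs_nm <- c(paste0("m", rev(seq_len(window))), "0", paste0("p", seq_len(window)))
  wt_scores <- vapply(offsets, function(o) {
    p <- position + o
    if (p < 1 || p > L) return(NA_real_)
    aa <- substr(pssm$sequence, p, p)
    if (!aa %in% aa_alphabet()) return(NA_real_)
    pssm$scores[p, aa]
  }, numeric(1))
  mp <- mut_pssm %||% pssm
  mut_scores <- wt_scores
  mut_scores[offsets == 0] <- mp$scores[position, toupper(mut_aa)]
  if (!is.null(mut_pssm)) {
    mut_scores <- vapply(offsets, function(o) {
      p <- position + o
      if (p < 1 || p > L) return(NA_real_)
      aa <- if (o == 0) toupper(mut_aa) else substr(mp$sequence, p, p)
      if (!aa %in% aa_alphabet()) return(NA_real_)
      mp$scores[p, aa]
    }, numeric(1))
  }
  wt_site <- pssm$scores[position, toupper(wt_aa)]
  wt_scores[offsets == 0] <- wt_site
  c(stats::setNames(wt_scores, paste0("wt_PSSM_score_", offs_nm)),
    stats::setNames(mut_scores, paste0("mut_PSSM_score_", offs_nm)),
    wt_PSSM_score_aver = mean(wt_scores, na.rm = TRUE),
    mut_PSSM_score_aver = mean(mut_scores, na.rm = TRUE),
    diff_PSSM_score = unname(mut_scores[offsets == 0] - wt_site),
    diff_PSSM_score_aver = mean(mut_scores, na.rm = TRUE) -
      mean(wt_scores, na.rm = TRUE))
}

#' Assemble the feature table for a mutation dataset
#'
#' Featurizes every record of an (augmented or direct-only) DDG dataset.
#' For reverse records the mutant structure plays the wild-type role and
#' vice versa, matching the antisymmetric construction; measuring
#' conditions are unchanged and the label was negated during
#' augmentation. Records that fail (unresolvable chain, wild-type
#' mismatch) are collected into a failure report and do not abort the
#' rest. Column order equals the registry order, identical across runs.
#'
#' @param ds A DDG tibble.
#' @param structures Named list of wild-type `protein_structure`s keyed by
#'   `pdb_id`.
#' @param profiles Optional named list of PSSM profiles keyed by `pdb_id`
#'   (site positions are author residue numbers mapped to profile
#'   positions by rank within the chain).
#' @param aaindex,matrices Registered AAindex entries / substitution
#'   matrices (named lists).
#' @param adapters Optional per-`pdb_id` list of saved tool reports, each
#'   element a list with any of `foldx_wt`, `foldx_mut`, `sift`,
#'   `bfactor`, `disorder`.
#' @param window Evolutionary window half-width.
#' @return A list of class `stab_features`: `table` (tibble: `record_id`,
#'   `pair_id`, `origin`, `ddg`, then one column per registry feature),
#'   `registry`, and `failures` (tibble of `record_id`, `message`).
#' @export
assemble_feature_table <- function(ds, structures, profiles = NULL,
                                   aaindex = list(), matrices = list(),
                                   adapters = NULL, window = 5) {
  validate_ddg(ds)
  registry <- feature_registry(
    aaindex_accessions = vapply(aaindex, `[[`, "", "accession"),
    matrix_accessions = vapply(matrices, `[[`, "", "accession"),
    window = window
  )
  n <- nrow(ds)
  record_id <- sprintf("rec%06d", seq_len(n))
  origin <- if ("origin" %in% names(ds)) ds$origin else rep("direct", n)
  pair_id <- if ("pair_id" %in% names(ds)) ds$pair_id else record_id
  # cache: wild-type structure profiles keyed by (pdb, site); mutant ones
  # are record-specific
  wt_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n)
  failures <- list()
  for (i in seq_len(n)) {
    rec <- ds[i, ]
    out <- tryCatch({
      struct <- structures[[rec$pdb_id]]
      if (is.null(struct)) stop("no structure supplied for ", rec$pdb_id)
      ad <- adapters[[rec$pdb_id]] %||% list()
      site <- list(chain = rec$chain_id, resno = rec$position,
                   icode = rec$icode)
      # roles: for reverse records the mutant structure is the wild type
      orig_wt <- if (origin[i] == "direct") rec$wt_aa else rec$mut_aa
      orig_mut <- if (origin[i] == "direct") rec$mut_aa else rec$wt_aa
      mut_struct <- build_mutant_baseline(struct, rec$chain_id, rec$position,
                                          orig_wt, orig_mut, rec$icode)
      if (origin[i] == "direct") {
        wt_struct <- struct; wt_role_aa <- rec$wt_aa; mut_role_aa <- rec$mut_aa
        wt_role_struct <- struct; mut_role_struct <- mut_struct
        fx_wt <- ad$foldx_wt; fx_mut <- ad$foldx_mut
      } else {
        wt_role_aa <- rec$wt_aa; mut_role_aa <- rec$mut_aa
        wt_role_struct <- mut_struct; mut_role_struct <- struct
        fx_wt <- ad$foldx_mut; fx_mut <- ad$foldx_wt
      }
      cache_key <- paste(rec$pdb_id, rec$chain_id, rec$position, rec$icode,
                         wt_role_aa, sep = "|")
      g1 <- if (origin[i] == "direct" && !is.null(wt_cache[[cache_key]])) {
        wt_cache[[cache_key]]
      } else {
        p <- compute_group1(wt_role_struct, site, wt_aa = wt_role_aa,
                            ph = rec$ph, temperature_c = rec$temperature_c,
                            aaindex = aaindex, foldx = fx_wt,
                            disorder = ad$disorder, bfactor = ad$bfactor)
        if (origin[i] == "direct") wt_cache[[cache_key]] <- p
        p
      }
      g1_mut <- compute_group1(mut_role_struct, site, wt_aa = mut_role_aa,
                               ph = rec$ph, temperature_c = rec$temperature_c,
                               aaindex = aaindex, foldx = fx_mut,
                               disorder = ad$disorder, bfactor = ad$bfactor)
      g2 <- compute_group2_diff(g1, g1_mut, wt_foldx = fx_wt,
                                mut_foldx = fx_mut, aaindex = aaindex,
                                wt_aa = wt_role_aa, mut_aa = mut_role_aa)
      g3 <- compute_group3_mutation_type(
        wt_role_aa, mut_role_aa, g1$site_ss, g1_mut$site_ss,
        g1$site_int, g1_mut$site_int, matrices = matrices,
        sift = ad$sift,
        substitution = paste0(rec$wt_aa, rec$position, rec$mut_aa))
      g4 <- if (!is.null(profiles[[rec$pdb_id]])) {
        pssm <- profiles[[rec$pdb_id]]
        pos <- .author_to_profile_position(struct, rec$chain_id, rec$position,
                                           rec$icode)
        compute_group4_evolutionary(pssm, pos, wt_role_aa, mut_role_aa,
                                    window = window)
      } else {
        v <- registry$name[registry$group == "G4_evolutionary"]
        stats::setNames(rep(NA_real_, length(v)), v)
      }
      c(g1$values, g2, g3, g4)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(record_id = record_id[i], message = conditionMessage(out))
      rows[i] <- list(NULL)
    } else {
      stopifnot(setequal(names(out), registry$name))
      rows[[i]] <- c(out[registry$name])
    }
  }
  ok <- !vapply(rows, is.null, TRUE)
  mat <- do.call(rbind, rows[ok])
  tbl <- dplyr::bind_cols(
    tibble::tibble(record_id = record_id[ok], pair_id = pair_id[ok],
                   origin = origin[ok], ddg = ds$ddg[ok]),
    tibble::as_tibble(mat)
  )
  structure(
    list(table = tbl, registry = registry,
         failures = if (length(failures)) dplyr::bind_rows(failures) else
           tibble::tibble(record_id = character(), message = character())),
    class = "stab_features"
  )
}

# map an author residue number to its rank within the chain (profile row)
.author_to_profile_position <- function(struct, chain, resno, icode = "") {
  res <- structure_residues(struct)
  res <- res[res$chain == chain, ]
  hit <- which(res$resno == resno & res$icode == icode)
  if (!length(hit)) stop("site not found in chain ", chain, call. = FALSE)
  hit[1]
}

#' @export
print.stab_features <- function(x, ...) {
  man <- registry_manifest(x$registry)
  cat("<stab_features> ", nrow(x$table), " records x ", nrow(x$registry),
      " features (", nrow(x$failures), " failures)\n", sep = "")
  print(man)
  invisible(x)
}
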