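# Self-contained structural/environmental descriptors over residue sets:
# amino-acid category proportions, geometric interaction networks,
# pharmacophore atom counts, hydrophobic clusters, and disorder proportion.

#' Amino-acid and category proportions over a residue set
#'
#' Computes the proportion of each of the 20 amino acids and of each of the
#' eight physicochemical categories (see [aa_categories()]) in a residue
#' set. Categories may overlap, so a residue counts towards every category
#' it belongs to; the four charge/polarity categories partition the
#' alphabet and their proportions sum to 1 on any non-empty set. An empty
#' set yields all zeros.
#'
#' @param aa1 Character vector of one-letter residues (a shell, or the
#'   whole protein).
#' @return A named numeric vector: `prop_aa_<letter>` (20) then
#'   `prop_cat_<category>` (8).
#' @export
aa_category_proportions <- function(aa1) {
  aa1 <- toupper(aa1)
  n <- length(aa1)
  aa_prop <- if (n == 0) {
    stats::setNames(numeric(20), aa_alphabet())
  } else {
    table(factor(aa1, levels = aa_alphabet())) / n
  }
  cat_prop <- vapply(.aa_category_members, function(members) {
    if (n == 0) 0 else mean(aa1 %in% members)
  }, numeric(1))
  c(stats::setNames(as.numeric(aa_prop), paste0("prop_aa_", aa_alphabet())),
    stats::setNames(as.numeric(cat_prop),
                    paste0("prop_cat_", names(.aa_category_members))))
}

# helper: xyz matrix of selected atoms
.atom_xyz <- function(at) as.matrix(at[, c("x", "y", "z")])

# minimum distance between two atom sets
.min_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  d <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(0, min(d)))
}

#' Residue interaction network by geometric criteria
#'
#' Detects inter-residue interactions with documented distance criteria
#' (all configurable): hydrogen bond, donor N/O-hydroxyl to acceptor N/O
#' within 3.5 A; disulfide, CYS SG-SG within 2.5 A; ionic, side-chain
#' cation to anion group atoms within 4.0 A; van der Waals, heavy-atom
#' distance within the radii sum + 0.5 A between residues non-adjacent in
#' sequence; pi-cation, cation atom to aromatic ring centroid within
#' 5.0 A; pi-pi, ring centroids within 6.5 A. A residue pair can carry
#' several edge types (e.g. a salt bridge satisfies both the ionic and the
#' hydrogen-bond criterion). Edges are unordered and reported once.
#'
#' @param struct A `protein_structure`.
#' @param scope Optional character vector of `res_key`s restricting the
#'   network (default: all residues). Both endpoints must be in scope.
#' @param cutoffs Named numeric overrides of the default criteria.
#' @return A tibble of edges: `res_a`, `res_b`, `type`, `distance`.
#' @export
interaction_network <- function(struct, scope = NULL, cutoffs = NULL) {
  cut <- .interaction_defaults
  if (!is.null(cutoffs)) cut[names(cutoffs)] <- cutoffs
  at <- heavy_atoms(struct)
  if (!is.null(scope)) at <- dplyr::filter(at, .data$res_key %in% scope)
  res <- unique(at$res_key)
  if (length(res) < 2) {
    return(tibble::tibble(res_a = character(), res_b = character(),
                          type = character(), distance = numeric()))
  }
  # residue order index for sequence adjacency (file order within chain)
  all_res <- structure_residues(struct)
  ord <- stats::setNames(seq_len(nrow(all_res)), all_res$res_key)
  chain_of <- stats::setNames(all_res$chain, all_res$res_key)
  by_res <- split(at, at$res_key)[res]

  edges <- list()
  add_edge <- function(ra, rb, type, distance) {
    edges[[length(edges) + 1L]] <<-
      tibble::tibble(res_a = ra, res_b = rb, type = type, distance = distance)
  }
  ring_centroid <- function(a) {
    ring <- .ring_atoms[[a$resname[1]]]
    if (is.null(ring)) return(NULL)
    sel <- a[a$atom %in% ring, ]
    if (nrow(sel) < 3) return(NULL)
    colMeans(.atom_xyz(sel))
  }
  for (i in seq_along(res)[-length(res)]) {
    ai <- by_res[[i]]
    xi <- .atom_xyz(ai)
    for (j in seq((i + 1), length(res))) {
      aj <- by_res[[j]]
      xj <- .atom_xyz(aj)
      # cheap reject: bounding distance
      if (.min_dist(xi, xj) > max(cut["pi_pi"], cut["pi_cation"], 8)) next
      ra <- res[i]; rb <- res[j]
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)
      d2[d2 < 0] <- 0
      dmat <- sqrt(d2)
      # hydrogen bond: donor (N, or hydroxyl O) vs acceptor (O, or HIS-type ring N)
      don_i <- ai$element == "N" | ai$atom %in% c("OG", "OG1", "OH")
      don_j <- aj$element == "N" | aj$atom %in% c("OG", "OG1", "OH")
      acc_i <- ai$element == "O" | ai$atom %in% c("ND1", "NE2")
      acc_j <- aj$element == "O" | aj$atom %in% c("ND1", "NE2")
      hb <- dmat[don_i, acc_j, drop = FALSE]
      hb2 <- dmat[acc_i, don_j, drop = FALSE]
      dmin_hb <- suppressWarnings(min(c(hb, hb2), na.rm = TRUE))
      if (is.finite(dmin_hb) && dmin_hb <= cut["hydrogen_bond"]) {
        add_edge(ra, rb, "hydrogen_bond", dmin_hb)
      }
      # disulfide
      if (ai$resname[1] == "CYS" && aj$resname[1] == "CYS") {
        si <- which(ai$atom == "SG"); sj <- which(aj$atom == "SG")
        if (length(si) && length(sj)) {
          dss <- min(dmat[si, sj])
          if (dss <= cut["disulfide"]) add_edge(ra, rb, "disulfide", dss)
        }
      }
      # ionic
      cat_i <- ai$atom %in% (.cation_atoms[[ai$resname[1]]] %||% character())
      cat_j <- aj$atom %in% (.cation_atoms[[aj$resname[1]]] %||% character())
      an_i <- ai$atom %in% (.anion_atoms[[ai$resname[1]]] %||% character())
      an_j <- aj$atom %in% (.anion_atoms[[aj$resname[1]]] %||% character())
      ion <- c(dmat[cat_i, an_j, drop = TRUE], dmat[an_i, cat_j, drop = TRUE])
      if (length(ion) && min(ion) <= cut["ionic"]) {
        add_edge(ra, rb, "ionic", min(ion))
      }
      # van der Waals: non-adjacent residues only
      adjacent <- chain_of[[ra]] == chain_of[[rb]] &&
        abs(ord[[ra]] - ord[[rb]]) == 1L
      if (!adjacent) {
        thresh <- outer(vdw_radius(ai$element), vdw_radius(aj$element), `+`) +
          cut["vdw_slack"]
        if (any(dmat <= thresh)) {
          add_edge(ra, rb, "vdw", min(dmat[dmat <= thresh]))
        }
      }
      # pi-cation and pi-pi via ring centroids
      ci <- ring_centroid(ai); cj <- ring_centroid(aj)
      if (!is.null(cj) && any(cat_i)) {
        dpc <- sqrt(colSums((t(xi[cat_i, , drop = FALSE]) - cj)^2))
        if (min(dpc) <= cut["pi_cation"]) add_edge(ra, rb, "pi_cation", min(dpc))
      }
      if (!is.null(ci) && any(cat_j)) {
        dpc <- sqrt(colSums((t(xj[cat_j, , drop = FALSE]) - ci)^2))
        if (min(dpc) <= cut["pi_cation"]) add_edge(ra, rb, "pi_cation", min(dpc))
      }
      if (!is.null(ci) && !is.null(cj)) {
        dpp <- sqrt(sum((ci - cj)^2))
        if (dpp <= cut["pi_pi"]) add_edge(ra, rb, "pi_pi", dpp)
      }
    }
  }
  if (!length(edges)) {
    return(tibble::tibble(res_a = character(), res_b = character(),
                          type = character(), distance = numeric()))
  }
  dplyr::distinct(dplyr::bind_rows(edges),
                  .data$res_a, .data$res_b, .data$type, .keep_all = TRUE)
}

#' Interaction-type counts
#'
#' @param edges Edge tibble from [interaction_network()].
#' @return Named numeric vector `n_int_<type>` over the six types.
#' @export
interaction_counts <- function(edges) {
  counts <- table(factor(edges$type, levels = .interaction_types))
  stats::setNames(as.numeric(counts), paste0("n_int_", .interaction_types))
}

#' Pharmacophore atom counts
#'
#' Types every heavy atom in scope by the shipped (residue, atom name)
#' table: charged side-chain nitrogens/oxygens are positive/negative,
#' amide and hydroxyl groups donate/accept, ring atoms are aromatic (ring
#' carbons also hydrophobic), CYS SG and MET SD are sulphur, backbone N
#' donates and backbone O accepts, untyped carbons are hydrophobic and
#' anything left is neutral. Atoms may carry several classes and count in
#' each (the classes are not mutually exclusive). Unknown atom names are
#' counted neutral with a warning.
#'
#' @param struct A `protein_structure`.
#' @param scope Optional `res_key` subset; default all residues.
#' @return Named numeric vector `n_pharm_<class>` over the eight classes.
#' @export
pharmacophore_counts <- function(struct, scope = NULL) {
  at <- heavy_atoms(struct)
  if (!is.null(scope)) at <- dplyr::filter(at, .data$res_key %in% scope)
  counts <- stats::setNames(numeric(length(.pharm_classes)), .pharm_classes)
  if (!nrow(at)) {
    return(stats::setNames(counts, paste0("n_pharm_", .pharm_classes)))
  }
  backbone <- c("N", "CA", "C", "O", "OXT")
  unknown <- character()
  for (i in seq_len(nrow(at))) {
    resn <- at$resname[i]; name <- at$atom[i]; elem <- at$element[i]
    classes <- .pharm_table[[resn]][[name]]
    if (is.null(classes)) {
      if (name == "N" && elem == "N") {
        classes <- "donor"
      } else if (name %in% c("O", "OXT") && elem == "O") {
        classes <- "acceptor"
      } else if (elem == "C") {
        classes <- "hydrophobic"
      } else {
        classes <- "neutral"
        if (!name %in% backbone && !elem %in% c("N", "O", "S")) {
          unknown <- c(unknown, paste0(resn, "/", name))
        }
      }
    }
    counts[classes] <- counts[classes] + 1
  }
  if (length(unknown)) {
    warning("untyped atoms counted neutral: ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  stats::setNames(counts, paste0("n_pharm_", .pharm_classes))
}

#' Hydrophobic clusters
#'
#' Nodes are residues in the hydrophobic set (A, V, L, I, M, F, W, C);
#' an edge joins two nodes whose side-chain heavy atoms come within
#' 4.5 A. Clusters are connected components of size >= 2.
#'
#' @param struct A `protein_structure`.
#' @param contact_cutoff Side-chain contact distance (Angstrom, default 4.5).
#' @param scope Optional `res_key` subset restricting the node set.
#' @return A list with `clusters` (list of `res_key` vectors) and
#'   `summary` (named vector: `n_hyd_clusters`, `hyd_cluster_max_size`,
#'   `hyd_clustered_fraction` of in-scope residues).
#' @export
hydrophobic_clusters <- function(struct, contact_cutoff = 4.5, scope = NULL) {
  res <- structure_residues(struct)
  if (!is.null(scope)) res <- dplyr::filter(res, .data$res_key %in% scope)
  nodes <- res$res_key[res$aa1 %in% .hydrophobic_aa]
  summary0 <- c(n_hyd_clusters = 0, hyd_cluster_max_size = 0,
                hyd_clustered_fraction = 0)
  if (length(nodes) < 2) return(list(clusters = list(), summary = summary0))
  backbone <- c("N", "CA", "C", "O", "OXT")
  at <- heavy_atoms(struct) |>
    dplyr::filter(.data$res_key %in% nodes, !.data$atom %in% backbone)
  by_res <- split(at, factor(at$res_key, levels = nodes))
  have <- nodes[vapply(by_res, nrow, 1L) > 0]
  if (length(have) < 2) return(list(clusters = list(), summary = summary0))
  adj <- matrix(FALSE, length(have), length(have), dimnames = list(have, have))
  for (i in seq_along(have)[-length(have)]) {
    for (j in seq((i + 1), length(have))) {
      d <- .min_dist(.atom_xyz(by_res[[have[i]]]), .atom_xyz(by_res[[have[j]]]))
      if (d <= contact_cutoff) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- split(have, comp$membership)
  clusters <- unname(clusters[vapply(clusters, length, 1L) >= 2])
  sizes <- vapply(clusters, length, 1L)
  list(
    clusters = clusters,
    summary = c(
      n_hyd_clusters = length(clusters),
      hyd_cluster_max_size = if (length(sizes)) max(sizes) else 0,
      hyd_clustered_fraction = sum(sizes) / nrow(res)
    )
  )
}

#' Disorder proportion
#'
#' Fraction of residues labelled disordered. When a disorder report (from
#' [parse_tool_report()] with `kind = "disorder"`) is supplied its labels
#' are used; otherwise a baseline labels every residue ordered and the
#' result is flagged `baseline`. Residue numbers in a report must exist in
#' the structure.
#'
#' @param struct A `protein_structure`.
#' @param report Optional disorder report tibble (`resno`, `disordered`).
#' @return A list with `proportion` and `baseline` (logical flag).
#' @export
disorder_proportion <- function(struct, report = NULL) {
  res <- structure_residues(struct)
  if (is.null(report)) {
    return(list(proportion = 0, baseline = TRUE))
  }
  if (!all(c("resno", "disordered") %in% names(report))) {
    stop("disorder report must have columns resno, disordered", call. = FALSE)
  }
  if (!all(report$resno %in% res$resno)) {
    stop("disorder report names residues absent from the structure",
         call. = FALSE)
  }
  flags <- res |>
    dplyr::left_join(report, by = "resno") |>
    dplyr::mutate(disordered = tidyr::replace_na(.data$disordered, FALSE))
  list(proportion = mean(flags$disordered), baseline = FALSE)
}
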