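# Geometric primitives consumed by the feature groups: spatial shells,
# Shrake-Rupley solvent accessibility, dihedral-based secondary structure,
# and a C-alpha Gaussian network model for residue fluctuations.

#' Residues within a radius of a mutation site
#'
#' Shell membership uses the minimum heavy-atom/heavy-atom distance between
#' a residue and the site residue (a C-alpha-only metric is available via
#' `metric = "calpha"`). The site residue is always a member; `radius =
#' Inf` returns all residues. Shells nest: members within 7 A are a subset
#' of those within 10 A, and so on.
#'
#' @param struct A `protein_structure`.
#' @param site Residue address, `"chain:resno"` string or list.
#' @param radius Shell radius in Angstrom (may be `Inf`).
#' @param metric `"heavy"` (default, minimum heavy-atom distance) or
#'   `"calpha"` (C-alpha to C-alpha distance).
#' @return Character vector of member `res_key`s, in structure order.
#' @export
residues_within_radius <- function(struct, site, radius,
                                   metric = c("heavy", "calpha")) {
  metric <- match.arg(metric)
  key <- resolve_site(struct, site)
  at <- heavy_atoms(struct)
  if (metric == "calpha") at <- dplyr::filter(at, .data$atom == "CA")
  res_keys <- unique(struct$atoms$res_key)
  if (is.infinite(radius)) return(res_keys)
  site_xyz <- as.matrix(at[at$res_key == key, c("x", "y", "z")])
  if (!nrow(site_xyz)) site_xyz <-
      as.matrix(heavy_atoms(struct)[heavy_atoms(struct)$res_key == key,
                                    c("x", "y", "z")])
  other_xyz <- as.matrix(at[, c("x", "y", "z")])
  # squared distance of every atom to its nearest site atom
  d2 <- apply(site_xyz, 1, function(p) {
    (other_xyz[, 1] - p[1])^2 + (other_xyz[, 2] - p[2])^2 + (other_xyz[, 3] - p[3])^2
  })
  min_d2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
  hit <- unique(at$res_key[min_d2 <= radius^2])
  members <- union(key, hit)
  res_keys[res_keys %in% members]
}

# deterministic quasi-uniform sphere points (Fibonacci / golden-angle spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area by sphere-point quadrature with a deterministic
#' golden-spiral point set, summed per residue. An atom's test sphere has
#' radius vdW + probe; a point is accessible when outside every
#' neighbouring atom's test sphere.
#'
#' @param struct A `protein_structure`.
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, water).
#' @param n_points Quadrature points per atom (default 960).
#' @return A tibble with `res_key` and `sasa` (square Angstrom).
#' @export
shrake_rupley_sasa <- function(struct, probe_radius = 1.4, n_points = 960) {
  at <- heavy_atoms(struct)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- vdw_radius(at$element) + probe_radius
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists: atoms whose test spheres can overlap
  max_r <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + max_r)^2 & seq_len(n) != i)
    test <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * sum(accessible) / n_points
  }
  tibble::tibble(res_key = at$res_key, atom_area = area) |>
    dplyr::group_by(.data$res_key) |>
    dplyr::summarise(sasa = sum(.data$atom_area), .groups = "drop") |>
    dplyr::arrange(match(.data$res_key, unique(struct$atoms$res_key)))
}

#' Relative solvent accessibility
#'
#' RSA = SASA / theoretical maximum area for the amino acid (see
#' [max_asa_table()]), clipped to `[0, 1.2]`. A residue is labelled
#' `buried` when RSA < 0.25, otherwise `exposed`.
#'
#' @param sasa Numeric SASA values (square Angstrom).
#' @param aa1 One-letter amino acid(s), recycled against `sasa`.
#' @return A tibble with `rsa` and `burial` (`"buried"`/`"exposed"`).
#' @export
relative_accessibility <- function(sasa, aa1) {
  aa1 <- toupper(aa1)
  mx <- max_asa_table()[aa1]
  if (anyNA(mx)) {
    stop("unknown residue letter: ",
         paste(unique(aa1[is.na(mx)]), collapse = ", "), call. = FALSE)
  }
  rsa <- pmin(pmax(sasa / unname(mx), 0), 1.2)
  tibble::tibble(rsa = rsa,
                 burial = ifelse(rsa < 0.25, "buried", "exposed"))
}

# dihedral angle (degrees) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedral angles
#'
#' Computes per-residue phi/psi from backbone N, CA, C atoms. Chain
#' termini and residues with missing backbone atoms get `NA`.
#'
#' @param struct A `protein_structure`.
#' @return A tibble with `res_key`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(struct) {
  res <- structure_residues(struct)
  bb <- function(key, name) {
    a <- struct$atoms[struct$atoms$res_key == key & struct$atoms$atom == name, ]
    if (!nrow(a)) return(NULL)
    c(a$x[1], a$y[1], a$z[1])
  }
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same_chain_prev <- i > 1 && res$chain[i - 1] == res$chain[i]
    same_chain_next <- i < n && res$chain[i + 1] == res$chain[i]
    Ni <- bb(res$res_key[i], "N"); CAi <- bb(res$res_key[i], "CA")
    Ci <- bb(res$res_key[i], "C")
    if (same_chain_prev && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
      Cp <- bb(res$res_key[i - 1], "C")
      if (!is.null(Cp)) phi[i] <- .dihedral(Cp, Ni, CAi, Ci)
    }
    if (same_chain_next && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
      Nn <- bb(res$res_key[i + 1], "N")
      if (!is.null(Nn)) psi[i] <- .dihedral(Ni, CAi, Ci, Nn)
    }
  }
  tibble::tibble(res_key = res$res_key, phi = phi, psi = psi)
}

#' Eight-state secondary structure from backbone dihedrals
#'
#' A baseline classifier mapping (phi, psi) Ramachandran regions (see
#' [rama_region_table()]) onto the eight classes of [ss_classes()].
#' Termini and residues with undefined dihedrals or missing backbone
#' atoms are labelled `loop` (with a warning for missing atoms). When a
#' DSSP report is available, [parse_tool_report()] supplies labels that
#' override this baseline in the feature pipeline.
#'
#' @param struct A `protein_structure`.
#' @param regions Region table, defaults to [rama_region_table()].
#' @return A tibble with `res_key` and `ss` (factor levels [ss_classes()]).
#' @export
assign_secondary_structure <- function(struct, regions = rama_region_table()) {
  dih <- backbone_dihedrals(struct)
  res <- structure_residues(struct)
  has_bb <- vapply(res$res_key, function(k) {
    all(c("N", "CA", "C") %in% struct$atoms$atom[struct$atoms$res_key == k])
  }, TRUE)
  if (!all(has_bb)) {
    warning("residues with missing backbone atoms labelled loop: ",
            paste(res$res_key[!has_bb], collapse = ", "), call. = FALSE)
  }
  classify <- function(phi, psi) {
    if (is.na(phi) || is.na(psi)) return("loop")
    hit <- which(phi >= regions$phi_min & phi <= regions$phi_max &
                   psi >= regions$psi_min & psi <= regions$psi_max)
    if (!length(hit)) "loop" else regions$class[hit[1]]
  }
  ss <- mapply(classify, dih$phi, dih$psi)
  ss[!has_bb] <- "loop"
  tibble::tibble(res_key = dih$res_key,
                 ss = factor(ss, levels = ss_classes()))
}

#' Gaussian-network-model residue fluctuations
#'
#' A C-alpha Gaussian network model: the Kirchhoff (connectivity) matrix
#' is built from C-alpha contacts within `cutoff`; per-residue mean-square
#' fluctuations are proportional to the diagonal of its Moore-Penrose
#' pseudo-inverse, reported both raw (`msf_raw`) and normalized to unit
#' mean (`msf`). The model is a topology-only baseline for normal-mode
#' flexibility analysis; output depends only on inter-residue distances,
#' so it is invariant under rigid motion of the coordinates.
#'
#' @param struct A `protein_structure`.
#' @param cutoff Contact cutoff in Angstrom (default 7.3).
#' @return A tibble with `res_key`, `msf_raw`, `msf`.
#' @export
gnm_fluctuations <- function(struct, cutoff = 7.3) {
  ca <- dplyr::filter(heavy_atoms(struct), .data$atom == "CA")
  if (nrow(ca) < 2) stop("at least 2 C-alpha atoms required", call. = FALSE)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  contact <- (d <= cutoff) & !diag(TRUE, nrow(d))
  if (any(rowSums(contact) == 0) || {
    g <- igraph::graph_from_adjacency_matrix(contact, mode = "undirected")
    igraph::components(g)$no > 1
  }) {
    warning("contact graph is disconnected; fluctuations computed per component",
            call. = FALSE)
  }
  kirchhoff <- -1 * contact
  diag(kirchhoff) <- rowSums(contact)
  pinv <- MASS::ginv(kirchhoff)
  msf_raw <- diag(pinv)
  msf_raw[msf_raw < 0 & msf_raw > -1e-12] <- 0  # numerical floor
  tibble::tibble(res_key = ca$res_key, msf_raw = msf_raw,
                 msf = msf_raw / mean(msf_raw))
}
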