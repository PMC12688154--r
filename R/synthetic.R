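# Synthetic input generators: ideal-helix PDB structures, profile and
# property flat files, raw mutation tables, and planted-signal DDG
# benchmarks with built-in antisymmetry. Every generator is a pure
# function of its arguments (seed included) and round-trips through the
# package's own parsers, so the whole pipeline builds and tests without
# any downloaded data.

# NeRF: place atom d bonded to c with |cd| = bond, angle(b,c,d) = angle
# and dihedral(a,b,c,d) = dihedral (degrees)
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  angle <- angle * pi / 180; dihedral <- -dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# C-beta from tetrahedral geometry around CA
.place_cb <- function(n_xyz, ca, c_xyz, bond = 1.53) {
  u1 <- n_xyz - ca; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c_xyz - ca; u2 <- u2 / sqrt(sum(u2^2))
  c12 <- sum(u1 * u2)
  ct <- cos(110.4 * pi / 180)
  # in-plane coefficients from the two dot-product constraints
  alpha <- ct * (1 - c12) / (1 - c12^2)
  beta <- alpha
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  inplane <- alpha * u1 + beta * u2
  gamma <- sqrt(max(0, 1 - sum(inplane^2)))
  ca + bond * (inplane + gamma * perp)
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           occ = 1, b = 0, element) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Generate an ideal alpha-helical structure as PDB text
#'
#' Builds a poly-residue backbone (N, CA, C, O and C-beta except for
#' glycine) at the given backbone dihedrals, default the ideal alpha
#' helix (phi = -57, psi = -47), with standard bond lengths and angles.
#' The output is valid fixed-width PDB text that [read_pdb()] re-parses
#' to the same residue sequence, and whose interior residues the
#' dihedral classifier labels alpha-helix.
#'
#' @param sequence One-letter amino-acid string, length >= 4.
#' @param phi,psi Backbone dihedrals in degrees.
#' @param chain Chain identifier (default "A").
#' @return A single string of PDB text.
#' @export
make_helix_structure <- function(sequence, phi = -57, psi = -47, chain = "A") {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 4) stop("sequence must have length >= 4", call. = FALSE)
  bad <- !aa %in% aa_alphabet()
  if (any(bad)) {
    stop("invalid amino-acid letter: ", paste(unique(aa[bad]), collapse = ", "),
         call. = FALSE)
  }
  L <- length(aa)
  N <- CA <- C <- O <- CB <- vector("list", L)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[[1]] <- CA[[1]] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                            1.329, 116.2, psi)
      CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                             1.458, 121.7, 180)
      C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi)
    }
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.5, psi + 180)
    if (aa[i] != "G") CB[[i]] <- .place_cb(N[[i]], CA[[i]], C[[i]])
  }
  lines <- character()
  serial <- 0L
  for (i in seq_len(L)) {
    resname <- aa1_to_aa3(aa[i])
    add <- function(name, xyz, element) {
      serial <<- serial + 1L
      lines <<- c(lines, .pdb_atom_line(serial, name, resname, chain, i,
                                        xyz, element = element))
    }
    add("N", N[[i]], "N"); add("CA", CA[[i]], "C"); add("C", C[[i]], "C")
    add("O", O[[i]], "O")
    if (aa[i] != "G") add("CB", CB[[i]], "C")
  }
  paste(c(lines, "TER", "END"), collapse = "\n")
}

#' Generate profile and property flat-file fixtures
#'
#' Produces syntactically valid PSI-BLAST ASCII PSSM, AAindex1 and
#' AAindex2 (lower-triangular substitution matrix) texts with seeded
#' pseudo-random values, returning the ground-truth objects alongside the
#' texts so round-trips through the parsers can be asserted exactly.
#'
#' @param sequence One-letter amino-acid string for the PSSM.
#' @param seed Integer seed.
#' @param n_aaindex Number of AAindex1 property entries (default 3).
#' @return A list: `pssm_text`, `pssm` (truth), `aaindex1_text`,
#'   `aaindex1` (truth), `matrix_text`, `matrix` (truth).
#' @export
make_profile_fixtures <- function(sequence, seed = 1, n_aaindex = 3) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(aa %in% aa_alphabet()))
  L <- length(aa)
  withr::with_seed(seed, {
    scores <- matrix(as.numeric(sample(-8:8, L * 20, replace = TRUE)), L, 20,
                     dimnames = list(seq_len(L), aa_alphabet()))
    pcts <- matrix(sample(0:100, L * 20, replace = TRUE), L, 20)
    hdr2 <- paste(c(sprintf("%4s", aa_alphabet()), sprintf("%4s", aa_alphabet())),
                  collapse = "")
    pssm_lines <- c(
      "",
      "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
      paste0("            ", hdr2),
      vapply(seq_len(L), function(i) {
        paste0(sprintf("%5d %s  ", i, aa[i]),
               paste(sprintf("%3d", scores[i, ]), collapse = " "), "  ",
               paste(sprintf("%3d", pcts[i, ]), collapse = " "),
               sprintf("  %4.2f %8.2f", stats::runif(1, 0, 2), 0.5))
      }, ""),
      "", "                      K         Lambda")
    aaindex1_entries <- lapply(seq_len(n_aaindex), function(e) {
      vals <- round(stats::runif(20, -3, 3), 3)
      list(accession = sprintf("SYN%03d", e),
           description = sprintf("Synthetic physicochemical property %d", e),
           values = stats::setNames(vals, .aaindex1_order))
    })
    names(aaindex1_entries) <- vapply(aaindex1_entries, `[[`, "", "accession")
    aaindex1_lines <- unlist(lapply(aaindex1_entries, function(e) {
      c(paste("H", e$accession),
        paste("D", e$description),
        "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
        paste0("   ", paste(sprintf("%7.3f", e$values[1:10]), collapse = " ")),
        paste0("   ", paste(sprintf("%7.3f", e$values[11:20]), collapse = " ")),
        "//")
    }))
    mat <- matrix(NA_real_, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
    for (r in seq_len(20)) {
      mat[r, seq_len(r)] <- round(stats::runif(r, -5, 5), 1)
    }
    mat[upper.tri(mat)] <- t(mat)[upper.tri(mat)]
    matrix_lines <- c(
      "H SYNMAT1",
      "D Synthetic lower-triangular substitution matrix",
      paste0("M rows = ", paste(aa_alphabet(), collapse = ""),
             ", cols = ", paste(aa_alphabet(), collapse = "")),
      vapply(seq_len(20), function(r) {
        paste0("  ", paste(sprintf("%5.1f", mat[r, seq_len(r)]), collapse = " "))
      }, ""),
      "//")
    list(
      pssm_text = paste(pssm_lines, collapse = "\n"),
      pssm = list(sequence = paste(aa, collapse = ""), scores = scores),
      aaindex1_text = paste(aaindex1_lines, collapse = "\n"),
      aaindex1 = aaindex1_entries,
      matrix_text = paste(matrix_lines, collapse = "\n"),
      matrix = list(accession = "SYNMAT1", matrix = mat,
                    symmetric_completed = TRUE)
    )
  })
}

#' Generate a synthetic raw mutation table
#'
#' Draws `n` unique mutation records (structure id, chain, position,
#' substitution, pH, temperature, DDG) for exercising the dataset
#' mechanics at realistic scale. DDG values are centred near zero
#' (mildly destabilizing on average) as curated stability datasets are.
#'
#' @param n Number of unique records.
#' @param seed Integer seed.
#' @param n_proteins Number of synthetic structure identifiers.
#' @return A DDG tibble of `n` unique direct records.
#' @export
make_ddg_table <- function(n, seed = 1, n_proteins = 222) {
  withr::with_seed(seed, {
    pool_size <- max(4 * n, 1000)
    candidates <- tibble::tibble(
      pdb_id = sprintf("S%03X", sample.int(n_proteins, pool_size, replace = TRUE)),
      chain_id = "A",
      position = sample.int(300, pool_size, replace = TRUE),
      icode = "",
      wt_aa = sample(aa_alphabet(), pool_size, replace = TRUE),
      mut_aa = sample(aa_alphabet(), pool_size, replace = TRUE)
    ) |>
      dplyr::filter(.data$wt_aa != .data$mut_aa) |>
      dplyr::distinct(.data$pdb_id, .data$chain_id, .data$position,
                      .data$wt_aa, .data$mut_aa, .keep_all = TRUE)
    if (nrow(candidates) < n) {
      stop("could not draw ", n, " unique mutations; increase n_proteins",
           call. = FALSE)
    }
    candidates |>
      dplyr::slice_head(n = n) |>
      dplyr::mutate(
        ph = round(stats::runif(n, 4, 9), 1),
        temperature_c = round(stats::runif(n, 20, 40), 1),
        ddg = round(stats::rnorm(n, mean = 0.5, sd = 1.5), 2)
      )
  })
}

#' Generate a planted-signal DDG benchmark with antisymmetric pairs
#'
#' Direct-record labels are a linear function of `n_informative` of the
#' `n_features` standard-normal features plus Gaussian noise; each
#' reverse twin carries the negated informative block and the exactly
#' negated label, mirroring the antisymmetric augmentation so that a
#' correct pipeline can recover near-perfect pair anticorrelation. The
#' remaining features are pure noise and are left unchanged on reverse
#' rows.
#'
#' @param n_pairs Number of direct/reverse pairs.
#' @param n_features Total feature count.
#' @param n_informative Number of features carrying signal
#'   (`<= n_features`).
#' @param noise_sd Label noise standard deviation (kcal/mol).
#' @param seed Integer seed.
#' @return A list of class `stab_benchmark`: `table` (tibble with
#'   `record_id`, `pair_id`, `origin`, `ddg` and feature columns
#'   `f001`...), `informative` (feature names), `weights`, `noise_sd`,
#'   `seed`.
#' @export
make_ddg_benchmark <- function(n_pairs, n_features = 40, n_informative = 5,
                               noise_sd = 0.2, seed = 1) {
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features", call. = FALSE)
  }
  if (n_pairs < 1 || n_features < 1) stop("invalid sizes", call. = FALSE)
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n_pairs * n_features), n_pairs, n_features)
    colnames(X) <- sprintf("f%03d", seq_len(n_features))
    informative <- colnames(X)[seq_len(n_informative)]
    w <- stats::runif(n_informative, 1, 2) *
      sample(c(-1, 1), n_informative, replace = TRUE)
    eps <- stats::rnorm(n_pairs, 0, noise_sd)
    y_dir <- as.numeric(X[, informative, drop = FALSE] %*% w) + eps
    X_rev <- X
    X_rev[, informative] <- -X_rev[, informative]
    pair_id <- sprintf("pair%06d", seq_len(n_pairs))
    tbl <- dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(record_id = paste0(pair_id, "_d"), pair_id = pair_id,
                       origin = "direct", ddg = y_dir),
        tibble::as_tibble(X)),
      dplyr::bind_cols(
        tibble::tibble(record_id = paste0(pair_id, "_r"), pair_id = pair_id,
                       origin = "reverse", ddg = -y_dir),
        tibble::as_tibble(X_rev))
    ) |>
      dplyr::arrange(.data$pair_id, dplyr::desc(.data$origin == "direct"))
    structure(
      list(table = tbl, informative = informative,
           weights = stats::setNames(w, informative),
           noise_sd = noise_sd, seed = seed),
      class = "stab_benchmark"
    )
  })
}
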