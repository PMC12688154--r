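# PDB parsing and the baseline mutant builder. bio3d does the fixed-width
# heavy lifting; this layer applies the package's contract on top: first
# model only, alternate locations resolved by occupancy, HETATM and waters
# dropped, and a tidy atom tibble as the working representation.

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM records (wwPDB v3.3 fixed-width dialect) into a
#' `protein_structure`: a list with an `atoms` tibble (one row per heavy
#' or hydrogen atom), the source identifier, and a `sidechain_complete`
#' flag. Only the first MODEL is read; alternate locations are resolved to
#' the highest-occupancy conformer (ties go to altloc `"A"`); HETATM
#' records and waters are excluded; hydrogens are retained but ignored by
#' heavy-atom geometry.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param id Optional source identifier stored on the structure.
#' @return A `protein_structure` object.
#' @export
read_pdb <- function(source, id = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    if (is.null(id)) id <- "structure"
  }
  # keep the first model only
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    end1 <- grep("^ENDMDL", lines)[1]
    if (!is.na(end1)) lines <- lines[seq_len(end1)]
  }
  atom_idx <- grep("^ATOM  ", lines)
  if (!length(atom_idx)) stop("no ATOM records found in PDB input", call. = FALSE)
  # pre-scan coordinates so malformed lines are reported with their number
  for (i in atom_idx) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54)
    )))
    if (anyNA(xyz)) {
      stop("unreadable coordinates in ATOM record at line ", i, call. = FALSE)
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(at, .data$type == "ATOM", .data$resid != "HOH")
  if (!nrow(at)) stop("no amino-acid ATOM records after filtering", call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$elesy[is.na(at$elesy) | !nzchar(trimws(at$elesy))] <-
    substr(gsub("[^A-Za-z]", "", at$elety[is.na(at$elesy) | !nzchar(trimws(at$elesy))]), 1, 1)
  atoms <- tibble::tibble(
    serial = at$eleno,
    atom = at$elety,
    altloc = at$alt,
    resname = at$resid,
    chain = at$chain,
    resno = at$resno,
    icode = at$insert,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    element = toupper(trimws(at$elesy))
  )
  # altloc resolution: per (residue, atom name) keep highest occupancy, tie -> 'A'
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$atom) |>
    dplyr::slice_min(
      order_by = tibble::tibble(neg_occ = -occupancy,
                                alt = ifelse(altloc == "", "A", altloc)),
      n = 1, with_ties = FALSE
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial) |>
    dplyr::mutate(
      aa1 = aa3_to_aa1(.data$resname),
      res_key = paste0(.data$chain, ":", .data$resno, .data$icode)
    )
  structure(
    list(atoms = atoms, id = id, sidechain_complete = TRUE),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat("<protein_structure> ", x$id, ": ", nrow(res), " residues, ",
      nrow(x$atoms), " atoms",
      if (!x$sidechain_complete) " (side-chain-incomplete baseline)", "\n",
      sep = "")
  invisible(x)
}

#' Residue summary of a structure
#'
#' @param struct A `protein_structure`.
#' @return A tibble with one row per residue: `res_key`, `chain`, `resno`,
#'   `icode`, `resname`, `aa1`, `n_atoms`, in file order.
#' @export
structure_residues <- function(struct) {
  struct$atoms |>
    dplyr::group_by(.data$res_key) |>
    dplyr::summarise(
      chain = dplyr::first(.data$chain),
      resno = dplyr::first(.data$resno),
      icode = dplyr::first(.data$icode),
      resname = dplyr::first(.data$resname),
      aa1 = dplyr::first(.data$aa1),
      n_atoms = dplyr::n(),
      .order = min(match(.data$res_key, struct$atoms$res_key)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.order) |>
    dplyr::select(-".order")
}

# resolve a site given as "A:6" / "A:6B" or a list(chain=, resno=, icode=)
resolve_site <- function(struct, site) {
  if (is.character(site) && length(site) == 1L) {
    m <- regmatches(site, regexec("^(.+?):(-?[0-9]+)([A-Za-z]?)$", site))[[1]]
    if (length(m) != 4L) stop("unparseable site: ", sQuote(site), call. = FALSE)
    site <- list(chain = m[2], resno = as.integer(m[3]), icode = m[4])
  }
  key <- paste0(site$chain, ":", site$resno, site$icode %||% "")
  if (!key %in% struct$atoms$res_key) {
    stop("site ", sQuote(key), " not found in structure ", struct$id, call. = FALSE)
  }
  key
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a baseline point-mutant structure
#'
#' A dependency-free mutant model: the target residue is renamed to the
#' mutant amino acid and its side chain truncated at C-beta (C-beta is
#' removed for mutations to glycine). Every atom of every other residue is
#' preserved bit-exactly. The result is flagged `sidechain_complete =
#' FALSE` so downstream features can distinguish baseline from fully
#' modelled mutants; a full side-chain modelling provider can be plugged
#' into the pipeline in its place.
#'
#' @param struct A `protein_structure`.
#' @param chain,position,icode Residue address (author numbering).
#' @param wt_aa,mut_aa One-letter wild-type and mutant amino acids; the
#'   wild-type letter is checked against the structure.
#' @return A `protein_structure` flagged side-chain-incomplete.
#' @export
build_mutant_baseline <- function(struct, chain, position, wt_aa, mut_aa,
                                  icode = "") {
  key <- resolve_site(struct, list(chain = chain, resno = position, icode = icode))
  res_atoms <- dplyr::filter(struct$atoms, .data$res_key == key)
  found <- res_atoms$aa1[1]
  if (found != toupper(wt_aa)) {
    stop("wild-type identity mismatch at ", key, ": structure has ", found,
         ", record says ", wt_aa, call. = FALSE)
  }
  keep <- c("N", "CA", "C", "O")
  if (toupper(mut_aa) != "G") keep <- c(keep, "CB")
  atoms <- struct$atoms |>
    dplyr::filter(.data$res_key != key | .data$atom %in% keep) |>
    dplyr::mutate(
      resname = ifelse(.data$res_key == key, aa1_to_aa3(mut_aa), .data$resname),
      aa1 = ifelse(.data$res_key == key, toupper(mut_aa), .data$aa1)
    )
  structure(
    list(atoms = atoms, id = paste0(struct$id, "_", wt_aa, position, mut_aa),
         sidechain_complete = FALSE),
    class = "protein_structure"
  )
}

# heavy atoms only (geometry operations ignore hydrogens)
heavy_atoms <- function(struct) {
  dplyr::filter(struct$atoms, .data$element != "H")
}
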