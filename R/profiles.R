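# Flat-file dialect readers: AAindex1 property entries, AAindex2/3
# substitution matrices, PSI-BLAST ASCII PSSMs, and saved reports from
# external tools (FoldX energies, DSSP, SIFT, B-factor and disorder
# predictions). This module never executes an external binary; it only
# ingests their saved outputs, or the pipeline falls back to internal
# baselines.

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE))
  }
}

# column order of the 'I' record in AAindex1: A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V
.aaindex1_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse AAindex1 property entries
#'
#' Reads the AAindex1 flat-file dialect (records `H` accession, `D`
#' description, `I` index header followed by two rows of ten values,
#' entries terminated by `//`). `NA` cells are masked (stored as `NA`,
#' never silently zero).
#'
#' @param text AAindex1 text or file path.
#' @return A named list of entries; each entry has `accession`,
#'   `description` and `values` (named numeric over the 20 amino acids,
#'   possibly with `NA`).
#' @export
parse_aaindex1 <- function(text) {
  lines <- .as_lines(text)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "H ")) {
      accession <- trimws(sub("^H ", "", lines[i]))
      description <- ""
      values <- NULL
      j <- i + 1L
      while (j <= length(lines) && !startsWith(lines[j], "//")) {
        if (startsWith(lines[j], "D ")) {
          description <- trimws(sub("^D ", "", lines[j]))
        }
        if (startsWith(lines[j], "I ")) {
          if (j + 2L > length(lines)) {
            stop("truncated AAindex1 entry ", accession, call. = FALSE)
          }
          toks <- unlist(strsplit(trimws(paste(lines[j + 1L], lines[j + 2L])),
                                  "[[:space:]]+"))
          if (length(toks) != 20L) {
            stop("AAindex1 entry ", accession, " has ", length(toks),
                 " values (expected 20)", call. = FALSE)
          }
          vals <- suppressWarnings(as.numeric(toks))
          vals[toks %in% c("NA", "NA.")] <- NA_real_
          if (any(is.na(vals) & !toks %in% c("NA", "NA."))) {
            stop("unparseable value in AAindex1 entry ", accession, call. = FALSE)
          }
          values <- stats::setNames(vals, .aaindex1_order)
          j <- j + 2L
        }
        j <- j + 1L
      }
      if (is.null(values)) {
        stop("AAindex1 entry ", accession, " has no I record", call. = FALSE)
      }
      entries[[accession]] <- list(accession = accession,
                                   description = description, values = values)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(entries)) stop("no AAindex1 entries found", call. = FALSE)
  entries
}

#' Look up an AAindex1 property value
#'
#' Errors on masked (`NA`) cells rather than returning them silently.
#'
#' @param entry An entry from [parse_aaindex1()].
#' @param aa One-letter amino acid.
#' @return The numeric property value.
#' @export
aaindex_value <- function(entry, aa) {
  v <- entry$values[[toupper(aa)]]
  if (is.null(v)) stop("unknown amino acid ", sQuote(aa), call. = FALSE)
  if (is.na(v)) {
    stop("AAindex entry ", entry$accession, " has a masked (NA) value for ",
         sQuote(aa), call. = FALSE)
  }
  v
}

#' Parse an AAindex2/3 substitution matrix
#'
#' Reads the matrix dialect: an `M rows = ..., cols = ...` declaration
#' followed by the matrix body, one row per line. Lower-triangular bodies
#' are symmetric-completed so `lookup(a, b) == lookup(b, a)`; square
#' bodies are accepted verbatim.
#'
#' @param text AAindex2/3 text or file path.
#' @param accession Optional accession override (default: from the `H`
#'   record).
#' @return A list with `accession`, `matrix` (20x20 or as declared, with
#'   dimnames), and `symmetric_completed` flag.
#' @export
parse_aaindex_matrix <- function(text, accession = NULL) {
  lines <- .as_lines(text)
  h <- grep("^H ", lines, value = TRUE)
  if (is.null(accession)) {
    accession <- if (length(h)) trimws(sub("^H ", "", h[1])) else "matrix"
  }
  m_idx <- grep("^M ", lines)
  if (!length(m_idx)) stop("no M record in AAindex matrix", call. = FALSE)
  decl <- lines[m_idx[1]]
  rows <- sub(".*rows = ([A-Z]+).*", "\\1", decl)
  cols <- sub(".*cols = ([A-Z]+).*", "\\1", decl)
  row_aa <- strsplit(rows, "")[[1]]
  col_aa <- strsplit(cols, "")[[1]]
  if (!identical(sort(row_aa), sort(col_aa))) {
    stop("row/col alphabet mismatch in AAindex matrix ", accession, call. = FALSE)
  }
  body <- lines[seq(m_idx[1] + 1L, length(lines))]
  body <- body[!startsWith(body, "//") & nzchar(trimws(body))]
  body <- body[seq_len(length(row_aa))]
  mat <- matrix(NA_real_, length(row_aa), length(col_aa),
                dimnames = list(row_aa, col_aa))
  lower_triangular <- TRUE
  for (r in seq_along(row_aa)) {
    toks <- unlist(strsplit(trimws(body[r]), "[[:space:]]+"))
    vals <- suppressWarnings(as.numeric(toks))
    vals[toks == "NA"] <- NA_real_
    if (length(vals) == length(col_aa)) {
      if (r < length(row_aa)) lower_triangular <- FALSE
      mat[r, ] <- vals
    } else if (length(vals) == r) {
      mat[r, seq_len(r)] <- vals
    } else {
      stop("row ", r, " of AAindex matrix ", accession, " has ", length(vals),
           " values (expected ", r, " or ", length(col_aa), ")", call. = FALSE)
    }
  }
  completed <- FALSE
  if (lower_triangular) {
    mat[upper.tri(mat)] <- t(mat)[upper.tri(mat)]
    completed <- TRUE
  }
  list(accession = accession, matrix = mat, symmetric_completed = completed)
}

#' Look up a substitution-matrix value
#'
#' @param sm A matrix object from [parse_aaindex_matrix()].
#' @param a,b One-letter amino acids.
#' @return Numeric matrix value.
#' @export
substitution_value <- function(sm, a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!a %in% rownames(sm$matrix) || !b %in% colnames(sm$matrix)) {
    stop("amino acid not covered by matrix ", sm$accession, call. = FALSE)
  }
  sm$matrix[a, b]
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII position-specific scoring matrix dialect written by
#' iterated profile search: a header naming the 20 amino-acid columns
#' twice, then one row per position with the position index, the query
#' residue, 20 integer log-odds, 20 weighted percentages and information
#' columns. Only the sequence and the log-odds block are captured.
#'
#' @param text PSSM text or file path.
#' @return A list with `sequence` (string of length L) and `scores`
#'   (L x 20 matrix, columns in [aa_alphabet()] order, rows 1-based
#'   positions).
#' @export
parse_pssm_ascii <- function(text) {
  lines <- .as_lines(text)
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s", lines, value = TRUE)
  if (!length(rows)) stop("empty PSSM body", call. = FALSE)
  parsed <- lapply(rows, function(l) unlist(strsplit(trimws(l), "[[:space:]]+")))
  lens <- vapply(parsed, length, 1L)
  if (any(lens < 22L)) {
    stop("PSSM row with fewer than 22 fields", call. = FALSE)
  }
  pos <- as.integer(vapply(parsed, `[[`, "", 1L))
  if (!identical(pos, seq_along(pos))) {
    stop("PSSM positions are not consecutive from 1 (row/sequence length mismatch)",
         call. = FALSE)
  }
  seq_aa <- vapply(parsed, `[[`, "", 2L)
  scores <- t(vapply(parsed, function(p) as.numeric(p[3:22]), numeric(20)))
  if (anyNA(scores)) stop("unparseable PSSM score cell", call. = FALSE)
  colnames(scores) <- aa_alphabet()
  rownames(scores) <- pos
  list(sequence = paste(seq_aa, collapse = ""), scores = scores)
}

#' Look up a PSSM log-odds score
#'
#' @param pssm A profile from [parse_pssm_ascii()].
#' @param position 1-based sequence position.
#' @param aa One-letter amino acid.
#' @return Numeric log-odds score.
#' @export
pssm_score <- function(pssm, position, aa) {
  if (position < 1 || position > nrow(pssm$scores)) {
    stop("position ", position, " outside profile length ",
         nrow(pssm$scores), call. = FALSE)
  }
  pssm$scores[position, toupper(aa)]
}

# the 20 named FoldX energy terms, in schema order; total first
.foldx_terms <- c(
  "total_energy", "backbone_hbond", "sidechain_hbond", "van_der_waals",
  "electrostatics", "solvation_polar", "solvation_hydrophobic",
  "vdw_clashes", "entropy_sidechain", "entropy_mainchain", "sloop_entropy",
  "mloop_entropy", "cis_bond", "torsional_clash", "backbone_clash",
  "helix_dipole", "water_bridge", "disulfide_energy", "electrostatic_kon",
  "partial_covalent"
)

#' FoldX energy-term schema
#'
#' @return Character vector of the 20 energy-term names, total energy first.
#' @export
foldx_term_names <- function() .foldx_terms

#' Parse a saved external-tool report
#'
#' Supported kinds and their dialects:
#' * `foldx`: tab-separated table whose last 20 numeric columns are the
#'   energy terms (total energy first); returns a named numeric vector
#'   over [foldx_term_names()].
#' * `dssp`: classic fixed-column DSSP output; returns a tibble with
#'   `resno`, `chain`, `aa1`, `ss` (letters mapped to [ss_classes()])
#'   and `acc`.
#' * `sift`: tab-separated `substitution`, `score`, `prediction`
#'   (TOLERATED/DELETERIOUS); returns a tibble.
#' * `bfactor`: tab-separated per-residue `resno`, `bfactor` predictions.
#' * `disorder`: tab-separated per-residue `resno`, `disordered` (0/1).
#'
#' @param kind One of `"foldx"`, `"dssp"`, `"sift"`, `"bfactor"`,
#'   `"disorder"`.
#' @param text Report text or file path.
#' @return Kind-specific bundle (see above).
#' @export
parse_tool_report <- function(kind, text) {
  kind <- as.character(kind)
  if (!kind %in% c("foldx", "dssp", "sift", "bfactor", "disorder")) {
    stop("unknown report kind: ", sQuote(kind), call. = FALSE)
  }
  lines <- .as_lines(text)
  switch(kind,
    foldx = {
      data_lines <- lines[nzchar(trimws(lines))]
      toks <- strsplit(data_lines[length(data_lines)], "\t", fixed = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      vals <- vals[!is.na(vals)]
      if (length(vals) < 20L) {
        stop("FoldX report has ", length(vals),
             " numeric fields (expected 20 energy terms)", call. = FALSE)
      }
      stats::setNames(utils::tail(vals, 20L), .foldx_terms)
    },
    dssp = {
      hdr <- grep("^  #  RESIDUE", lines)
      if (!length(hdr)) stop("no DSSP residue header found", call. = FALSE)
      body <- lines[seq(hdr[1] + 1L, length(lines))]
      body <- body[nzchar(trimws(body))]
      body <- body[substr(body, 14, 14) != "!"]
      if (!length(body)) stop("empty DSSP body", call. = FALSE)
      resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
      if (anyNA(resno)) {
        bad <- which(is.na(resno))[1]
        stop("malformed DSSP residue line at byte offset ",
             sum(nchar(lines[seq_len(hdr[1] + bad - 1L)]) + 1L), call. = FALSE)
      }
      tibble::tibble(
        resno = resno,
        chain = trimws(substr(body, 12, 12)),
        aa1 = substr(body, 14, 14),
        ss = dssp_letter_to_class(substr(body, 17, 17)),
        acc = suppressWarnings(as.numeric(substr(body, 35, 38)))
      )
    },
    sift = {
      df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                              stringsAsFactors = FALSE)
      need <- c("substitution", "score", "prediction")
      if (!all(need %in% names(df))) {
        stop("SIFT report must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      if (!all(df$prediction %in% c("TOLERATED", "DELETERIOUS"))) {
        stop("SIFT prediction must be TOLERATED or DELETERIOUS", call. = FALSE)
      }
      tibble::as_tibble(df)
    },
    bfactor = {
      df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                              stringsAsFactors = FALSE)
      if (!all(c("resno", "bfactor") %in% names(df))) {
        stop("B-factor report must have columns resno, bfactor", call. = FALSE)
      }
      tibble::as_tibble(df)
    },
    disorder = {
      df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                              stringsAsFactors = FALSE)
      if (!all(c("resno", "disordered") %in% names(df))) {
        stop("disorder report must have columns resno, disordered", call. = FALSE)
      }
      df$disordered <- as.logical(df$disordered)
      tibble::as_tibble(df)
    }
  )
}
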