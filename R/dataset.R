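# Mutation-dataset mechanics: parsing, validation, merging, antisymmetric
# reverse-mutation augmentation, and pair-level splitting / fold assignment.
#
# A DDG dataset is an ordinary tibble with one row per mutation observation:
#   pdb_id, chain_id, position, icode, wt_aa, mut_aa, ph, temperature_c, ddg
# plus, after augmentation, `origin` ("direct"/"reverse") and `pair_id`.

.ddg_required_cols <- c("pdb_id", "chain_id", "position", "icode",
                        "wt_aa", "mut_aa", "ph", "temperature_c", "ddg")

#' Parse a substitution string
#'
#' Substitutions are written `<wt><position><mut>`, e.g. `"K6Q"` for
#' lysine to glutamine at author position 6. Insertion codes are not part
#' of the substitution string; they travel in the dataset's `icode`
#' column.
#'
#' @param text Character vector of substitution strings.
#' @return A tibble with columns `wt_aa`, `position`, `mut_aa`.
#' @examples
#' parse_substitution("K6Q")
#' @export
parse_substitution <- function(text) {
  text <- toupper(trimws(text))
  if (any(!nzchar(text))) stop("empty substitution string", call. = FALSE)
  m <- regmatches(text, regexec("^([A-Z])([0-9]+)([A-Z])$", text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed substitution string: ",
         paste(sQuote(text[bad]), collapse = ", "), call. = FALSE)
  }
  wt <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  mut <- vapply(m, `[[`, "", 4L)
  non_std <- !(wt %in% aa_alphabet()) | !(mut %in% aa_alphabet())
  if (any(non_std)) {
    stop("non-standard amino acid in substitution: ",
         paste(sQuote(text[non_std]), collapse = ", "), call. = FALSE)
  }
  self <- wt == mut
  if (any(self)) {
    stop("self-substitution (wild-type equals mutant): ",
         paste(sQuote(text[self]), collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1L)) stop("substitution position must be >= 1", call. = FALSE)
  tibble::tibble(wt_aa = wt, position = pos, mut_aa = mut)
}

#' Read a raw mutation table
#'
#' Reads a CSV with header columns `pdb_id, substitution, chain_id, ph,
#' temperature_c, ddg` (UTF-8, comma separator, `.` decimal) and returns a
#' validated DDG tibble. The substitution column is expanded into
#' `wt_aa`/`position`/`mut_aa`; an optional `icode` column is carried
#' through (default empty).
#'
#' @param file Path to the CSV file.
#' @return A DDG tibble (one row per observation).
#' @export
read_ddg_csv <- function(file) {
  raw <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  need <- c("pdb_id", "substitution", "chain_id", "ph", "temperature_c", "ddg")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  parsed <- parse_substitution(raw$substitution)
  out <- tibble::tibble(
    pdb_id = toupper(as.character(raw$pdb_id)),
    chain_id = as.character(raw$chain_id),
    position = parsed$position,
    icode = if ("icode" %in% names(raw)) {
      tidyr::replace_na(as.character(raw$icode), "")
    } else "",
    wt_aa = parsed$wt_aa,
    mut_aa = parsed$mut_aa,
    ph = as.numeric(raw$ph),
    temperature_c = as.numeric(raw$temperature_c),
    ddg = as.numeric(raw$ddg)
  )
  validate_ddg(out)
}

#' Validate a DDG tibble
#'
#' Checks the column contract and the row invariants: standard amino acids,
#' wild-type differing from mutant, finite pH/temperature/ddg values, and
#' (when `origin` is present) that every reverse row has a direct sibling
#' sharing its `pair_id`.
#'
#' @param ds A DDG tibble.
#' @return The validated input, for piping.
#' @export
validate_ddg <- function(ds) {
  missing <- setdiff(.ddg_required_cols, names(ds))
  if (length(missing)) {
    stop("DDG table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok_aa <- ds$wt_aa %in% aa_alphabet() & ds$mut_aa %in% aa_alphabet()
  if (!all(ok_aa)) stop("non-standard amino acid letter in DDG table", call. = FALSE)
  if (any(ds$wt_aa == ds$mut_aa)) stop("self-substitution in DDG table", call. = FALSE)
  if (any(ds$position < 1L)) stop("position must be >= 1", call. = FALSE)
  num <- c("ph", "temperature_c", "ddg")
  if (!all(vapply(ds[num], function(x) all(is.finite(x)), TRUE))) {
    stop("non-finite ph, temperature or ddg value", call. = FALSE)
  }
  if ("origin" %in% names(ds)) {
    if (!all(ds$origin %in% c("direct", "reverse"))) {
      stop("origin must be 'direct' or 'reverse'", call. = FALSE)
    }
    rev_ids <- ds$pair_id[ds$origin == "reverse"]
    dir_ids <- ds$pair_id[ds$origin == "direct"]
    if (!all(rev_ids %in% dir_ids)) {
      stop("reverse record without a direct sibling sharing its pair_id",
           call. = FALSE)
    }
  }
  ds
}

# identity of a mutation observation for merging: key + measuring conditions
.mutation_group_key <- function(ds) {
  paste(ds$pdb_id, ds$chain_id, ds$position, ds$icode,
        ds$wt_aa, ds$mut_aa, ds$ph, ds$temperature_c, sep = "|")
}

#' Merge mutation datasets
#'
#' Concatenates the sources (in order), then deduplicates groups sharing
#' the same mutation key and measuring conditions (pH, temperature):
#' within a group with identical DDG one row is kept; within a group with
#' differing DDG values the row with |ddg| closest to zero is kept, ties
#' broken by first occurrence in input order. Output preserves
#' first-occurrence order, so downstream seeded operations are
#' deterministic.
#'
#' @param ... DDG tibbles (or a single list of them).
#' @return A merged DDG tibble.
#' @export
merge_ddg_records <- function(...) {
  sources <- list(...)
  if (length(sources) == 1L && is.list(sources[[1]]) &&
      !is.data.frame(sources[[1]])) {
    sources <- sources[[1]]
  }
  ds <- dplyr::bind_rows(lapply(sources, validate_ddg))
  key <- .mutation_group_key(ds)
  ds |>
    dplyr::mutate(.key = key, .ord = dplyr::row_number()) |>
    dplyr::group_by(.data$.key) |>
    dplyr::mutate(.grp_ord = min(.data$.ord)) |>
    dplyr::slice_min(
      order_by = tibble::tibble(abs_ddg = abs(ddg), ord = .ord),
      n = 1, with_ties = FALSE
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.grp_ord) |>
    dplyr::select(-".key", -".ord", -".grp_ord")
}

#' Add hypothetical reverse mutations
#'
#' Free energy is a state function, so the stability change of the reverse
#' substitution B->A equals the negation of A->B. For every (direct) row
#' this adds its reverse sibling: amino acids swapped, ddg negated,
#' measuring conditions unchanged, and a shared `pair_id`. The output
#' interleaves each direct row with its reverse and carries `origin`.
#'
#' @param ds A DDG tibble containing only direct records.
#' @return An augmented DDG tibble with exactly `2 * nrow(ds)` rows.
#' @export
augment_reverse <- function(ds) {
  validate_ddg(ds)
  if ("origin" %in% names(ds) && any(ds$origin == "reverse")) {
    stop("dataset already contains reverse records; double augmentation is forbidden",
         call. = FALSE)
  }
  n <- nrow(ds)
  direct <- ds |>
    dplyr::select(dplyr::all_of(.ddg_required_cols)) |>
    dplyr::mutate(origin = "direct", pair_id = sprintf("pair%06d", seq_len(n)))
  reverse <- direct |>
    dplyr::mutate(
      wt_aa = direct$mut_aa,
      mut_aa = direct$wt_aa,
      ddg = -direct$ddg,
      origin = "reverse"
    )
  dplyr::bind_rows(direct, reverse) |>
    dplyr::arrange(.data$pair_id, dplyr::desc(.data$origin == "direct"))
}

# pair ids in first-occurrence order, with integrity check
.pair_ids_checked <- function(ds) {
  if (!all(c("origin", "pair_id") %in% names(ds))) {
    stop("dataset is not augmented: origin/pair_id columns required", call. = FALSE)
  }
  counts <- table(ds$pair_id)
  dir_n <- table(ds$pair_id[ds$origin == "direct"])
  if (any(counts != 2L) || length(dir_n) != length(counts) || any(dir_n != 1L)) {
    stop("unpaired record: every pair_id must have exactly one direct and one reverse row",
         call. = FALSE)
  }
  unique(ds$pair_id)
}

#' Split an augmented dataset at the pair level
#'
#' Direct/reverse pairs are the sampling unit: pairs are shuffled with the
#' given seed and the first `ceiling(train_fraction * n_pairs)` pairs form
#' the training set, the remainder the test set. No pair is ever split
#' across partitions.
#'
#' @param ds Augmented DDG tibble (from [augment_reverse()]).
#' @param train_fraction Fraction of pairs assigned to training (default 0.9).
#' @param seed Integer seed for the shuffle (default 42).
#' @return A list with tibbles `train` and `test`.
#' @examples
#' ds <- augment_reverse(make_ddg_table(20, seed = 1))
#' sp <- pair_split(ds, 0.9, seed = 42)
#' length(unique(sp$train$pair_id))  # 18 of 20 pairs
#' @export
pair_split <- function(ds, train_fraction = 0.9, seed = 42) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  ids <- .pair_ids_checked(ds)
  shuffled <- withr::with_seed(seed, sample(ids))
  n_train <- ceiling(train_fraction * length(ids))
  train_ids <- shuffled[seq_len(n_train)]
  list(
    train = dplyr::filter(ds, .data$pair_id %in% train_ids),
    test = dplyr::filter(ds, !.data$pair_id %in% train_ids)
  )
}

#' Assign pairs to cross-validation folds
#'
#' Pair-level fold assignment: each direct/reverse pair lands wholly in one
#' of `k` folds, and fold sizes differ by at most one pair. Keeping the
#' augmented twin with its source record prevents leakage between training
#' and validation folds.
#'
#' @param ds Augmented DDG tibble.
#' @param k Number of folds (default 20).
#' @param seed Integer seed.
#' @return A tibble with columns `pair_id` and `fold`.
#' @export
make_pair_folds <- function(ds, k = 20, seed = 42) {
  ids <- .pair_ids_checked(ds)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(ids)) stop("k exceeds the number of pairs", call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(ids))
  fold <- rep(seq_len(k), length.out = length(shuffled))
  # rep() cycles 1..k so sizes differ by at most one
  tibble::tibble(pair_id = shuffled, fold = fold) |>
    dplyr::arrange(match(.data$pair_id, ids))
}

#' Write a DDG tibble to CSV
#'
#' Emits the input schema (`pdb_id, substitution, chain_id, ph,
#' temperature_c, ddg`) plus `origin` and `pair_id` when present.
#'
#' @param ds A DDG tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ddg_csv <- function(ds, file) {
  validate_ddg(ds)
  out <- tibble::tibble(
    pdb_id = ds$pdb_id,
    substitution = paste0(ds$wt_aa, ds$position, ds$mut_aa),
    chain_id = ds$chain_id,
    ph = ds$ph,
    temperature_c = ds$temperature_c,
    ddg = ds$ddg
  )
  if ("origin" %in% names(ds)) out$origin <- ds$origin
  if ("pair_id" %in% names(ds)) out$pair_id <- ds$pair_id
  readr::write_csv(out, file, progress = FALSE)
  invisible(file)
}
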