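# End-to-end orchestration: featurize -> select -> train -> predict ->
# evaluate, with every artifact written to disk alongside a manifest of
# seeds and versions, plus saturation-mutagenesis enumeration.

#' Run the full analysis pipeline
#'
#' Wires the modules into one flow and writes five artifacts into
#' `out_dir`: `features.csv` (+ `features_manifest.json`),
#' `rfe_trace.csv`, `model_card.json`, `predictions.csv` and
#' `evaluation.json`. Inputs are supplied either as a raw mutation CSV
#' plus a directory of PDB files (the featurize stage runs), or as a
#' ready feature table (featurization is skipped). Stages are resumable:
#' an existing `features.csv` is reused byte-identically when the config
#' is unchanged.
#'
#' @param config A named list:
#'   * `raw_csv`, `pdb_dir` (+ optional `pssm_dir`) for the featurize
#'     path, or `feature_table` (a `stab_features`/`stab_benchmark`
#'     object or tibble);
#'   * `out_dir` (required);
#'   * `k` folds (default 20), `seed` (default 42),
#'     `train_fraction` (default 0.9), `run_rfe` (default TRUE),
#'     `rfe_step` (default 1), `hyperparams` (default
#'     [default_hyperparams()]).
#' @return A list with the fitted model, the RFE result (or NULL), the
#'   held-out evaluation report, and the artifact paths.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  has_features <- !is.null(config$feature_table)
  if (!has_features) {
    if (is.null(config$raw_csv) || is.null(config$pdb_dir)) {
      stop("config must name either feature_table or raw_csv + pdb_dir",
           call. = FALSE)
    }
    if (!dir.exists(config$pdb_dir)) {
      stop("structure directory does not exist: ", config$pdb_dir, call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- config$k %||% 20
  seed <- config$seed %||% 42
  train_fraction <- config$train_fraction %||% 0.9
  hyperparams <- config$hyperparams %||% list()

  if (has_features) {
    feats <- config$feature_table
    if (inherits(feats, "stab_benchmark")) feats <- feats$table
    if (inherits(feats, "stab_features")) {
      manifest <- registry_manifest(feats$registry)
      feats <- feats$table
    } else {
      manifest <- NULL
    }
  } else {
    ds <- read_ddg_csv(config$raw_csv)
    if (!"origin" %in% names(ds)) ds <- augment_reverse(ds)
    pdb_files <- list.files(config$pdb_dir, pattern = "\\.pdb$",
                            full.names = TRUE)
    structures <- stats::setNames(
      lapply(pdb_files, read_pdb),
      toupper(sub("\\.pdb$", "", basename(pdb_files))))
    profiles <- NULL
    if (!is.null(config$pssm_dir)) {
      pssm_files <- list.files(config$pssm_dir, pattern = "\\.pssm$",
                               full.names = TRUE)
      profiles <- stats::setNames(
        lapply(pssm_files, parse_pssm_ascii),
        toupper(sub("\\.pssm$", "", basename(pssm_files))))
    }
    fset <- assemble_feature_table(ds, structures, profiles = profiles)
    manifest <- registry_manifest(fset$registry)
    feats <- fset$table
  }
  readr::write_csv(feats, file.path(out_dir, "features.csv"), progress = FALSE)
  jsonlite::write_json(
    list(seed = seed, k = k, train_fraction = train_fraction,
         n_records = nrow(feats),
         manifest = manifest,
         package_version = as.character(utils::packageVersion("stabshift"))),
    file.path(out_dir, "features_manifest.json"), auto_unbox = TRUE, digits = NA)

  split <- pair_split(feats, train_fraction = train_fraction, seed = seed)
  train_tbl <- split$train
  test_tbl <- split$test

  rfe <- NULL
  selected <- setdiff(names(feats),
                      c("record_id", "pair_id", "origin", "ddg"))
  if (config$run_rfe %||% TRUE) {
    rfe <- rfe_select(train_tbl, k = k, seed = seed,
                      hyperparams = hyperparams,
                      step = config$rfe_step %||% 1)
    selected <- rfe$selected
    readr::write_csv(rfe$trace, file.path(out_dir, "rfe_trace.csv"),
                     progress = FALSE)
  } else {
    readr::write_csv(tibble::tibble(round = integer(), n_features = integer(),
                                    mean_r2 = numeric(), sd_r2 = numeric(),
                                    removed = character()),
                     file.path(out_dir, "rfe_trace.csv"), progress = FALSE)
  }
  model <- train_regressor(train_tbl, features = selected,
                           hyperparams = hyperparams, seed = seed)
  jsonlite::write_json(
    list(features = model$features, hyperparams = model$hyperparams,
         seed = seed, importance = as.list(model$importance)),
    file.path(out_dir, "model_card.json"), auto_unbox = TRUE, digits = NA)

  preds <- tibble::tibble(
    record_id = test_tbl$record_id %||% seq_len(nrow(test_tbl)),
    pair_id = test_tbl$pair_id, origin = test_tbl$origin,
    ddg = test_tbl$ddg, pred = predict_ddg(model, test_tbl)
  )
  readr::write_csv(preds, file.path(out_dir, "predictions.csv"),
                   progress = FALSE)
  report <- evaluation_report(preds)
  jsonlite::write_json(as.list(report), file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  list(
    model = model, rfe = rfe, report = report, predictions = preds,
    paths = file.path(out_dir, c("features.csv", "rfe_trace.csv",
                                 "model_card.json", "predictions.csv",
                                 "evaluation.json"))
  )
}

#' Enumerate saturation mutagenesis
#'
#' Produces one raw mutation record per non-identity substitution: 19 per
#' site, for one site or every standard residue of a chain. Measuring
#' conditions are filled from the supplied defaults; non-standard
#' residues are skipped with a warning.
#'
#' @param struct A `protein_structure`.
#' @param chain Chain identifier.
#' @param position Optional author residue number; `NULL` enumerates all
#'   sites in the chain.
#' @param ph,temperature_c Condition defaults for the generated records.
#' @return A DDG tibble (with `ddg = NA`) ready for featurization.
#' @export
enumerate_saturation <- function(struct, chain, position = NULL,
                                 ph = 7, temperature_c = 25) {
  res <- structure_residues(struct)
  res <- res[res$chain == chain, ]
  if (!nrow(res)) stop("chain ", sQuote(chain), " not found", call. = FALSE)
  if (!is.null(position)) {
    res <- res[res$resno %in% position, ]
    if (!nrow(res)) stop("site ", position, " not found in chain ", chain,
                         call. = FALSE)
  }
  skip <- res$aa1 == "X"
  if (any(skip)) {
    warning("skipping non-standard residue(s): ",
            paste(res$res_key[skip], collapse = ", "), call. = FALSE)
    res <- res[!skip, ]
  }
  purrr::pmap_dfr(res[, c("resno", "icode", "aa1")], function(resno, icode, aa1) {
    tibble::tibble(
      pdb_id = struct$id, chain_id = chain, position = resno, icode = icode,
      wt_aa = aa1, mut_aa = setdiff(aa_alphabet(), aa1),
      ph = ph, temperature_c = temperature_c, ddg = NA_real_
    )
  })
}
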