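# Pair-level cross-validation, recursive feature elimination and the
# boosted-tree regression harness. The estimator interface is pluggable so
# any regressor can be run through identical folds; the default engine is
# a gradient-boosted tree with native missing-value handling.

#' Default gradient-boosted tree hyperparameters
#'
#' @return Named list of xgboost hyperparameters used throughout the
#'   package (single-threaded for determinism).
#' @export
default_hyperparams <- function() {
  list(nrounds = 300, eta = 0.08, max_depth = 5, subsample = 0.9,
       colsample_bytree = 0.9, min_child_weight = 3, reg_lambda = 1,
       reg_alpha = 0)
}

# estimator interface: list(fit(X, y, seed) -> model,
#                           predict(model, X) -> numeric,
#                           importance(model, feature_names) -> named numeric >= 0)
xgb_estimator <- function(hyperparams = default_hyperparams()) {
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  list(
    fit = function(X, y, seed = 1) {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(
          objective = "reg:squarederror", eta = hp$eta,
          max_depth = hp$max_depth, subsample = hp$subsample,
          colsample_bytree = hp$colsample_bytree,
          min_child_weight = hp$min_child_weight,
          lambda = hp$reg_lambda, alpha = hp$reg_alpha,
          nthread = 1, seed = seed
        ),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    },
    predict = function(model, X) {
      stats::predict(model, as.matrix(X))
    },
    importance = function(model, feature_names) {
      imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
      if (length(feature_names) == 1L) return(imp + 1)
      tab <- xgboost::xgb.importance(model = model)
      # Gain share is monotone in total gain, which is the ranking metric
      imp[tab$Feature] <- tab$Gain
      imp
    }
  )
}

# coerce a stab_features object or plain tibble to (X, y, pair_id)
.as_ml_table <- function(table) {
  if (inherits(table, "stab_features")) table <- table$table
  meta <- intersect(c("record_id", "pair_id", "origin", "ddg"), names(table))
  if (!"ddg" %in% meta) stop("feature table must carry a ddg label column",
                             call. = FALSE)
  if (!"pair_id" %in% meta) stop("feature table must carry pair_id", call. = FALSE)
  features <- setdiff(names(table), meta)
  list(X = as.data.frame(table[features]), y = table$ddg,
       pair_id = table$pair_id, features = features)
}

# fold assignment over pair ids; sizes differ by at most one pair
.pair_fold_assignment <- function(pair_id, k, seed) {
  ids <- unique(pair_id)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > length(ids)) stop("k exceeds the number of pairs", call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(ids))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)),
                             shuffled)
  unname(fold_of[pair_id])
}

#' Pair-level cross-validation
#'
#' Splits records into `k` folds by direct/reverse pair (pairs never
#' straddle folds), trains the estimator on `k - 1` folds and scores the
#' coefficient of determination `R^2 = 1 - SSE/SST` on the held-out fold.
#' Zero-variance validation labels are a degenerate case and raise an
#' error; folds with fewer than 2 pairs are rejected.
#'
#' @param table A `stab_features` object or tibble with `pair_id`, `ddg`
#'   and feature columns.
#' @param k Number of folds (default 20; desk-scale runs use 3-5).
#' @param seed Integer seed controlling fold assignment and model fits.
#' @param hyperparams Hyperparameter overrides for the default engine.
#' @param estimator Optional estimator interface (overrides
#'   `hyperparams`); see [xgb_estimator()].
#' @param features Optional feature subset (column names).
#' @return A list of class `stab_cv`: `fold_scores` tibble (`fold`,
#'   `r_squared`, `n_pairs`), `mean_r2`, `sd_r2`, `k`, `seed`, and
#'   `predictions` (out-of-fold, with `pair_id`, `origin` when present).
#' @export
crossval_pairlevel <- function(table, k = 20, seed = 42,
                               hyperparams = list(), estimator = NULL,
                               features = NULL) {
  ml <- .as_ml_table(table)
  est <- estimator %||% xgb_estimator(hyperparams)
  feats <- features %||% ml$features
  stopifnot(all(feats %in% ml$features))
  fold <- .pair_fold_assignment(ml$pair_id, k, seed)
  if (any(table(fold[!duplicated(ml$pair_id)]) < 2)) {
    stop("cross-validation folds with fewer than 2 pairs are rejected",
         call. = FALSE)
  }
  origin <- if (inherits(table, "stab_features")) table$table$origin
    else if ("origin" %in% names(table)) table$origin else rep(NA, length(ml$y))
  preds <- rep(NA_real_, length(ml$y))
  scores <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f; va <- fold == f
    y_va <- ml$y[va]
    if (stats::var(y_va) == 0) {
      stop("validation fold ", f, " has zero label variance; R^2 undefined",
           call. = FALSE)
    }
    model <- est$fit(ml$X[tr, feats, drop = FALSE], ml$y[tr], seed = seed + f)
    p <- est$predict(model, ml$X[va, feats, drop = FALSE])
    preds[va] <<- p
    tibble::tibble(fold = f,
                   r_squared = 1 - sum((p - y_va)^2) /
                     sum((y_va - mean(y_va))^2),
                   n_pairs = length(unique(ml$pair_id[va])))
  })
  structure(
    list(fold_scores = scores, mean_r2 = mean(scores$r_squared),
         sd_r2 = stats::sd(scores$r_squared), k = k, seed = seed,
         predictions = tibble::tibble(pair_id = ml$pair_id, origin = origin,
                                      ddg = ml$y, pred = preds),
         fold_assignment = tibble::tibble(pair_id = ml$pair_id, fold = fold)),
    class = "stab_cv"
  )
}

#' Recursive feature elimination with pair-level cross-validation
#'
#' Per round: cross-validate the current feature set, record the mean
#' `R^2`, fit on all rows, rank features by importance (total gain) and
#' remove exactly the least important one (ties broken by removing the
#' later registry column). The optimal subset is the remaining set at the
#' round with the highest mean `R^2` (ties: the later round, i.e. fewer
#' features). A `step` > 1 removes several features per round for speed
#' but defaults to 1.
#'
#' @inheritParams crossval_pairlevel
#' @param stop_size Stop when this many features remain (default 1).
#' @param step Features removed per round (default 1).
#' @return A list of class `stab_rfe`: `trace` tibble (`round`,
#'   `n_features`, `mean_r2`, `sd_r2`, `removed`), `selected` (character
#'   vector of the optimal subset), `best_round`.
#' @export
rfe_select <- function(table, k = 20, seed = 42, hyperparams = list(),
                       estimator = NULL, stop_size = 1, step = 1) {
  ml <- .as_ml_table(table)
  est <- estimator %||% xgb_estimator(hyperparams)
  current <- ml$features
  if (length(current) < 2) stop("need at least 2 features for RFE", call. = FALSE)
  trace <- list()
  subsets <- list()
  round <- 0L
  stop_size <- max(stop_size, 1)
  while (length(current) >= stop_size) {
    round <- round + 1L
    cv <- crossval_pairlevel(table, k = k, seed = seed, estimator = est,
                             features = current)
    removed <- character()
    if (length(current) > stop_size) {
      model <- est$fit(ml$X[, current, drop = FALSE], ml$y, seed = seed)
      imp <- est$importance(model, current)
      # ascending importance; ties broken by removing the later registry column
      ord <- order(imp, -match(current, ml$features))
      removed <- current[ord[seq_len(min(step, length(current) - stop_size))]]
    }
    trace[[round]] <- tibble::tibble(
      round = round, n_features = length(current),
      mean_r2 = cv$mean_r2, sd_r2 = cv$sd_r2,
      removed = paste(removed, collapse = ",")
    )
    subsets[[round]] <- current
    if (!length(removed)) break
    current <- setdiff(current, removed)
  }
  trace <- dplyr::bind_rows(trace)
  best_round <- max(which(trace$mean_r2 == max(trace$mean_r2)))
  structure(
    list(trace = trace, selected = subsets[[best_round]],
         best_round = best_round, k = k, seed = seed),
    class = "stab_rfe"
  )
}

#' Train the boosted-tree DDG regressor
#'
#' @inheritParams crossval_pairlevel
#' @param features Feature subset to train on (default: all).
#' @return A list of class `stab_model`: the fitted handle, `features`,
#'   `importance` (named, >= 0), `hyperparams`, `seed`.
#' @export
train_regressor <- function(table, features = NULL, hyperparams = list(),
                            seed = 42, estimator = NULL) {
  ml <- .as_ml_table(table)
  feats <- features %||% ml$features
  if (!length(feats)) stop("empty feature subset", call. = FALSE)
  stopifnot(all(feats %in% ml$features))
  if (length(ml$y) < 2) stop("need at least 2 rows to train", call. = FALSE)
  if (!is.numeric(ml$y)) stop("labels must be numeric", call. = FALSE)
  est <- estimator %||% xgb_estimator(hyperparams)
  model <- est$fit(ml$X[, feats, drop = FALSE], ml$y, seed = seed)
  structure(
    list(model = model, features = feats,
         importance = est$importance(model, feats),
         hyperparams = utils::modifyList(default_hyperparams(), hyperparams),
         seed = seed, estimator = est),
    class = "stab_model"
  )
}

#' Predict DDG for new rows
#'
#' Columns are aligned by name, so extra columns and column order are
#' irrelevant. In strict mode a missing model feature is an error;
#' otherwise it is supplied as masked `NA` (the tree engine handles
#' missingness natively).
#'
#' @param model A `stab_model`.
#' @param table A `stab_features` object or tibble containing the model's
#'   feature columns.
#' @param strict Error on missing feature columns (default TRUE).
#' @return Numeric vector of predicted DDG (kcal/mol), one per row.
#' @export
predict_ddg <- function(model, table, strict = TRUE) {
  if (inherits(table, "stab_features")) table <- table$table
  missing <- setdiff(model$features, names(table))
  if (length(missing) && strict) {
    stop("missing required feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.data.frame(table)[intersect(model$features, names(table))]
  for (m in missing) X[[m]] <- NA_real_
  X <- X[model$features]
  model$estimator$predict(model$model, X)
}

#' @export
predict.stab_model <- function(object, newdata, ...) {
  predict_ddg(object, newdata, ...)
}

#' Hyperparameter search over pair-level cross-validation
#'
#' Maximizes the mean pair-level cross-validated `R^2`. The default
#' strategy is seeded uniform random search over the declared space; a
#' custom `sampler(space, budget, seed)` hook (e.g. a Bayesian
#' optimizer) can supply the trial points instead. Every trial is logged.
#'
#' @inheritParams crossval_pairlevel
#' @param space Named list of parameter ranges: numeric `c(lo, hi)` for
#'   continuous, integer `c(lo, hi)` for integer parameters (detected by
#'   `is.integer` or whole-number bounds on `nrounds`/`max_depth`/
#'   `min_child_weight`), or an explicit vector of candidate values.
#' @param budget Number of trials (>= 1).
#' @param sampler Optional function returning a list of trial parameter
#'   lists.
#' @return A list of class `stab_tune`: `best` (hyperparameter list),
#'   `best_score`, and `log` tibble (one row per trial).
#' @export
tune_hyperparameters <- function(table, space, budget = 10, k = 20, seed = 42,
                                 sampler = NULL) {
  if (!length(space)) stop("empty search space", call. = FALSE)
  if (budget < 1) stop("budget must be >= 1", call. = FALSE)
  int_params <- c("nrounds", "max_depth", "min_child_weight")
  trials <- if (!is.null(sampler)) {
    sampler(space, budget, seed)
  } else {
    withr::with_seed(seed, lapply(seq_len(budget), function(i) {
      purrr::imap(space, function(rng, nm) {
        if (length(rng) == 2 && is.numeric(rng)) {
          v <- stats::runif(1, rng[1], rng[2])
          if (nm %in% int_params) round(v) else v
        } else {
          sample(rng, 1)
        }
      })
    }))
  }
  log <- purrr::imap_dfr(trials, function(hp, i) {
    cv <- crossval_pairlevel(table, k = k, seed = seed, hyperparams = hp)
    tibble::tibble(trial = i, mean_r2 = cv$mean_r2, sd_r2 = cv$sd_r2,
                   params = list(hp))
  })
  best_i <- which.max(log$mean_r2)
  structure(
    list(best = log$params[[best_i]], best_score = log$mean_r2[best_i],
         log = log, seed = seed),
    class = "stab_tune"
  )
}
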