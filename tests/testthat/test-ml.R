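# Cross-validation, recursive feature elimination, training, tuning and
# prediction.

# deterministic stub estimator: fixed per-feature importances, predicts the
# first available feature so validation R^2 is defined
stub_estimator <- function(importances) {
  list(
    fit = function(X, y, seed = 1) list(features = names(X)),
    predict = function(model, X) X[[1]],
    importance = function(model, feature_names) {
      importances[feature_names]
    }
  )
}

test_that("pair-level cross-validation never leaks pairs and is reproducible", {
  bm <- make_ddg_benchmark(60, 8, 3, 0.1, seed = 21)
  cv <- crossval_pairlevel(bm$table, k = 4, seed = 9,
                           hyperparams = list(nrounds = 40))
  fa <- cv$fold_assignment
  spans <- tapply(fa$fold, fa$pair_id, function(x) length(unique(x)))
  expect_true(all(spans == 1))
  expect_equal(nrow(cv$fold_scores), 4L)
  cv2 <- crossval_pairlevel(bm$table, k = 4, seed = 9,
                            hyperparams = list(nrounds = 40))
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$fold_scores, cv2$fold_scores)
})

test_that("a noiseless linear signal is recovered almost perfectly", {
  bm <- make_ddg_benchmark(150, 6, 3, 0, seed = 33)
  # least-squares estimator through the pluggable interface: the CV
  # harness itself must deliver near-perfect held-out R^2 here
  lm_est <- list(
    fit = function(X, y, seed = 1) stats::lm.fit(cbind(1, as.matrix(X)), y),
    predict = function(model, X) {
      as.numeric(cbind(1, as.matrix(X)) %*% model$coefficients)
    },
    importance = function(model, feature_names) {
      abs(model$coefficients[-1])[seq_along(feature_names)]
    }
  )
  cv <- crossval_pairlevel(bm$table, k = 3, seed = 5, estimator = lm_est)
  expect_gte(cv$mean_r2, 0.99)
  # the boosted default approximates the same signal closely
  cv_gb <- crossval_pairlevel(bm$table, k = 3, seed = 5)
  expect_gte(cv_gb$mean_r2, 0.85)
})

test_that("degenerate validation labels raise a descriptive error", {
  tbl <- tibble::tibble(
    record_id = sprintf("r%02d", 1:12),
    pair_id = rep(sprintf("p%02d", 1:6), each = 2),
    origin = rep(c("direct", "reverse"), 6),
    ddg = 1,  # constant labels: R^2 denominator is zero
    f1 = rnorm(12), f2 = rnorm(12)
  )
  expect_error(crossval_pairlevel(tbl, k = 3, seed = 1), "zero label variance")
  expect_error(crossval_pairlevel(tbl, k = 6, seed = 1), "fewer than 2 pairs")
})

test_that("RFE with a stub estimator reproduces the hand-traced removal order", {
  # labels equal f001 exactly; stub predicts f001, so every round scores
  # R^2 = 1 and removal follows the fixed importances: f004, f003, f002
  tbl <- withr::with_seed(77, tibble::tibble(
    record_id = sprintf("r%02d", 1:40),
    pair_id = rep(sprintf("p%02d", 1:20), each = 2),
    origin = rep(c("direct", "reverse"), 20),
    f001 = rnorm(40), f002 = rnorm(40), f003 = rnorm(40), f004 = rnorm(40)
  ))
  tbl$ddg <- tbl$f001
  est <- stub_estimator(c(f001 = 4, f002 = 3, f003 = 2, f004 = 1))
  rfe <- rfe_select(tbl, k = 4, seed = 2, estimator = est)
  expect_equal(rfe$trace$n_features, c(4L, 3L, 2L, 1L))
  expect_equal(rfe$trace$removed, c("f004", "f003", "f002", ""))
  expect_equal(rfe$trace$mean_r2, rep(1, 4))
  # all rounds tie at R^2 = 1: the later round (fewest features) wins
  expect_equal(rfe$selected, "f001")
})

test_that("RFE ties break by removing the later registry column", {
  tbl <- withr::with_seed(78, tibble::tibble(
    record_id = sprintf("r%02d", 1:20),
    pair_id = rep(sprintf("p%02d", 1:10), each = 2),
    origin = rep(c("direct", "reverse"), 10),
    f001 = rnorm(20), f002 = rnorm(20), f003 = rnorm(20)
  ))
  tbl$ddg <- tbl$f001
  est <- stub_estimator(c(f001 = 5, f002 = 1, f003 = 1))  # f002/f003 tied
  rfe <- rfe_select(tbl, k = 3, seed = 2, estimator = est)
  expect_equal(rfe$trace$removed[1], "f003")
})

test_that("the planted-signal benchmark importance ranks informative features first", {
  bm <- make_ddg_benchmark(200, 20, 5, 0.2, seed = 41)
  m <- train_regressor(bm$table, seed = 3)
  ranked <- names(sort(m$importance, decreasing = TRUE))
  expect_setequal(ranked[1:5], bm$informative)
  expect_true(all(m$importance >= 0))
  # capacity check: training-set predictions on a noiseless benchmark
  bm0 <- make_ddg_benchmark(150, 6, 3, 0, seed = 42)
  m0 <- train_regressor(bm0$table, seed = 3)
  p0 <- predict_ddg(m0, bm0$table)
  expect_gte(regression_metrics(p0, bm0$table$ddg)$r_squared, 0.99)
})

test_that("training and prediction are deterministic and name-aligned", {
  bm <- make_ddg_benchmark(50, 6, 2, 0.1, seed = 51)
  m1 <- train_regressor(bm$table, seed = 12, hyperparams = list(nrounds = 60))
  m2 <- train_regressor(bm$table, seed = 12, hyperparams = list(nrounds = 60))
  expect_identical(predict_ddg(m1, bm$table), predict_ddg(m2, bm$table))
  # duplicated rows get identical predictions
  dup <- bm$table[c(1, 1, 2), ]
  pd <- predict_ddg(m1, dup)
  expect_equal(pd[1], pd[2])
  # column order permutation does not change predictions
  shuffled <- bm$table[, c(1:4, rev(5:10))]
  expect_equal(predict_ddg(m1, shuffled), predict_ddg(m1, bm$table))
  # strict mode errors on missing features
  expect_error(predict_ddg(m1, bm$table[, -5]), "missing required feature")
  expect_error(train_regressor(bm$table, features = character()), "empty")
})

test_that("hyperparameter search logs every trial and returns the maximum", {
  bm <- make_ddg_benchmark(40, 5, 2, 0.1, seed = 61)
  space <- list(nrounds = c(20, 40), max_depth = c(2, 4))
  one <- tune_hyperparameters(bm$table, space, budget = 1, k = 3, seed = 8)
  expect_equal(nrow(one$log), 1L)
  expect_equal(one$best_score, one$log$mean_r2[1])

  three <- tune_hyperparameters(bm$table, space, budget = 3, k = 3, seed = 8)
  expect_equal(three$best_score, max(three$log$mean_r2))
  # seeded search is reproducible trial-for-trial
  three2 <- tune_hyperparameters(bm$table, space, budget = 3, k = 3, seed = 8)
  expect_identical(tidy(three), tidy(three2))
  expect_error(tune_hyperparameters(bm$table, list(), budget = 1), "empty")
  expect_error(tune_hyperparameters(bm$table, space, budget = 0), "budget")
})

test_that("tidiers expose fold scores, traces and importances", {
  bm <- make_ddg_benchmark(40, 5, 2, 0.1, seed = 71)
  cv <- crossval_pairlevel(bm$table, k = 3, seed = 2,
                           hyperparams = list(nrounds = 30))
  expect_named(tidy(cv), c("fold", "r_squared", "n_pairs"))
  expect_equal(glance(cv)$mean_r2, cv$mean_r2)
  m <- train_regressor(bm$table, seed = 2, hyperparams = list(nrounds = 30))
  td <- tidy(m)
  expect_equal(td$feature[1], names(sort(m$importance, decreasing = TRUE))[1])
})
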