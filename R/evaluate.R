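# The evaluation suite: regression metrics (Pearson gamma, RMSE sigma,
# coefficient of determination R^2), antisymmetry metrics over
# direct/reverse pairs (gamma_dir_rev, delta), the biased maximum mean
# discrepancy statistic under an RBF kernel, Steiger's Z for dependent
# correlations, and equal-count binned calibration.

#' Regression metrics: Pearson correlation, RMSE, R-squared
#'
#' Exact formula implementations: `gamma` is the Pearson correlation
#' between predictions and truth, `sigma = sqrt(mean((pred - truth)^2))`,
#' and `r_squared = 1 - SSE/SST` (which may be negative; it is not a
#' squared correlation).
#'
#' @param pred,truth Equal-length numeric vectors (n >= 2).
#' @return A tibble with one row: `gamma`, `sigma`, `r_squared`, `n`.
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  n <- length(pred)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) stop("zero-variance truth: gamma and R^2 undefined", call. = FALSE)
  dx <- pred - mean(pred); dy <- truth - mean(truth)
  gamma <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  tibble::tibble(
    gamma = gamma,
    sigma = sqrt(mean((pred - truth)^2)),
    r_squared = 1 - sum((pred - truth)^2) / sst,
    n = n
  )
}

#' Antisymmetry metrics over direct/reverse pairs
#'
#' `gamma_dir_rev` is the Pearson correlation between the paired direct
#' and reverse predictions; `delta` is the mean of the per-pair sums. An
#' ideal antisymmetric predictor gives exactly (-1, 0).
#'
#' @param pred_dir,pred_rev Aligned numeric vectors, one per pair member.
#' @return A tibble with one row: `gamma_dir_rev`, `delta`, `n_pairs`.
#' @export
antisymmetry_metrics <- function(pred_dir, pred_rev) {
  if (length(pred_dir) != length(pred_rev)) {
    stop("unpaired entries: direct and reverse predictions differ in length",
         call. = FALSE)
  }
  dd <- pred_dir - mean(pred_dir); dr <- pred_rev - mean(pred_rev)
  denom <- sqrt(sum(dd^2) * sum(dr^2))
  tibble::tibble(
    gamma_dir_rev = if (denom == 0) NA_real_ else sum(dd * dr) / denom,
    delta = mean(pred_dir + pred_rev),
    n_pairs = length(pred_dir)
  )
}

#' Squared maximum mean discrepancy (biased, RBF kernel)
#'
#' The biased V-statistic including diagonal terms:
#' `MMD^2 = mean(k(x_i, x_j)) + mean(k(y_i, y_j)) - 2 mean(k(x_i, y_j))`
#' with the RBF kernel `k(a, b) = exp(-bandwidth * ||a - b||^2)`. The
#' bandwidth parameter defaults to `1/ncol(X)`. Identical samples give
#' exactly 0; the statistic is non-negative and symmetric in its
#' arguments.
#'
#' @param X,Y Sample matrices (rows = observations) of equal
#'   dimensionality; vectors are treated as 1-column matrices.
#' @param bandwidth RBF kernel coefficient (default `1/ncol(X)`).
#' @return A tibble with one row: `mmd2`, `bandwidth`, `m`, `n`.
#' @export
mmd2_rbf <- function(X, Y, bandwidth = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch", call. = FALSE)
  bandwidth <- bandwidth %||% (1 / ncol(X))
  sq <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  }
  kxx <- exp(-bandwidth * pmax(sq(X, X), 0))
  kyy <- exp(-bandwidth * pmax(sq(Y, Y), 0))
  kxy <- exp(-bandwidth * pmax(sq(X, Y), 0))
  tibble::tibble(
    mmd2 = mean(kxx) + mean(kyy) - 2 * mean(kxy),
    bandwidth = bandwidth, m = nrow(X), n = nrow(Y)
  )
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether `r1y` and `r2y` (both against the same target variable)
#' differ, given the correlation `r12` between the two predictors.
#' Implements the Fisher-z based Steiger (1980) statistic with the
#' Dunn-Clark covariance evaluated at the average correlation. The
#' reported p is one-tailed (upper): `p = 0.5` at `z = 0`, strictly
#' decreasing in z, and swapping `r1y` and `r2y` negates z.
#'
#' @param r1y,r2y Correlations of each predictor with the target, in
#'   (-1, 1).
#' @param r12 Correlation between the two predictors, in (-1, 1).
#' @param n Sample size (> 3).
#' @return A tibble with one row: `z`, `p`, `r1y`, `r2y`, `r12`, `n`.
#' @export
steiger_z <- function(r1y, r2y, r12, n) {
  if (any(abs(c(r1y, r2y, r12)) >= 1)) {
    stop("correlations must lie strictly within (-1, 1)", call. = FALSE)
  }
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  rm2 <- ((r1y + r2y) / 2)^2
  cov_term <- (r12 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r12^2)) /
    (1 - rm2)^2
  z1 <- atanh(r1y); z2 <- atanh(r2y)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  tibble::tibble(z = z, p = stats::pnorm(z, lower.tail = FALSE),
                 r1y = r1y, r2y = r2y, r12 = r12, n = n)
}

#' Equal-count binned calibration
#'
#' Sorts observations by truth and splits them into `bins` bins of equal
#' count (any remainder spread one-per-bin over the leading bins),
#' reporting per bin the mean prediction, mean truth, and the standard
#' error of the residuals `pred - truth`.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @param bins Number of bins (default 10); must satisfy
#'   `1 <= bins <= n`.
#' @return A tibble with `bin`, `n`, `mean_pred`, `mean_truth`,
#'   `se_residual`.
#' @export
binned_calibration <- function(pred, truth, bins = 10) {
  n <- length(truth)
  if (length(pred) != n) stop("length mismatch", call. = FALSE)
  if (bins < 1 || bins > n) stop("bins must lie in [1, n]", call. = FALSE)
  ord <- order(truth)
  base <- n %/% bins
  sizes <- rep(base, bins) + c(rep(1, n %% bins), rep(0, bins - n %% bins))
  bin <- rep(seq_len(bins), times = sizes)
  tibble::tibble(pred = pred[ord], truth = truth[ord], bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pred = mean(.data$pred),
      mean_truth = mean(.data$truth),
      se_residual = {
        r <- .data$pred - .data$truth
        if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
      },
      .groups = "drop"
    )
}

#' Full evaluation report for paired predictions
#'
#' Computes the eight comparison metrics over a paired prediction table:
#' Pearson correlation and RMSE for all rows, direct rows and reverse
#' rows; `gamma_dir_rev` and `delta` over the pairs; plus `r_squared`
#' over all rows.
#'
#' @param predictions A tibble with columns `pair_id`, `origin`
#'   (`direct`/`reverse`), `ddg` (truth) and `pred`.
#' @return A one-row tibble of class `stab_eval`: `gamma_all`,
#'   `gamma_dir`, `gamma_rev`, `sigma_all`, `sigma_dir`, `sigma_rev`,
#'   `r_squared`, `gamma_dir_rev`, `delta`, `n`, `n_pairs`.
#' @export
evaluation_report <- function(predictions) {
  need <- c("pair_id", "origin", "ddg", "pred")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  all_m <- regression_metrics(predictions$pred, predictions$ddg)
  dirs <- predictions[predictions$origin == "direct", ]
  revs <- predictions[predictions$origin == "reverse", ]
  dir_m <- regression_metrics(dirs$pred, dirs$ddg)
  rev_m <- regression_metrics(revs$pred, revs$ddg)
  revs_aligned <- revs[match(dirs$pair_id, revs$pair_id), ]
  if (anyNA(revs_aligned$pred)) stop("unpaired entries in predictions",
                                     call. = FALSE)
  anti <- antisymmetry_metrics(dirs$pred, revs_aligned$pred)
  out <- tibble::tibble(
    gamma_all = all_m$gamma, gamma_dir = dir_m$gamma, gamma_rev = rev_m$gamma,
    sigma_all = all_m$sigma, sigma_dir = dir_m$sigma, sigma_rev = rev_m$sigma,
    r_squared = all_m$r_squared,
    gamma_dir_rev = anti$gamma_dir_rev, delta = anti$delta,
    n = all_m$n, n_pairs = anti$n_pairs
  )
  class(out) <- c("stab_eval", class(out))
  out
}
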