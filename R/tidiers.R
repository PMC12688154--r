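# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `stab_cv` object.
#' @param ... Ignored.
#' @return One row per fold: `fold`, `r_squared`, `n_pairs`.
#' @method tidy stab_cv
#' @export
tidy.stab_cv <- function(x, ...) x$fold_scores

#' @rdname tidy.stab_cv
#' @method glance stab_cv
#' @export
glance.stab_cv <- function(x, ...) {
  tibble::tibble(mean_r2 = x$mean_r2, sd_r2 = x$sd_r2, k = x$k, seed = x$seed)
}

#' Tidy an RFE result
#'
#' @param x A `stab_rfe` object.
#' @param ... Ignored.
#' @return The round-by-round trace tibble.
#' @method tidy stab_rfe
#' @export
tidy.stab_rfe <- function(x, ...) x$trace

#' @rdname tidy.stab_rfe
#' @method glance stab_rfe
#' @export
glance.stab_rfe <- function(x, ...) {
  tibble::tibble(
    best_round = x$best_round,
    n_selected = length(x$selected),
    best_mean_r2 = x$trace$mean_r2[x$best_round],
    k = x$k, seed = x$seed
  )
}

#' Tidy a trained regressor
#'
#' @param x A `stab_model` object.
#' @param ... Ignored.
#' @return One row per feature with its importance, descending.
#' @method tidy stab_model
#' @export
tidy.stab_model <- function(x, ...) {
  tibble::tibble(feature = names(x$importance),
                 importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.stab_model
#' @method glance stab_model
#' @export
glance.stab_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), seed = x$seed)
}

#' Tidy a tuning result
#'
#' @param x A `stab_tune` object.
#' @param ... Ignored.
#' @return The trial log with unnested parameters.
#' @method tidy stab_tune
#' @export
tidy.stab_tune <- function(x, ...) {
  x$log |>
    dplyr::mutate(params = purrr::map(.data$params, tibble::as_tibble)) |>
    tidyr::unnest("params")
}

#' @rdname tidy.stab_tune
#' @method glance stab_tune
#' @export
glance.stab_tune <- function(x, ...) {
  tibble::tibble(best_score = x$best_score, n_trials = nrow(x$log),
                 seed = x$seed)
}

#' Long-format evaluation report
#'
#' @param x A `stab_eval` report.
#' @param ... Ignored.
#' @return One row per metric: `metric`, `value`.
#' @method tidy stab_eval
#' @export
tidy.stab_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
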