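# Tidiers for fitted objects.

#' Tidy a trained COSTAR model
#'
#' One row per selected secondary target gene with its coefficient on
#' the original connectivity scale (the intercept is reported by
#' [glance.costar_model()]).
#'
#' @param x A `costar_model`.
#' @param ... Unused.
#' @return Tibble: term, estimate.
#' @export
tidy.costar_model <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta)) |>
    dplyr::arrange(dplyr::desc(abs(.data$estimate)))
}

#' One-row summary of a trained COSTAR model
#'
#' @param x A `costar_model`.
#' @param ... Unused.
#' @return Tibble: intercept, lambda, n_selected, n_features, n_obs,
#'   k_folds, cv_deviance.
#' @export
glance.costar_model <- function(x, ...) {
  tibble::tibble(
    intercept = x$beta0, lambda = x$lambda,
    n_selected = length(x$beta), n_features = length(x$feature_names),
    n_obs = x$n_obs, k_folds = x$k,
    cv_deviance = min(x$cv$path$mean_deviance))
}

#' Tidy a cross-validation path
#'
#' @param x A `costar_cv`.
#' @param ... Unused.
#' @return The per-lambda path tibble (lambda, mean_deviance,
#'   se_deviance, n_nonzero).
#' @export
tidy.costar_cv <- function(x, ...) x$path

#' Tidy classification diagnostics
#'
#' @param x A `costar_eval`.
#' @param ... Unused.
#' @return The confusion tibble (truth, predicted, n).
#' @export
tidy.costar_eval <- function(x, ...) x$confusion

#' @rdname tidy.costar_eval
#' @return `glance()` returns a one-row tibble: accuracy, auc,
#'   threshold.
#' @export
glance.costar_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc, threshold = x$threshold)
}
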