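# Model serialization: schema-versioned JSON round trip.

#' Write a trained COSTAR model to JSON
#'
#' Serializes intercept, sparse coefficients, selected lambda, the
#' cross-validation path, fold assignment, standardization info and the
#' feature-order hash; [read_costar_model()] restores an object whose
#' predictions reproduce the original bit-for-bit.
#'
#' @param model A `costar_model`.
#' @param path Output JSON path.
#' @export
write_costar_model <- function(model, path) {
  stopifnot(inherits(model, "costar_model"))
  obj <- list(
    schema = "neurocostar-model-1",
    beta0 = model$beta0,
    beta_names = names(model$beta),
    beta = unname(model$beta),
    lambda = model$lambda,
    lambda_path = model$cv$path$lambda,
    mean_deviance = model$cv$path$mean_deviance,
    se_deviance = model$cv$path$se_deviance,
    n_nonzero = model$cv$path$n_nonzero,
    folds = model$cv$folds,
    k = model$k, seed = model$seed, n_obs = model$n_obs,
    feature_names = model$feature_names,
    feature_hash = model$feature_hash,
    center = unname(model$center), scale = unname(model$scale),
    standardize = model$standardize,
    ppi_threshold = model$ppi_threshold, mode = model$mode)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_costar_model
#' @return `read_costar_model()` returns the `costar_model`.
#' @export
read_costar_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "neurocostar-model-1")) {
    abort("unrecognised model schema")
  }
  cv <- structure(
    list(path = tibble::tibble(lambda = obj$lambda_path,
                               mean_deviance = obj$mean_deviance,
                               se_deviance = obj$se_deviance,
                               n_nonzero = obj$n_nonzero),
         lambda_min = obj$lambda, folds = obj$folds, k = obj$k,
         seed = obj$seed, full_fit = NULL),
    class = "costar_cv")
  structure(
    list(beta0 = obj$beta0,
         beta = setNames(as.numeric(obj$beta), as.character(unlist(obj$beta_names))),
         lambda = obj$lambda, cv = cv,
         feature_names = obj$feature_names,
         feature_hash = obj$feature_hash,
         center = setNames(as.numeric(obj$center), as.character(unlist(obj$beta_names))),
         scale = setNames(as.numeric(obj$scale), as.character(unlist(obj$beta_names))),
         standardize = obj$standardize, k = obj$k, seed = obj$seed,
         n_obs = obj$n_obs, ppi_threshold = obj$ppi_threshold,
         mode = obj$mode),
    class = "costar_model")
}
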