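# Cross-validated lambda selection and the trained COSTAR model object.

#' Cross-validated selection of the regularization penalty
#'
#' k-fold cross-validation over a descending lambda grid; for every
#' lambda the mean held-out binomial deviance (and its standard error
#' across folds) is recorded, and the selected lambda is the strict
#' minimiser of the mean deviance (no one-standard-error rule).  Folds
#' are stratified by class by default: with few positives, unstratified
#' 20-fold splits can produce positive-free folds, which the binomial
#' deviance cannot score.
#'
#' @param X Feature matrix.
#' @param y Binary response (0/1).
#' @param k Number of folds; reduced with a warning when a class has
#'   fewer members than `k` under stratification.
#' @param grid Lambda grid (defaults to [lambda_grid()]).
#' @param seed Integer seed for the fold assignment.
#' @param stratified Stratify folds by class.
#' @param standardize,tol,max_iter Passed to
#'   [fit_penalized_logistic()].
#' @return A `costar_cv`: list with `path` (tibble: lambda,
#'   mean_deviance, se_deviance, n_nonzero), `lambda_min`, `folds`,
#'   `k`, `seed`, and `heldout_eta` (n x lambda matrix of held-out
#'   linear predictors, the basis for cross-validated accuracy).
#' @export
cv_select_lambda <- function(X, y, k = 20, grid = NULL, seed = 1L,
                             stratified = TRUE, standardize = TRUE,
                             tol = 1e-7, max_iter = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (k > n) abort("`k` must not exceed the number of observations")
  if (is.null(grid)) grid <- lambda_grid(X, y, standardize = standardize)
  if (stratified) {
    min_class <- min(table(y))
    if (min_class < k) {
      warn(sprintf("smallest class has %d members; reducing k from %d to %d",
                   min_class, k, min_class))
      k <- min_class
    }
  }
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }

  dev <- matrix(NA_real_, nrow = k, ncol = length(grid))
  heldout_eta <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (f in seq_len(k)) {
    hold <- folds == f
    y_tr <- y[!hold]
    if (length(unique(y_tr)) < 2) {
      abort(sprintf("fold %d leaves a single-class training set; use stratified folds", f))
    }
    fit <- fit_penalized_logistic(X[!hold, , drop = FALSE], y_tr, grid,
                                  standardize = standardize,
                                  tol = tol, max_iter = max_iter,
                                  on_nonconvergence = "silent")
    eta <- cbind(1, X[hold, , drop = FALSE]) %*% rbind(fit$beta0, fit$beta)
    heldout_eta[hold, ] <- eta
    for (l in seq_along(grid)) {
      dev[f, l] <- binomial_deviance(y[hold], sigmoid(eta[, l]))
    }
  }
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2, sd) / sqrt(k)
  full <- fit_penalized_logistic(X, y, grid, standardize = standardize,
                                 tol = tol, max_iter = max_iter,
                                 on_nonconvergence = "silent")
  path <- tibble::tibble(
    lambda = grid, mean_deviance = mean_dev, se_deviance = se_dev,
    n_nonzero = colSums(full$beta != 0))
  structure(
    list(path = path, lambda_min = grid[which.min(mean_dev)],
         folds = folds, k = k, seed = seed, full_fit = full,
         heldout_eta = heldout_eta),
    class = "costar_cv")
}

#' Train a COSTAR model on a constellation
#'
#' Learns the minimal drug-target connectivity signature that
#' discriminates screening hits from negatives: 20-fold cross-validated
#' L1-penalized (LASSO) logistic regression on the drug x STG
#' integrated-connectivity matrix, with the penalty chosen at minimum
#' cross-validated binomial deviance over a 60-value geometric grid.
#'
#' @param constellation A `constellation` (or a plain feature matrix
#'   with column names).
#' @param labels Tibble (compound_id, hit) or a named/plain 0-1 vector
#'   aligned to the matrix rows.
#' @param k Cross-validation folds.
#' @param n_lambda,lambda_min_ratio Grid shape (see [lambda_grid()]).
#' @param seed Fold-assignment seed.
#' @param standardize Standardize features before penalization.
#' @param tol,max_iter Optimizer controls.
#' @return A `costar_model`: intercept, sparse named coefficient vector
#'   (original scale), selected lambda, the `costar_cv` path, fold
#'   assignment, standardization info and a feature-order hash.
#' @export
costar_train <- function(constellation, labels, k = 20, n_lambda = 60,
                         lambda_min_ratio = 1e-4, seed = 1L,
                         standardize = TRUE, tol = 1e-7, max_iter = 500) {
  X <- if (inherits(constellation, "constellation")) constellation$X else constellation
  X <- as.matrix(X)
  if (is.data.frame(labels)) {
    y <- labels$hit[match(rownames(X), labels$compound_id)]
    if (anyNA(y)) abort("labels missing for some drugs in the feature matrix")
  } else {
    y <- as.numeric(labels)
  }
  if (min(table(y)) < 2) abort("need at least 2 drugs per class")
  grid <- lambda_grid(X, y, n = n_lambda, ratio = lambda_min_ratio,
                      standardize = standardize)
  cv <- cv_select_lambda(X, y, k = k, grid = grid, seed = seed,
                         stratified = TRUE, standardize = standardize,
                         tol = tol, max_iter = max_iter)
  l_idx <- which(cv$full_fit$lambda == cv$lambda_min)[1]
  if (!cv$full_fit$converged[l_idx]) {
    warn("the fit at the selected lambda is iteration-capped; consider raising max_iter")
  }
  beta <- cv$full_fit$beta[, l_idx]
  nz <- beta != 0
  structure(
    list(beta0 = unname(cv$full_fit$beta0[l_idx]),
         beta = beta[nz],
         lambda = cv$lambda_min,
         cv = cv,
         feature_names = colnames(X),
         feature_hash = feature_hash(colnames(X)),
         center = cv$full_fit$center[nz],
         scale = cv$full_fit$scale[nz],
         standardize = standardize,
         k = cv$k, seed = seed, n_obs = nrow(X),
         ppi_threshold = if (inherits(constellation, "constellation"))
           constellation$ppi_threshold else NA_real_,
         mode = if (inherits(constellation, "constellation"))
           constellation$mode else NA_character_),
    class = "costar_model")
}

#' @export
print.costar_model <- function(x, ...) {
  cat(sprintf(
    "<costar_model> %d selected STGs of %d features; lambda = %.4g (%d-fold CV, n = %d)\n",
    length(x$beta), length(x$feature_names), x$lambda, x$k, x$n_obs))
  invisible(x)
}
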