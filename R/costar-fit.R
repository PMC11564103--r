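# L1-penalized logistic regression: grids, single fits, KKT checks.

#' Geometric regularization grid for the penalized logistic model
#'
#' `lambda_max = max_j |x_j' (y - ybar)| / n` on the (optionally
#' standardized) features is the smallest penalty at which the null
#' model is stationary; the grid descends geometrically over `n` values
#' down to `ratio * lambda_max`.
#'
#' @param X Feature matrix (drugs x STGs); dense or sparse.
#' @param y Binary response vector (0/1).
#' @param n Number of grid values.
#' @param ratio Ratio of smallest to largest lambda.
#' @param standardize Compute the grid on centered/scaled columns,
#'   matching [fit_penalized_logistic()]'s default.
#' @return Strictly decreasing numeric vector of length `n`.
#' @export
lambda_grid <- function(X, y, n = 60, ratio = 1e-4, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("degenerate labels: y is constant")
  if (standardize) X <- .standardize(X)$X
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  exp(seq(log(lam_max), log(lam_max * ratio), length.out = n))
}

# Center and scale columns with population (1/n) standard deviations,
# the convention under which lambda_max has its closed form.  Constant
# columns get scale 1 (they stay zero after centering).
.standardize <- function(X) {
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  scale[scale == 0] <- 1
  list(X = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

#' Fit the L1-penalized logistic model at fixed penalties
#'
#' Minimises `(1/n) sum_i [log(1 + exp(eta_i)) - y_i eta_i] +
#' lambda * ||beta||_1` with an unpenalized intercept, by cyclic
#' coordinate descent on the IRLS quadratic approximation.  With
#' `standardize = TRUE` columns are centered/scaled internally and
#' coefficients are returned on the original scale (the penalty applies
#' on the standardized scale).  Fits a whole descending `lambda` path
#' with warm starts.
#'
#' @param X Feature matrix.
#' @param y Binary response (0/1).
#' @param lambda Penalty (scalar or descending vector).
#' @param standardize Standardize columns before penalization.
#' @param tol Convergence tolerance (coordinate updates and IRLS drift).
#' @param max_iter Iteration cap per loop level.
#' @param on_nonconvergence `"error"` (default), `"warn"` or
#'   `"silent"`; cross-validation uses `"silent"` internally, where a
#'   capped fit at an extreme penalty only perturbs one held-out
#'   deviance value.
#' @return A `costar_fit`: list with `lambda`, `beta0`, `beta` (matrix,
#'   features x lambdas, original scale), standardization info and
#'   convergence flags.
#' @export
fit_penalized_logistic <- function(X, y, lambda, standardize = TRUE,
                                   tol = 1e-8, max_iter = 500,
                                   on_nonconvergence = c("error", "warn", "silent")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("rows of X must match length of y")
  if (any(!is.finite(X)) || any(!is.finite(y))) abort("non-finite entries in X or y")
  if (any(lambda < 0)) abort("`lambda` must be >= 0")
  if (length(unique(y)) < 2) abort("degenerate labels: y is constant")
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  std <- if (standardize) .standardize(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  fit <- .cd_lasso_path(std$X, y, lambda, tol, max_iter)
  fit$beta0 <- as.numeric(fit$beta0)
  if (!all(fit$converged)) {
    msg <- sprintf("coordinate descent did not converge for %d of %d lambda values (max_iter = %d, smallest affected lambda = %.3g)",
                   sum(!fit$converged), length(lambda), max_iter,
                   min(lambda[!fit$converged]))
    switch(on_nonconvergence, error = abort(msg), warn = warn(msg), silent = NULL)
  }
  beta_std <- fit$beta
  beta <- beta_std / std$scale
  beta0 <- fit$beta0 - colSums(beta_std * (std$center / std$scale))
  rownames(beta) <- colnames(X)
  structure(
    list(lambda = lambda, beta0 = beta0, beta = beta,
         beta_std = beta_std, beta0_std = fit$beta0,
         center = std$center, scale = std$scale,
         standardize = standardize, feature_names = colnames(X),
         converged = as.logical(fit$converged)),
    class = "costar_fit")
}

#' KKT stationarity residual of a penalized logistic fit
#'
#' For the objective of [fit_penalized_logistic()] at a solution, the
#' gradient `g = X'(mu - y)/n` (standardized scale) must satisfy
#' `|g_j| <= lambda` where `beta_j = 0` and `g_j = -sign(beta_j) *
#' lambda` otherwise, and the intercept gradient must vanish.  Returns
#' the largest violation.
#'
#' @param fit A `costar_fit`.
#' @param X,y The training data the fit was produced from.
#' @param which Index into the lambda path (default: all).
#' @return Numeric vector of maximal KKT residuals, one per checked
#'   lambda.
#' @export
kkt_residual <- function(fit, X, y, which = seq_along(fit$lambda)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  n <- nrow(X)
  vapply(which, function(l) {
    eta <- fit$beta0_std[l] + Xs %*% fit$beta_std[, l]
    mu <- sigmoid(eta)
    g <- crossprod(Xs, mu - y) / n
    b <- fit$beta_std[, l]
    lam <- fit$lambda[l]
    viol_zero <- pmax(abs(g[b == 0]) - lam, 0)
    viol_act <- abs(g[b != 0] + sign(b[b != 0]) * lam)
    max(abs(mean(mu - y)), viol_zero, viol_act, 0)
  }, numeric(1))
}

# Mean binomial deviance of predicted probabilities, -2/n * loglik.
binomial_deviance <- function(y, mu) {
  eps <- 1e-10
  mu <- pmin(pmax(mu, eps), 1 - eps)
  -2 * mean(y * log(mu) + (1 - y) * log(1 - mu))
}
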