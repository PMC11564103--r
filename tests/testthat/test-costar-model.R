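# Penalized logistic fitting, cross-validation, prediction,
# diagnostics, screening.

random_instance <- function(seed, n = 20, p = 10) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  list(X = X, y = y)
}

test_that("lambda grid is geometric and lambda_max gives the null model", {
  inst <- random_instance(1)
  g <- lambda_grid(inst$X, inst$y, n = 60, ratio = 1e-4)
  ratios <- g[-1] / g[-60]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  expect_equal(g[60] / g[1], 1e-4, tolerance = 1e-10)
  # at lambda_max the KKT condition holds at the null model exactly
  f <- fit_penalized_logistic(inst$X, inst$y, g[1], tol = 1e-10)
  expect_true(all(f$beta == 0))
  expect_equal(f$beta0[1], qlogis(mean(inst$y)), tolerance = 1e-8)
  # single feature proportional to y - ybar: lambda_max is its
  # absolute covariance / n
  yc <- inst$y - mean(inst$y)
  X1 <- matrix(2 * yc, ncol = 1)
  expect_equal(lambda_grid(X1, inst$y, standardize = FALSE)[1],
               abs(sum(2 * yc * yc)) / length(yc))
  expect_error(lambda_grid(inst$X, rep(1, 20)), "degenerate labels")
})

test_that("fits satisfy KKT and match the proximal-gradient oracle", {
  worst_coef <- 0
  worst_kkt <- 0
  for (seed in 1:20) {
    inst <- random_instance(seed)
    lam <- 0.1 * lambda_grid(inst$X, inst$y, standardize = FALSE)[1]
    f <- fit_penalized_logistic(inst$X, inst$y, lam, standardize = FALSE,
                                tol = 1e-9)
    o <- oracle_prox_logistic(inst$X, inst$y, lam)
    worst_coef <- max(worst_coef,
                      max(abs(c(f$beta0[1] - o$beta0, f$beta[, 1] - o$beta))))
    worst_kkt <- max(worst_kkt, kkt_residual(f, inst$X, inst$y))
  }
  expect_lt(worst_coef, 1e-4)
  expect_lt(worst_kkt, 1e-6)
})

test_that("L1 norm is non-increasing along the penalty path", {
  inst <- random_instance(3, n = 60, p = 15)
  g <- lambda_grid(inst$X, inst$y)
  f <- fit_penalized_logistic(inst$X, inst$y, g, tol = 1e-8,
                              on_nonconvergence = "silent")
  l1 <- colSums(abs(f$beta_std))
  expect_true(all(diff(l1) > -1e-6))
})

test_that("duplicating a feature column never raises the optimum", {
  inst <- random_instance(5)
  lam <- 0.2 * lambda_grid(inst$X, inst$y, standardize = FALSE)[1]
  obj <- function(X, fit) {
    eta <- fit$beta0[1] + X %*% fit$beta[, 1]
    mean(log1p(exp(eta)) - inst$y * eta) + lam * sum(abs(fit$beta[, 1]))
  }
  f1 <- fit_penalized_logistic(inst$X, inst$y, lam, standardize = FALSE,
                               tol = 1e-10)
  Xd <- cbind(inst$X, dup = inst$X[, 1])
  f2 <- fit_penalized_logistic(Xd, inst$y, lam, standardize = FALSE,
                               tol = 1e-10)
  expect_lte(obj(Xd, f2), obj(inst$X, f1) + 1e-8)
})

test_that("cross-validation selects the signal and is reproducible", {
  # one perfectly predictive binary feature among noise
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 127
    y <- rbinom(n, 1, 30 / 127)
    if (sum(y) < 20) y[sample(which(y == 0), 20 - sum(y))] <- 1
    X <- cbind(signal = y, matrix(rnorm(n * 12), n,
                                  dimnames = list(NULL, sprintf("n%02d", 1:12))))
    cv <- cv_select_lambda(X, y, k = 20, seed = seed)
    idx <- which(cv$path$lambda == cv$lambda_min)
    beta <- cv$full_fit$beta[, idx]
    if (beta["signal"] > 0) hits <- hits + 1
    if (seed == 1) {
      cv2 <- cv_select_lambda(X, y, k = 20, seed = seed)
      expect_identical(cv$path, cv2$path)
    }
  }
  expect_gte(hits, 10 * 0.95)
})

test_that("pure-noise features mostly yield the null model", {
  nulls <- 0
  for (seed in 1:12) {
    set.seed(seed + 100)
    X <- matrix(rnorm(60 * 10), 60, dimnames = list(NULL, sprintf("n%d", 1:10)))
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    cv <- cv_select_lambda(X, y, k = 10, seed = seed)
    idx <- which(cv$path$lambda == cv$lambda_min)
    if (all(cv$full_fit$beta[, idx] == 0)) nulls <- nulls + 1
  }
  expect_gt(nulls, 6)
})

test_that("stratified folds degrade gracefully with tiny classes", {
  inst <- random_instance(2, n = 30)
  y <- c(rep(1, 5), rep(0, 25))
  expect_warning(cv <- cv_select_lambda(inst$X[1:30, ], y, k = 20, seed = 1),
                 "reducing k")
  expect_equal(cv$k, 5)
})

test_that("prediction, subscores and contributions decompose the logit", {
  cfg <- network_sim_config(n_drugs = 50, n_eptg = 500, n_stg = 150,
                            n_planted_stg = 6, n_hits = 12, seed = 31)
  sim <- simulate_constellation(cfg)
  cons <- build_constellation(sim$bioactivity, sim$ppi,
                              drugs = sim$labels$compound_id)
  m <- suppressWarnings(costar_train(cons, sim$labels, k = 10, seed = 31))
  sc <- predict_costar_score(m, cons)
  expect_true(all(sc$costar_score > 0 & sc$costar_score < 1))
  expect_setequal(sc$rank, seq_len(nrow(sc)))
  # all-zero feature row scores sigmoid(beta0)
  zero <- matrix(0, 1, length(m$feature_names),
                 dimnames = list("z", m$feature_names))
  expect_equal(predict_costar_score(m, zero)$costar_score,
               plogis(m$beta0))
  # subscore identity: rowSums + intercept = logit(score)
  S <- subscores(m, cons)
  logit_sc <- qlogis(sc$costar_score[match(rownames(S), sc$compound_id)])
  expect_equal(unname(rowSums(S) + attr(S, "intercept")), logit_sc,
               tolerance = 1e-10)
  # increasing a positive-coefficient feature raises the score
  pos <- names(m$beta)[m$beta > 0][1]
  bumped <- as.matrix(cons$X)
  bumped[1, pos] <- bumped[1, pos] + 1
  s2 <- predict_costar_score(m, bumped)
  d1 <- sc$costar_score[sc$compound_id == rownames(bumped)[1]]
  d2 <- s2$costar_score[s2$compound_id == rownames(bumped)[1]]
  expect_gt(d2, d1)

  contrib <- eptg_contributions(m, cons)
  expect_true(all(abs(contrib$contribution) <= 1))
  expect_equal(max(abs(contrib$contribution)), 1)
  # an ePTG with no selected STG neighbours contributes 0
  none <- setdiff(unique(cons$eptg_stg$eptg),
                  cons$eptg_stg$eptg[cons$eptg_stg$stg %in% names(m$beta)])
  if (length(none)) {
    expect_true(all(contrib$contribution[contrib$eptg %in% none] == 0))
  }
})

test_that("classification diagnostics match hand arithmetic", {
  # the training confusion of 20/30 hits and 96/97 negatives correct
  y <- c(rep(1, 30), rep(0, 97))
  scores <- c(rep(0.9, 20), rep(0.1, 10), rep(0.9, 1), rep(0.1, 96))
  ev <- evaluate_classification(y, scores)
  expect_equal(ev$accuracy, 116 / 127)
  expect_equal(ev$confusion$n, c(20, 10, 1, 96))
  # perfect separation
  ev2 <- evaluate_classification(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$auc, 1)
  # random scores: AUC near 1/2, and agreement with an independent AUC
  set.seed(4)
  yy <- rbinom(1000, 1, 0.5)
  ss <- runif(1000)
  ev3 <- evaluate_classification(yy, ss)
  expect_lt(abs(ev3$auc - 0.5), 0.05)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- pROC::auc(pROC::roc(yy, ss, quiet = TRUE, direction = "<"))
    expect_equal(ev3$auc, as.numeric(ref), tolerance = 1e-10)
  }
  expect_warning(ev4 <- evaluate_classification(c(1, 1), c(0.2, 0.6)),
                 "single-class")
  expect_true(is.na(ev4$auc))
})

test_that("model serialization round-trips predictions bit-for-bit", {
  cfg <- network_sim_config(n_drugs = 40, n_eptg = 300, n_stg = 120,
                            n_planted_stg = 5, n_hits = 10, seed = 13)
  sim <- simulate_constellation(cfg)
  cons <- build_constellation(sim$bioactivity, sim$ppi,
                              drugs = sim$labels$compound_id)
  m <- suppressWarnings(costar_train(cons, sim$labels, k = 8, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_costar_model(m, path)
  back <- read_costar_model(path)
  expect_identical(predict_costar_score(back, cons),
                   predict_costar_score(m, cons))
})

test_that("library screening returns candidate sets of the requested size", {
  cfg <- network_sim_config(n_drugs = 60, n_eptg = 500, n_stg = 200,
                            n_planted_stg = 8, n_hits = 15, seed = 17)
  sim <- simulate_constellation(cfg)
  cons <- build_constellation(sim$bioactivity, sim$ppi,
                              drugs = sim$labels$compound_id)
  m <- suppressWarnings(costar_train(cons, sim$labels, k = 10, seed = 17))
  # held-out compounds from the same generator and network
  cfg2 <- network_sim_config(n_drugs = 80, n_eptg = 500, n_stg = 200,
                             n_planted_stg = 8, n_hits = 20, seed = 18)
  sim2 <- simulate_constellation(cfg2)
  expect_warning(
    out <- screen_library(m, sim2$bioactivity, sim2$ppi,
                          top_k = 23, bottom_k = 25),
    "features absent")
  expect_equal(sum(out$candidate == "top", na.rm = TRUE), 23)
  expect_equal(sum(out$candidate == "bottom", na.rm = TRUE), 25)
  expect_true(all(out$costar_score > 0 & out$costar_score < 1))
})
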