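# Scoring, diagnostics and in-silico screening with a trained model.

# Align a new feature matrix to the model's training feature order:
# missing features are imputed as zero connectivity, extra features are
# dropped with a warning.
.align_features <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new))) {
    if (ncol(X_new) != length(model$feature_names)) {
      abort("feature-order hash mismatch: unnamed columns of the wrong width")
    }
    colnames(X_new) <- model$feature_names
    return(X_new)
  }
  if (identical(feature_hash(colnames(X_new)), model$feature_hash)) return(X_new)
  extra <- setdiff(colnames(X_new), model$feature_names)
  if (length(extra)) {
    warn(sprintf("dropping %d features absent from the trained model", length(extra)))
  }
  out <- matrix(0, nrow(X_new), length(model$feature_names),
                dimnames = list(rownames(X_new), model$feature_names))
  common <- intersect(colnames(X_new), model$feature_names)
  out[, common] <- X_new[, common]
  out
}

#' Predict COSTAR scores (hit probabilities) for compounds
#'
#' `score = sigmoid(beta0 + x . beta)`, the predicted probability that
#' a compound is a screening hit.  Compounds are ranked by descending
#' score with ties broken by compound id, and classified at
#' `threshold`.
#'
#' @param model A `costar_model`.
#' @param X_new Feature matrix (drug x STG); columns aligned by name
#'   (missing features 0, extras dropped with a warning), or a
#'   `constellation`.
#' @param threshold Classification threshold on the score.
#' @return Tibble: compound_id, costar_score (in (0, 1)), rank,
#'   predicted_hit.
#' @export
predict_costar_score <- function(model, X_new, threshold = 0.5) {
  if (inherits(X_new, "constellation")) X_new <- X_new$X
  X <- .align_features(model, X_new)
  sel <- names(model$beta)
  eta <- as.numeric(model$beta0 +
    (if (length(sel)) X[, sel, drop = FALSE] %*% model$beta else 0))
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("compound%05d", seq_len(nrow(X)))
  out <- tibble::tibble(compound_id = ids, costar_score = sigmoid(eta))
  out <- out[order(-out$costar_score, out$compound_id), ]
  out$rank <- seq_len(nrow(out))
  out$predicted_hit <- out$costar_score > threshold
  out
}

#' Per-compound, per-target subscores
#'
#' The subscore of compound `d` for a selected target `g` is the model
#' coefficient multiplied by the integrated connectivity,
#' `S[d, g] = beta_g * X[d, g]` (on the original connectivity scale, so
#' the logit decomposes as `logit(score_d) = beta0_adj + sum_g S[d, g]`
#' where `beta0_adj` absorbs the standardization centering).
#'
#' @param model A `costar_model`.
#' @param X Feature matrix or `constellation`.
#' @return Matrix (compounds x selected targets) with attribute
#'   `"intercept"` such that `rowSums(S) + intercept = logit(score)`.
#' @export
subscores <- function(model, X) {
  if (inherits(X, "constellation")) X <- X$X
  X <- .align_features(model, X)
  sel <- names(model$beta)
  S <- sweep(X[, sel, drop = FALSE], 2, model$beta, "*")
  attr(S, "intercept") <- model$beta0
  S
}

#' Integrated ePTG contributions to the learned signature
#'
#' Aggregates the selected-STG coefficients attached to each ePTG:
#' `raw(e) = sum_{g in STG(e)} beta_g`, normalised by the largest
#' absolute aggregate so contributions lie in \[-1, 1\], signed toward
#' hit (+) or non-hit (-).  ePTGs connected to no selected STG get 0.
#'
#' @param model A `costar_model`.
#' @param constellation The `constellation` the model was trained on
#'   (shares the STG vocabulary).
#' @return Tibble (eptg, raw, contribution) sorted by contribution.
#' @export
eptg_contributions <- function(model, constellation) {
  stopifnot(inherits(constellation, "constellation"))
  links <- constellation$eptg_stg
  sel <- names(model$beta)
  raw <- links[links$stg %in% sel, ] |>
    dplyr::mutate(beta = model$beta[.data$stg]) |>
    dplyr::group_by(.data$eptg) |>
    dplyr::summarise(raw = sum(.data$beta), .groups = "drop")
  all_eptg <- tibble::tibble(eptg = sort(unique(links$eptg)))
  out <- dplyr::left_join(all_eptg, raw, by = "eptg") |>
    dplyr::mutate(raw = dplyr::coalesce(.data$raw, 0))
  m <- max(abs(out$raw))
  out$contribution <- if (m > 0) out$raw / m else 0
  dplyr::arrange(out, dplyr::desc(.data$contribution))
}

#' Classification diagnostics: confusion matrix, accuracy, ROC, AUC
#'
#' Confusion counts at `threshold`; ROC by a score-sorted sweep in
#' which tied scores move as one block (midrank tie handling), AUC by
#' the trapezoid rule.
#'
#' @param labels Binary labels (0/1).
#' @param scores Scores in \[0, 1\].
#' @param threshold Classification threshold.
#' @return A `costar_eval`: list with `confusion` (tibble), `accuracy`,
#'   `roc` (tibble fpr/tpr), `auc` (NA with a warning for single-class
#'   labels).
#' @export
evaluate_classification <- function(labels, scores, threshold = 0.5) {
  y <- as.integer(labels)
  stopifnot(length(y) == length(scores))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  confusion <- tibble::tibble(
    truth = c(1, 1, 0, 0), predicted = c(1, 0, 1, 0),
    n = c(tp, fn, fp, tn))
  accuracy <- (tp + tn) / length(y)
  if (length(unique(y)) < 2) {
    warn("single-class labels: ROC/AUC undefined")
    roc <- tibble::tibble(fpr = numeric(), tpr = numeric())
    auc <- NA_real_
  } else {
    # sweep thresholds over unique score values, descending
    ord <- order(-scores)
    ys <- y[ord]; ss <- scores[ord]
    grp <- cumsum(!duplicated(ss))
    pos_steps <- tapply(ys == 1, grp, sum)
    neg_steps <- tapply(ys == 0, grp, sum)
    tpr <- c(0, cumsum(pos_steps) / sum(y == 1))
    fpr <- c(0, cumsum(neg_steps) / sum(y == 0))
    roc <- tibble::tibble(fpr = as.numeric(fpr), tpr = as.numeric(tpr))
    auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
  structure(list(confusion = confusion, accuracy = accuracy, roc = roc,
                 auc = auc, threshold = threshold),
            class = "costar_eval")
}

#' @export
print.costar_eval <- function(x, ...) {
  cat(sprintf("<costar_eval> accuracy %.3f, AUC %s (threshold %.2f)\n",
              x$accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$threshold))
  invisible(x)
}

#' Screen a compound library in silico
#'
#' Builds the drug x STG connectivity of new compounds from their
#' bioactivity annotations and the same PPI network/threshold the model
#' was trained with, scores every compound, and returns the full
#' ranking plus the `top_k` predicted hits and `bottom_k` predicted
#' non-hits.  Compounds without any annotation score `sigmoid(beta0)`
#' and are flagged.
#'
#' @param model A `costar_model`.
#' @param bio Bioactivity table for the new compounds.
#' @param ppi PPI table (raw; same network as training).
#' @param top_k,bottom_k Sizes of the candidate sets.
#' @param min_score PPI threshold; defaults to the model's.
#' @return Tibble: compound_id, costar_score, rank, predicted_hit,
#'   unannotated, candidate (`"top"`, `"bottom"` or NA).
#' @export
screen_library <- function(model, bio, ppi, top_k = 23, bottom_k = 25,
                           min_score = NULL) {
  if (is.null(min_score)) {
    min_score <- if (is.na(model$ppi_threshold)) 0.6 else model$ppi_threshold
  }
  bio <- ingest_bioactivity(bio)
  all_cpds <- sort(unique(bio$compound_id))
  cons <- build_constellation(bio, ppi, min_score = min_score,
                              mode = if (is.na(model$mode)) "path_count" else model$mode,
                              drugs = all_cpds)
  out <- predict_costar_score(model, cons)
  out$unannotated <- out$compound_id %in% cons$unannotated
  n <- nrow(out)
  out$candidate <- NA_character_
  out$candidate[out$rank <= top_k] <- "top"
  out$candidate[out$rank > n - bottom_k] <- "bottom"
  out
}
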