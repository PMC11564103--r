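# ggplot2 graphics for the main result types.

#' Volcano plot of drug responses
#'
#' PCY score against -log10(q); on-target hits (score > 0,
#' -log10(q) > 1.3) are highlighted.
#'
#' @param responses Output of [score_drug_responses()].
#' @return A ggplot.
#' @export
plot_pcy_volcano <- function(responses) {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$pcy_score,
                               y = -log10(.data$q_value),
                               colour = .data$on_target_hit)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1.3, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60"),
                                 name = "on-target hit") +
    ggplot2::labs(x = "PCY score", y = expression(-log[10](q))) +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_methods Cross-validated deviance path with
#'   standard-error ribbon; the vertical line marks the selected
#'   lambda.
#' @export
autoplot.costar_cv <- function(object, ...) {
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = log10(.data$lambda),
                               y = .data$mean_deviance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_deviance - .data$se_deviance,
      ymax = .data$mean_deviance + .data$se_deviance), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(x = expression(log[10](lambda)),
                  y = "mean held-out binomial deviance") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_methods ROC curve with the chance diagonal.
#' @export
autoplot.costar_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#1b7837") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_methods Selected-coefficient lollipop plot.
#' @export
autoplot.costar_model <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$estimate,
                                       yend = .data$term), colour = "grey60") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "coefficient (connectivity scale)",
                  y = "secondary target gene") +
    ggplot2::theme_minimal()
}

#' Plot calcium traces
#'
#' Faceted per-ROI traces with the drug-addition time marked.
#'
#' @param traces Long tibble (roi_id, time_s, intensity).
#' @param drug_time_s Optional drug-addition time.
#' @param max_rois Cap on the number of ROIs shown.
#' @return A ggplot.
#' @export
plot_traces <- function(traces, drug_time_s = NULL, max_rois = 12) {
  rois <- head(unique(traces$roi_id), max_rois)
  p <- ggplot2::ggplot(traces[traces$roi_id %in% rois, ],
                       ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~roi_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(drug_time_s)) {
    p <- p + ggplot2::geom_vline(xintercept = drug_time_s,
                                 linetype = "dashed", colour = "#b2182b")
  }
  p
}

#' Autoplot methods
#'
#' @param object A fitted object from this package.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_methods
NULL
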