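#' Scatter plot of edge co-expression dynamics
#'
#' The classic two-condition PCC scatter: one dot per interaction, coloured by
#' where its correlation magnitude reaches the significance threshold.
#'
#' @param object An `edge_dynamics` tibble from [classify_edge_dynamics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.edge_dynamics <- function(object, ...) {
  thr <- attr(object, "threshold")
  conds <- attr(object, "conditions")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pcc_a, y = .data$pcc_b,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(-thr, thr), linetype = 2,
                        colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = sprintf("PCC (%s)", conds[1]),
                  y = sprintf("PCC (%s)", conds[2]),
                  colour = NULL,
                  title = "Interaction co-expression across conditions") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Degree-vs-SDEG-proportion curve
#' @param object An `sdeg_association` from [sdeg_degree_association()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdeg_association <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$mean_degree, y = .data$sdeg_prop)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::labs(x = "Mean CePIN degree (bin)",
                  y = "SDEG proportion",
                  size = "Nodes",
                  title = sprintf(
                    "SDEG proportion vs degree (high %.2f vs low %.2f, Fisher p = %.2g)",
                    object$proportions["high"], object$proportions["low"],
                    object$p_value)) +
    ggplot2::theme_minimal()
}

#' Module activity by condition
#'
#' @param module A `functional_module` or gene vector.
#' @param expr Expression matrix.
#' @param design A [sample_design()].
#' @return A ggplot (per-condition boxplot of the module activity score).
#' @export
plot_module_activity <- function(module, expr, design) {
  act <- module_activity(module, expr) |>
    inner_join(design, by = "sample")
  ggplot2::ggplot(act, ggplot2::aes(x = .data$condition, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "Module activity (mean member expression)") +
    ggplot2::theme_minimal()
}
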