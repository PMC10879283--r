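#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of per-fold balanced accuracies
#'
#' @param object An `ftd_cv_result`.
#' @param ... Unused.
#' @return A ggplot: balanced accuracy per class (and overall) across
#'   outer folds.
#' @export
autoplot.ftd_cv_result <- function(object, ...) {
  ggplot2::ggplot(object$fold_metrics,
                  ggplot2::aes(x = .data$class,
                               y = .data$balanced_accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "balanced accuracy",
                  title = "Per-fold balanced accuracy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Ablation comparison box plot
#'
#' @param object An `ftd_ablation`.
#' @param ... Unused.
#' @return A ggplot of per-fold balanced accuracies by experiment and
#'   class.
#' @export
autoplot.ftd_ablation <- function(object, ...) {
  ggplot2::ggplot(object$fold_values,
                  ggplot2::aes(x = .data$class,
                               y = .data$balanced_accuracy,
                               fill = .data$experiment)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                          outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "balanced accuracy", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Flat heatmap of per-patch importance maps
#'
#' Tabular stand-in for cortical-surface rendering: features on the x
#' axis (grouped by block), subtypes on the y axis, signed importance as
#' a symmetric diverging fill.
#'
#' @param maps Tibble(s) from [population_importance_map()].
#' @param limit Symmetric color limit; defaults to max |importance|.
#' @return A ggplot.
#' @export
plot_importance_heatmap <- function(maps, limit = NULL) {
  maps <- dplyr::bind_rows(maps)
  if (is.null(limit)) limit <- max(abs(maps$importance))
  ggplot2::ggplot(maps,
                  ggplot2::aes(x = .data$index, y = .data$subtype,
                               fill = .data$importance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B",
                                  limits = c(-limit, limit)) +
    ggplot2::labs(x = "feature index (thickness | cortical volume | subcortical)",
                  y = NULL, fill = "importance") +
    ggplot2::theme_minimal()
}

#' W-score panorama heatmap
#'
#' Subjects (rows, grouped by diagnosis) by features (columns) heatmap of
#' z-standardized values, the standard diagnostic for residual cohort
#' structure before/after harmonization.
#'
#' @param data Feature table (raw or harmonized).
#' @param schema An [atlas_schema()].
#' @param limit Symmetric color limit on the displayed scores.
#' @return A ggplot.
#' @export
plot_wscore_panorama <- function(data, schema = default_atlas_schema(),
                                 limit = 4) {
  X <- feature_matrix(data, schema)
  if (!is_harmonized(data)) X <- scale(X)
  ord <- order(data$diagnosis, data$cohort)
  long <- tibble::tibble(
    row = rep(seq_along(ord), times = ncol(X)),
    col = rep(seq_len(ncol(X)), each = length(ord)),
    value = as.vector(pmin(pmax(X[ord, ], -limit), limit))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B",
                                  limits = c(-limit, limit)) +
    ggplot2::labs(x = "feature", y = "subject (by diagnosis, cohort)",
                  fill = "score") +
    ggplot2::theme_minimal()
}
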