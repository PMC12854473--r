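# ggplot2 views of the main result types.

#' Plot a slide annotation
#'
#' Nucleus centroids colored by class over the tumor-region outline (and the
#' vicinity ring when supplied). The y axis is flipped so the plot matches
#' image orientation (origin top-left).
#'
#' @param annotation A [slide_annotation()].
#' @param regions Optional [label_tumor_regions()] result.
#' @param vicinity Optional ring raster from [compute_vicinity()].
#' @param point_size Point size, default 0.4.
#' @return A ggplot object.
#' @export
plot_slide <- function(annotation, regions = NULL, vicinity = NULL,
                       point_size = 0.4) {
  nuc <- mutate(annotation$nuclei, class_name = class_name(.data$class))
  p <- ggplot(nuc, aes(x = .data$x, y = .data$y, colour = .data$class_name))
  raster_layer <- function(raster, ds, fill) {
    idx <- which(raster > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    geom_tile(
      data = tibble(x = (idx[, 2] - 0.5) * ds, y = (idx[, 1] - 0.5) * ds),
      aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
      fill = fill, alpha = 0.3, width = ds, height = ds)
  }
  if (!is.null(vicinity) && !is.null(regions)) {
    p <- p + raster_layer(vicinity, regions$downsample, "goldenrod")
  }
  if (!is.null(regions)) {
    p <- p + raster_layer(regions$label_raster, regions$downsample, "grey40")
  }
  p + geom_point(size = point_size) +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", colour = "class",
         title = annotation$sample_id) +
    theme_minimal()
}

#' @describeIn sweep_n_features Mean balanced accuracy against the number of
#'   kept features, with the per-fold curves in grey and `n_best` marked.
#' @param object An `hf_sweep`.
#' @param ... Unused.
#' @export
autoplot.hf_sweep <- function(object, ...) {
  ggplot(object$summary,
         aes(x = .data$n, y = .data$mean_balanced_accuracy)) +
    geom_line(data = object$per_fold,
              aes(y = .data$balanced_accuracy, group = .data$fold),
              colour = "grey70", linewidth = 0.3) +
    geom_line(colour = "steelblue", linewidth = 0.8) +
    geom_vline(xintercept = object$n_best, linetype = "dashed") +
    labs(x = "features kept (N)", y = "balanced accuracy",
         title = sprintf("Feature-count sweep (n_best = %d)", object$n_best)) +
    theme_minimal()
}

#' @describeIn fit_and_evaluate Per-fold ROC curves with the vertically
#'   averaged mean curve.
#' @param object An `hf_response_fit`.
#' @param ... Unused.
#' @export
autoplot.hf_response_fit <- function(object, ...) {
  ggplot(object$roc_points,
         aes(x = .data$fpr, y = .data$tpr, group = .data$fold)) +
    geom_step(colour = "grey60", linewidth = 0.4) +
    geom_line(data = object$mean_roc, aes(group = NULL),
              colour = "firebrick", linewidth = 0.9) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("Mean AUROC %.3f +/- %.3f (%d features/fold)",
                         object$mean_auc, object$sd_auc, object$n_best)) +
    theme_minimal()
}

#' Plot aggregated feature scores
#'
#' Occurrence count and rank score of the top aggregated features from
#' [aggregate_scores()].
#'
#' @param scores Tibble from [aggregate_scores()].
#' @param top Number of features to show, default 20.
#' @return A ggplot object.
#' @export
plot_feature_scores <- function(scores, top = 20) {
  dat <- head(scores, top) |>
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(dat, aes(x = .data$s, y = .data$feature,
                  colour = factor(.data$c))) +
    geom_point(size = 2) +
    labs(x = "rank score s", y = NULL, colour = "occurrences c") +
    theme_minimal()
}
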