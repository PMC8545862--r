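#' ROC curve of a binary cross-validation result
#'
#' Pools the held-out scores (one per subject) into a single ROC curve.
#'
#' @param object A binary `gbc_cv` with scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gbc_cv
#' @export
autoplot.gbc_cv <- function(object, ...) {
  m <- compute_metrics(object)
  if (is.null(m$roc)) abort("ROC curves are defined for binary results with scores.")
  ggplot2::ggplot(m$roc, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("LOSOCV ROC (AUC = %.3f)", m$overall$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Null distribution of a performance permutation test
#'
#' @param object A `gbc_permtest`.
#' @param metric Metric to display (default `"balanced_accuracy"`).
#' @param ... Unused.
#' @return A ggplot object: null histogram with the observed value marked.
#' @method autoplot gbc_permtest
#' @export
autoplot.gbc_permtest <- function(object, metric = "balanced_accuracy", ...) {
  df <- tibble(value = object$null[[metric]])
  obs <- object$observed[[metric]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "red", linewidth = 1) +
    ggplot2::labs(x = metric, y = "Permutations",
                  title = sprintf("Permutation null (observed = %.3f)", obs)) +
    ggplot2::theme_minimal()
}

#' Axial slice of a GBC (or weight) map
#'
#' @param map A `gbc_map`.
#' @param slice Z index of the axial slice (default: middle slice).
#' @return A ggplot raster of the slice, mask voxels only.
#' @export
plot_gbc_slice <- function(map, slice = NULL) {
  dims <- dim(map$data)
  slice <- slice %||% ceiling(dims[3] / 2)
  sl <- map$data[, , slice]
  df <- tidyr::expand_grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$value <- as.vector(sl)[(df$y - 1) * dims[1] + df$x]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Axial slice z = %d", slice), fill = "zGBC") +
    ggplot2::theme_minimal()
}
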