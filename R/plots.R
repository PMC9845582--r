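#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Density plot of per-pair log10 likelihood ratios
#'
#' Overlaid density curves of the simulated log10 LR for related versus
#' unrelated pairs, faceted by relationship — the standard view of how well
#' a panel separates the two hypotheses.
#'
#' @param object A `dip_lr_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dip_lr_study
#' @export
autoplot.dip_lr_study <- function(object, ...) {
  ggplot2::ggplot(
    object$log10_lr,
    ggplot2::aes(x = .data$log10_lr, fill = .data$class)
  ) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~relationship, scales = "free") +
    ggplot2::labs(
      x = expression(log[10] ~ LR),
      y = "density",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `dip_ancestry_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dip_ancestry_eval
#' @export
autoplot.dip_ancestry_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$truth, y = .data$prediction, fill = .data$count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf(
        "accuracy %.4f (%.0f%% CI %.4f-%.4f)",
        object$accuracy, 100 * object$conf_level, object$ci_low, object$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of MDS or PCA coordinates
#'
#' @param coords Tibble from [classical_mds()] or [pca_panel()].
#' @param dims Which two axes to draw (column indices among the coordinate
#'   columns).
#' @return A ggplot object.
#' @export
plot_coordinates <- function(coords, dims = c(1, 2)) {
  axis_cols <- grep("^(dim|pc)[0-9]+$", names(coords), value = TRUE)
  stopifnot(length(axis_cols) >= max(dims))
  xs <- axis_cols[dims[1]]
  ys <- axis_cols[dims[2]]
  colour <- if ("group" %in% names(coords)) "group" else NULL
  vf <- attr(coords, "variance_fraction")
  lab <- function(i) {
    if (!is.null(vf) && length(vf) >= dims[i]) {
      sprintf("%s (%.1f%%)", axis_cols[dims[i]], 100 * vf[dims[i]])
    } else axis_cols[dims[i]]
  }
  p <- ggplot2::ggplot(
    coords,
    ggplot2::aes(x = .data[[xs]], y = .data[[ys]])
  )
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}
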