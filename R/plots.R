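#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot for a PCA model
#'
#' @param object A `pca_model`.
#' @param classes Optional class label per sample for colouring.
#' @param components Two component indices to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot score scatter with explained-variance axis labels.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, classes = NULL, components = c(1, 2), ...) {
  df <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                          rownames = "sample")
  names(df)[2:3] <- c("x", "y")
  if (!is.null(classes)) df$class <- classes
  pct <- 100 * object$explained_variance[components]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], pct[1]),
      y = sprintf("PC%d (%.1f%%)", components[2], pct[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(classes)) {
    p + ggplot2::geom_point() +
      ggplot2::geom_text(ggplot2::aes(label = .data$sample), vjust = -0.8, size = 3)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2)
  }
}

#' Score plot for a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param components Two latent-variable indices to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot score scatter coloured by class.
#' @method autoplot plsda_model
#' @export
autoplot.plsda_model <- function(object, components = c(1, 2), ...) {
  df <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                          rownames = "sample")
  names(df)[2:3] <- c("x", "y")
  df$class <- object$classes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("LV", components[1]),
                  y = paste0("LV", components[2]), colour = "class") +
    ggplot2::theme_minimal()
}

#' Stacked-bar composition profile
#'
#' @param profile Tibble from [composition_profile()].
#' @return A ggplot stacked bar chart of per-sample category percentages.
#' @export
plot_composition <- function(profile) {
  cat_col <- setdiff(names(profile), c("sample", "percent"))[1]
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$sample, y = .data$percent,
                               fill = .data[[cat_col]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of detected volatiles", fill = cat_col) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' VIP bar chart for a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param top Show the `top` highest-VIP variables (default 20).
#' @param threshold Reference line (default 1, the usual marker cut-off).
#' @return A ggplot bar chart of VIP scores.
#' @export
plot_vip <- function(model, top = 20, threshold = 1) {
  df <- tidy(model, "vip")
  df <- head(dplyr::arrange(df, dplyr::desc(.data$vip)), top)
  df$compound <- factor(df$compound, levels = rev(df$compound))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vip, y = .data$compound)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "VIP", y = NULL) +
    ggplot2::theme_minimal()
}
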