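# ggplot2 views of the main result types.

#' Plot reflectance spectra
#'
#' @param spectra Long tibble with `wavelength`, `reflectance` and
#'   optionally `species`/`category` columns.
#' @param colour Column mapped to colour (default `"category"` if present).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, colour = NULL) {
  spectra <- tibble::as_tibble(spectra)
  if (is.null(colour)) {
    colour <- intersect(c("category", "species"), names(spectra))[1]
  }
  grp <- intersect(c("species", "fruit"), names(spectra))
  spectra$..grp <- interaction(spectra[grp], drop = TRUE)
  p <- ggplot2::ggplot(spectra, ggplot2::aes(.data$wavelength, .data$reflectance,
                                             group = .data$..grp))
  if (!is.na(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]), alpha = 0.5)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.5)
  }
  p + ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance")
}

#' Plot species in a projection of tetrahedral color space
#'
#' @param points Tibble with `x`, `y`, `z` and optionally `category`.
#' @param axes Which two coordinates to show (default x, y).
#' @return A ggplot object.
#' @export
plot_color_space <- function(points, axes = c("x", "y")) {
  points <- tibble::as_tibble(points)
  p <- ggplot2::ggplot(points, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]]))
  if ("category" %in% names(points)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = paste("Tetrahedral", axes[1]), y = paste("Tetrahedral", axes[2]))
}

#' @rdname autoplot-drupevol
#' @param object A `phylo_pca` object.
#' @param data Optional tibble with `species` and a `category` column used
#'   to colour the scores.
#' @param components Two components to display.
#' @param ... Unused.
#' @method autoplot phylo_pca
#' @export
autoplot.phylo_pca <- function(object, data = NULL, components = c("PC1", "PC2"),
                               ...) {
  sc <- pca_scores(object)
  if (!is.null(data) && "category" %in% names(data)) {
    data <- tibble::as_tibble(data)
    data$species <- normalize_taxa(data$species)
    sc <- dplyr::left_join(sc, data[, c("species", "category")], by = "species")
  }
  ve <- round(100 * object$variance_explained, 1)
  lab <- function(pc) {
    i <- match(pc, colnames(object$loadings))
    paste0(pc, " (", ve[i], "%)")
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[components[1]]], .data[[components[2]]]))
  if ("category" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = lab(components[1]), y = lab(components[2]))
}

#' Autoplot methods for drupevol results
#'
#' @name autoplot-drupevol
NULL

#' @rdname autoplot-drupevol
#' @method autoplot simmap_result
#' @export
autoplot.simmap_result <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$mean_counts), .name_repair = "minimal")
  names(d) <- c("from", "to", "mean_count")
  ggplot2::ggplot(d, ggplot2::aes(.data$to, .data$from, fill = .data$mean_count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$mean_count, 2))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "To state", y = "From state", fill = "Mean transitions")
}
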