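# ggplot2 displays for the grid-shaped results. All maps use the symmetric
# blue-white-red convention: red for maximum, blue for minimum eMAF.

map_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   axis.text = ggplot2::element_blank(),
                   axis.title = ggplot2::element_blank())
}

#' Plot an accession portrait
#'
#' @param object A `som_portrait`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.som_portrait <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$emaf), .Machine$double.eps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$emaf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim), name = "eMAF") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::ggtitle(attr(object, "label")) +
    map_theme()
}

#' Plot a phenotype map
#'
#' @param object A `phenotype_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenotype_map <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::ggtitle(sprintf("%s (%s)", attr(object, "phenotype"),
                             attr(object, "statistic"))) +
    map_theme()
  if (identical(attr(object, "statistic"), "pointbiserial")) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                      limits = c(-1, 1), name = "r")
  } else {
    p + ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                     name = "-log10 p")
  }
}

#' Plot a spot map over the summary landscape
#'
#' @param object A `spot_map`.
#' @param ... Unused.
#' @return A ggplot object with spot letters at the centroids.
#' @export
autoplot.spot_map <- function(object, ...) {
  nr <- nrow(object$summary)
  nc <- ncol(object$summary)
  df <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    emaf = as.vector(object$summary)
  )
  lim <- max(abs(df$emaf), .Machine$double.eps)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$emaf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim), name = "eMAF") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    map_theme()
  if (nrow(object$spots) > 0) {
    p <- p + ggplot2::geom_text(
      data = object$spots,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row,
                   label = .data$spot),
      inherit.aes = FALSE)
  }
  p
}

#' Plot pseudotime spot profiles
#'
#' @param curves Output of [pt_profiles()].
#' @return A ggplot with one panel per spot, points per accession and the
#'   LOESS fits per branch.
#' @export
plot_pt_profiles <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$pt, y = .data$emaf,
                                       colour = .data$branch)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), na.rm = TRUE) +
    ggplot2::facet_wrap(~spot) +
    ggplot2::labs(x = "pseudotime", y = "spot eMAF") +
    ggplot2::theme_minimal()
}

#' Plot accession PCA coordinates
#'
#' @param pca Output of [pca_accessions()].
#' @param groups Optional named group label per accession for colouring.
#' @return A ggplot of the first two components.
#' @export
plot_pca_accessions <- function(pca, groups = NULL) {
  df <- pca$coords
  if (!is.null(groups)) df$group <- unname(groups[df$accession_id])
  aes <- if (is.null(groups)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Export a portrait as TSV and PNG
#'
#' @param p A `som_portrait`.
#' @param path_prefix Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_portrait <- function(p, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  readr::write_tsv(tidy(p), tsv, progress = FALSE)
  png_path <- paste0(path_prefix, ".png")
  grDevices::png(png_path, width = 480, height = 480)
  print(autoplot(p))
  grDevices::dev.off()
  invisible(c(tsv, png_path))
}
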