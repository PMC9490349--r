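# ggplot2 views of the main result types.

#' Map of an active surface with detected pits
#'
#' Plots the active-plane points coloured by elevation (or TPI) with pit
#' planform polygons and centroids overlaid.
#'
#' @param model an oriented `percussr_surface`.
#' @param pits optional `percussr_pits` tibble (with polygons if available).
#' @param tpi optional `percussr_tpi`; when given, colour is TPI.
#' @param point_size plotting size of surface points.
#' @return a ggplot object.
#' @export
plot_active_surface <- function(model, pits = NULL, tpi = NULL,
                                point_size = 0.3) {
  idx <- active_idx(model)
  df <- tibble::tibble(x = model$points[idx, 1], y = model$points[idx, 2],
                       value = model$points[idx, 3])
  lab <- "z (mm)"
  if (!is.null(tpi)) {
    df <- tibble::tibble(x = tpi$x, y = tpi$y, value = tpi$tpi)
    lab <- "TPI (mm)"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$value)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_colour_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = model$tool_id, x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(pits) && nrow(pits) > 0) {
    if ("polygon" %in% names(pits)) {
      polys <- dplyr::bind_rows(lapply(seq_len(nrow(pits)), function(i) {
        tibble::tibble(pit_id = pits$pit_id[i],
                       x = pits$polygon[[i]][, 1],
                       y = pits$polygon[[i]][, 2])
      }))
      p <- p + ggplot2::geom_path(
        data = polys,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$pit_id),
        colour = "red", inherit.aes = FALSE
      )
    }
    p <- p + ggplot2::geom_point(
      data = pits,
      ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
      colour = "red", shape = 3, size = 2, inherit.aes = FALSE
    )
  }
  p
}

#' @export
autoplot.percussr_tpi <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y, tpi = object$tpi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$tpi)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "TPI (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.percussr_pca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  cn <- paste0("PC", components)
  has_group <- "group" %in% names(sc)
  p <- ggplot2::ggplot(
    sc, ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]])
  )
  if (has_group)
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  else p <- p + ggplot2::geom_point(size = 2)
  p +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cn[1],
                  object$percent_variance[components[1]]),
      y = sprintf("%s (%.1f%%)", cn[2],
                  object$percent_variance[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.assemblage_comparison <- function(object, ...) {
  autoplot(object$pca, ...) +
    ggplot2::labs(title = paste(object$labels, collapse = " vs "))
}
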