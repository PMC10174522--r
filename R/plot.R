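# ggplot2 display methods for rasters, meshes and study results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pixel image as a raster
#' @param object a `pixel_image`
#' @param ... unused
#' @export
autoplot.pixel_image <- function(object, ...) {
  pc <- pixel_centres(object$extent, nrow(object$values), ncol(object$values))
  df <- tibble::tibble(
    x = rep(pc$x, each = nrow(object$values)),
    y = rep(pc$y, times = ncol(object$values)),
    value = as.vector(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$semantics) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @export
plot.pixel_image <- function(x, ...) print(autoplot(x, ...))

#' Plot a reconstruction's restored image
#' @param object an `eit_recon`
#' @param ... unused
#' @export
autoplot.eit_recon <- function(object, ...) {
  autoplot(object$restored_image) +
    ggplot2::ggtitle(sprintf("%s (lambda = %.3g, NF = %.3f)", object$method,
                             object$lambda_used, object$achieved_noise_figure))
}

#' @export
plot.eit_recon <- function(x, ...) print(autoplot(x, ...))

#' Plot per-case mean l2 differences of a study
#' @param object an `eit_study`
#' @param ... unused
#' @export
autoplot.eit_study <- function(object, ...) {
  df <- summary_table(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$case, .data$l2,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "l2-norm image difference",
                  title = sprintf("%s study", object$study)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
plot.eit_study <- function(x, ...) print(autoplot(x, ...))

#' Plot a mesh outline with electrodes
#' @param x an `eit_mesh`
#' @param ... unused
#' @export
plot.eit_mesh <- function(x, ...) {
  nd <- x$nodes
  el <- x$elements
  seg <- rbind(cbind(nd[el[, 1], ], nd[el[, 2], ]),
               cbind(nd[el[, 2], ], nd[el[, 3], ]),
               cbind(nd[el[, 3], ], nd[el[, 1], ]))
  df <- tibble::tibble(x = seg[, 1], y = seg[, 2],
                       xend = seg[, 3], yend = seg[, 4])
  edf <- dplyr::bind_rows(lapply(seq_along(x$electrodes), function(l) {
    tibble::tibble(x = nd[x$electrodes[[l]], 1],
                   y = nd[x$electrodes[[l]], 2], electrode = factor(l))
  }))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.1, colour = "grey60") +
    ggplot2::geom_point(data = edf,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$electrode), size = 1) +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = NULL)
  print(p)
  invisible(x)
}
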