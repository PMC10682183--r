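## ggplot2 displays for the main result types.

#' Plot the colony as its colour-assay image
#'
#' Paints every occupied lattice segment with its owner's red/white assay
#' colour, reproducing the appearance of a plated colony screen.
#'
#' @param sim a `prion_sim`.
#' @return a ggplot object.
#' @export
plot_colony <- function(sim) {
  col <- as_colony(sim)
  seg <- occupied_segments(col)
  cen <- colony_census(col)
  pos <- match(seg$cell, cen$index)
  seg$fill <- grDevices::rgb(cen$colour_R[pos], cen$colour_G[pos],
                             cen$colour_B[pos], maxColorValue = 255)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), colour = "grey80",
                       linewidth = 0.1) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (segments)", y = "y (segments)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.curing_curve <- function(object, ...) {
  mode <- attr(object, "mode")
  y <- if (identical(mode, "count")) "n_cured" else "fraction_cured"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation",
                  y = if (identical(mode, "count")) "cells cured"
                      else "fraction of cells cured",
                  title = paste0("curing curve (marker ", attr(object, "marker"),
                                 ", threshold ", format(attr(object, "threshold")),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prion_lineage <- function(object, species = c("C_M", "C_MA1"), ...) {
  ser <- tidyr::pivot_longer(object$series,
                             cols = dplyr::all_of(species),
                             names_to = "species", values_to = "conc")
  ser$cell <- factor(ser$cell, levels = object$chain)
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$time, y = .data$conc,
                                    colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell), ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (min)", y = "concentration (M)",
                  title = paste("lineage of cell", object$target)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prion_fate <- function(object, ...) {
  ed <- object$edges
  births <- c(stats::setNames(0, object$root),
              stats::setNames(ed$birth_time, ed$child))
  ord <- order(births)
  ypos <- stats::setNames(seq_along(births), names(births)[ord])
  seg <- tibble::tibble(
    cell = as.integer(names(births)),
    start = as.numeric(births),
    end = object$clock,
    y = ypos[names(births)]
  )
  link <- tibble::tibble(
    x = ed$birth_time,
    y = ypos[as.character(ed$parent)],
    yend = ypos[as.character(ed$child)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_segment(data = link,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$y, yend = .data$yend),
                          linetype = "dotted") +
    ggplot2::scale_y_continuous(breaks = seg$y, labels = seg$cell) +
    ggplot2::labs(x = "time (min)", y = "cell index",
                  title = paste("fate map of cell", object$root)) +
    ggplot2::theme_minimal()
}
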