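# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot berry records as a stage map
#'
#' Draws each berry at its centroid, sized by length and filled with its
#' measured mean colour; QC-flagged berries get a red outline. The y-axis is
#' reversed to match image coordinates.
#'
#' @param object a `berry_records` tibble from [process_image()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.berry_records <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$fill <- grDevices::rgb(clamp(df$r_mean, 0, 255),
                            clamp(df$g_mean, 0, 255),
                            clamp(df$b_mean, 0, 255), maxColorValue = 255)
  df$flagged <- nzchar(df$qc_flags)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centroid_x,
                                   y = .data$centroid_y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$length_px,
                                     colour = .data$flagged),
                        fill = df$fill, shape = 21, stroke = 1.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red"),
                                 name = "QC flagged") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_area(name = "length (px)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = unique(df$image_id)[1]) +
    ggplot2::theme_minimal()
}

#' Plot platform agreement per trait
#'
#' Dot plot of the range-normalised mean difference and the Pearson
#' correlation for each compared trait.
#'
#' @param object a `trait_comparison` from [compare_traits()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trait_comparison <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df[, c("trait", "rmd", "r")],
                              cols = c("rmd", "r"),
                              names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$trait)) +
    ggplot2::geom_point(size = 2.5, colour = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Platform agreement by trait") +
    ggplot2::theme_minimal()
}

#' Plot a width profile
#'
#' Slice widths along the major axis; the silhouette these trace is the
#' solid of revolution used by the volume and surface-area estimators.
#'
#' @param object a [width_profile()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.width_profile <- function(object, ...) {
  df <- tibble::tibble(i = seq_len(object$h), w = object$widths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = -.data$w / 2,
                                      ymax = .data$w / 2),
                         fill = "firebrick", alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "slice along major axis (px)", y = "width (px)") +
    ggplot2::theme_minimal()
}
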