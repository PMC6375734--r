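# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_hline scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an origin-centered heatmap
#'
#' Rows ordered by increasing t_rep from the top, columns by offset from
#' the origin; masked cells are blank.
#'
#' @param object An origin heatmap.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.origin_heatmap <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(row = match(.data$origin_id, rev(object$origins$origin_id)))
  ggplot(d, aes(x = .data$offset / 1000, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white") +
    labs(x = "offset from origin (kb)",
         y = "origins (increasing t_rep ↓)", fill = "signal") +
    theme_minimal()
}

#' Plot an origin-averaged profile
#'
#' @param object An average profile.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.average_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset / 1000, y = .data$value)) +
    geom_line(na.rm = TRUE) +
    labs(x = "offset from origin (kb)", y = "mean signal") +
    theme_minimal()
}

#' Plot a copy-number profile along the genome
#'
#' @param object A copy-number profile.
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @export
autoplot.copy_number_profile <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot(d, aes(x = (.data$start + .data$end) / 2e6, y = .data$value)) +
    geom_point(size = 0.2, na.rm = TRUE) +
    facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    labs(x = "position (Mb)", y = "copy number (N)") +
    theme_minimal()
  if (isTRUE(attr(object, "calibrated"))) {
    p <- p + geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50")
  }
  p
}
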