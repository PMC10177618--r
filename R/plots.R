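#' Plot a stage snapshot
#'
#' Dorsal view: anteroposterior vs mediolateral centroid positions, coloured
#' by region; the dashed line marks the midline.
#'
#' @param object A [psm_snapshot()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psm_snapshot <- function(object, ...) {
  cells <- tibble::as_tibble(object)
  ggplot2::ggplot(cells, ggplot2::aes(.data$x_um, .data$y_um,
                                      colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anteroposterior [µm]",
                  y = "mediolateral [µm]",
                  title = sprintf("stage %s", attr(object, "stage"))) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise-distance cohesion result
#'
#' Frequency distribution of in-section pairwise distances with the group
#' median marked.
#'
#' @param object A `cohesion_result` from [pairwise_cohesion()].
#' @param binwidth Histogram bin width in µm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohesion_result <- function(object, binwidth = 5, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$distance_um)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$median_um, colour = "red") +
    ggplot2::labs(x = "pairwise distance [µm]", y = "pairs",
                  title = sprintf("%s: median %.1f µm (%d pairs)",
                                  paste(object$region, collapse = "/"),
                                  object$median_um, object$n_pairs)) +
    ggplot2::theme_minimal()
}

#' Plot the relative-displacement timecourse
#'
#' @param timecourse Output of [generate_embryo_timecourse()] (optionally
#'   several tissues bound together with a `tissue` column).
#' @return A ggplot object.
#' @export
plot_displacement <- function(timecourse) {
  if (!"tissue" %in% names(timecourse)) timecourse$tissue <- "label"
  ggplot2::ggplot(timecourse, ggplot2::aes(.data$stage, .data$d_rel,
                                           colour = .data$tissue)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "stage", y = expression(d[rel])) +
    ggplot2::theme_minimal()
}
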