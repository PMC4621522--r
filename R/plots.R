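# ggplot2 views of screen results.

#' Mass versus retention-time scatter of calls or records
#'
#' The classic screen overview: one point per accepted call (colored by
#' derivative type) or per deduplicated record. Vertical stacks of points
#' at one mass reveal cyclotides shared across many species.
#'
#' @param data A calls tibble (from [annotate_derivatives()]) or a
#'   `cyclotide_records` tibble.
#' @param mass_window,rt_window Optional windows drawn as dashed guides.
#' @return A ggplot object.
#' @export
plot_mass_rt <- function(data, mass_window = NULL, rt_window = NULL) {
  p <- if (inherits(data, "cyclotide_records")) {
    ggplot2::ggplot(data, ggplot2::aes(x = .data$consensus_rt,
                                       y = .data$consensus_mass)) +
      ggplot2::geom_point(alpha = 0.6, size = 1)
  } else {
    d <- data
    if ("accepted" %in% names(d)) d <- d[d$accepted, , drop = FALSE]
    ggplot2::ggplot(d, ggplot2::aes(x = .data$rt, y = .data$neutral_mass,
                                    colour = .data$derivative_type)) +
      ggplot2::geom_point(alpha = 0.6, size = 1) +
      ggplot2::labs(colour = "derivative")
  }
  if (!is.null(mass_window)) {
    p <- p + ggplot2::geom_hline(yintercept = mass_window,
                                 linetype = "dashed", colour = "grey50")
  }
  if (!is.null(rt_window)) {
    p <- p + ggplot2::geom_vline(xintercept = rt_window,
                                 linetype = "dashed", colour = "grey50")
  }
  p + ggplot2::labs(x = "retention time (min)", y = "neutral mass (Da)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.cyclotide_records <- function(object, ...) {
  plot_mass_rt(object, ...)
}

#' @export
autoplot.cyclotide_screen <- function(object, ...) {
  plot_mass_rt(object$calls,
               mass_window = object$params$mass_window,
               rt_window = object$params$rt_window)
}

#' Per-species cyclotide count distribution
#'
#' @param x An `occurrence_matrix`.
#' @return A ggplot histogram of records per species.
#' @export
plot_species_counts <- function(x) {
  stats <- tibble::tibble(n_records = colSums(unclass(x) > 0))
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$n_records)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "cyclotides per species", y = "species") +
    ggplot2::theme_minimal()
}
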