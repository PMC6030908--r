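#' Guide map along the input sequence
#'
#' One segment per guide at its protospacer interval, coloured by the
#' green/yellow/red specificity class, strands on separate tracks.
#'
#' @param design A `guide_design` from [design_guides()].
#' @return A ggplot object.
#' @export
plot_guide_map <- function(design) {
  g <- design$guides
  g$y <- ifelse(g$strand == "+", 1, -1)
  ggplot2::ggplot(g) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start + 1, xend = .data$start + nchar(.data$protospacer),
                   y = .data$y, yend = .data$y, colour = .data$color),
      linewidth = 3, lineend = "butt",
      position = ggplot2::position_jitter(width = 0, height = 0.35, seed = 1)
    ) +
    ggplot2::scale_colour_manual(
      values = c(green = "#2e7d32", yellow = "#f9a825", red = "#c62828"),
      name = "specificity"
    ) +
    ggplot2::scale_y_continuous(breaks = c(-1, 1), labels = c("-", "+"),
                                limits = c(-1.6, 1.6)) +
    ggplot2::labs(x = "input position (bp)", y = "strand",
                  title = sprintf("%s: %d guide candidates", design$input$name,
                                  nrow(g))) +
    ggplot2::theme_minimal()
}

#' Specificity vs efficiency scatter for a design
#'
#' @param design A `guide_design`.
#' @return A ggplot object.
#' @export
plot_guide_scores <- function(design) {
  ggplot2::ggplot(design$guides,
                  ggplot2::aes(x = .data$spec_score, y = .data$eff_score,
                               colour = .data$color)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(green = "#2e7d32", yellow = "#f9a825", red = "#c62828"),
      guide = "none") +
    ggplot2::lims(x = c(0, 100), y = c(0, 100)) +
    ggplot2::labs(x = "specificity score", y = "efficiency score") +
    ggplot2::theme_minimal()
}

#' Off-target mismatch/CFD profile for one guide
#'
#' @param hits Off-target tibble from [find_offtargets()].
#' @return A ggplot object.
#' @export
plot_offtarget_profile <- function(hits) {
  h <- filter(hits, !.data$is_on_target)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$mismatches), y = .data$cfd)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "mismatches", y = "CFD score") +
    ggplot2::lims(y = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for guide designs
#'
#' @param object A `guide_design`.
#' @param ... Unused.
#' @return A ggplot object (the guide map).
#' @method autoplot guide_design
#' @export
autoplot.guide_design <- function(object, ...) plot_guide_map(object)
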