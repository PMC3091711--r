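#' Dot plot of locus self-matches
#'
#' @param matches a [self_match()] result (optionally thinned).
#' @param blocks optional [chain_and_delimit()] result whose block grid is
#'   drawn over the plot.
#' @param max_points subsample ceiling to keep plots light.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(matches, blocks = NULL, max_points = 50000L) {
  m <- as_tibble(matches)
  if (nrow(m) > max_points) m <- dplyr::slice_sample(m, n = max_points)
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$pos_a, y = .data$pos_b)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position (bp)", y = "position (bp)") +
    ggplot2::theme_minimal()
  if (!is.null(blocks)) {
    b <- blocks$blocks
    p <- p +
      ggplot2::geom_vline(xintercept = c(b$start, max(b$end)),
                          colour = "red", linewidth = 0.2) +
      ggplot2::geom_hline(yintercept = c(b$start, max(b$end)),
                          colour = "red", linewidth = 0.2)
  }
  p
}

#' Diagnostic-site tick plot for a candidate recombinant
#'
#' Reproduces the classic chimera diagnostic: group-assigned sites as tall
#' ticks coloured by parental group along the candidate CDS, within-group
#' variable sites as long ticks and transversions-to-both as short ticks.
#'
#' @param classifications a [classify_sites()] result.
#' @return A ggplot object.
#' @export
plot_chimera_ticks <- function(classifications) {
  d <- as_tibble(classifications) |>
    mutate(height = dplyr::case_when(
      .data$class == "variable-within-group" ~ 1.0,
      .data$class == "transversion-to-both" ~ 0.4,
      TRUE ~ 0.7
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, y = 0,
                                       yend = .data$height)) +
    ggplot2::labs(x = "position along candidate CDS (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-copy peak-relative expression series
#'
#' @param profiles an [expression_profiles()] result.
#' @return A ggplot object (one panel per cultivar).
#' @export
plot_expression_profiles <- function(profiles) {
  d <- profiles$peak_relative
  ggplot2::ggplot(d, ggplot2::aes(x = .data$organ_or_stage,
                                  y = .data$peak_relative,
                                  colour = .data$copy, group = .data$copy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cultivar) +
    ggplot2::labs(x = "stage", y = "expression relative to copy peak") +
    ggplot2::theme_minimal()
}

#' @method autoplot flank_profile
#' @export
autoplot.flank_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset, y = .data$identity)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "distance from CDS (bp)", y = "window identity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
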