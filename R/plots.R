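#' Site map of an annotated protein
#'
#' Lollipop-style map of classified sites along the sequence, optionally
#' with domain intervals as shaded tracks underneath.
#'
#' @param object A `yy_annotation` tibble (see [annotate_sites()]).
#' @param domains Optional domain map tibble (`name`, `start`, `end`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yy_annotation
#' @export
autoplot.yy_annotation <- function(object, domains = NULL, ...) {
  dat <- as_tibble(object) |>
    dplyr::mutate(
      classification = factor(.data$classification, levels = YY_CLASSES)
    )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$position, y = 0, yend = 1,
                   colour = .data$classification),
      linewidth = 0.4
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = 1, colour = .data$classification,
                   shape = .data$residue),
      size = 2
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL,
                                limits = c(-0.35, 1.1)) +
    ggplot2::labs(x = "residue position", colour = "class",
                  shape = "residue") +
    ggplot2::theme_minimal()
  if (!is.null(domains)) {
    p <- p + ggplot2::geom_rect(
      data = domains,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.3, ymax = -0.05, fill = .data$name),
      inherit.aes = FALSE, alpha = 0.5
    ) +
      ggplot2::labs(fill = "domain")
  }
  p
}

#' Conservation support along the reference sequence
#'
#' @param object A [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$support)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, .data$conserved),
      colour = "steelblue", size = 0.6
    ) +
    ggplot2::geom_hline(yintercept = attr(object, "min_fraction"),
                        linetype = "dashed") +
    ggplot2::labs(x = "reference position",
                  y = "identical-residue fraction") +
    ggplot2::theme_minimal()
}

#' Bar chart of classification counts
#'
#' @param counts Output of [summarize_classifications()].
#' @return A ggplot object.
#' @export
plot_classification_summary <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$classification, y = .data$n,
                               fill = .data$residue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sites", fill = "residue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
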