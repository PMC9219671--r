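#' Plot a set of spectra
#'
#' @param df Long spectra tibble.
#' @param alpha Line transparency.
#' @return A ggplot.
#' @export
plot_spectra <- function(df, alpha = 0.3) {
  check_spectra_df(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   group = .data$spectrum_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)", colour = "Class")
}

#' Plot per-class archetypes (mean spectrum with SD band)
#'
#' @param archetype Tibble from [compute_archetype()].
#' @return A ggplot.
#' @export
plot_archetype <- function(archetype) {
  ggplot2::ggplot(archetype, ggplot2::aes(.data$wavenumber, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Normalized intensity")
}

#' @rdname autoplot-methods
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for fitted objects
#'
#' `autoplot.sers_lda()` draws the discriminant plane: training class
#' centroids (crosses) and, optionally, projected spectra.
#' `autoplot.sers_importance()` draws per-class weight profiles (retained
#' features highlighted when present). `autoplot.sers_accuracy_curve()`
#' draws mean accuracy against the number of top features with a 2-SD
#' ribbon.
#'
#' @param object The fitted object.
#' @param newdata Optional long spectra tibble to project.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @method autoplot sers_lda
#' @export
autoplot.sers_lda <- function(object, newdata = NULL, ...) {
  cent <- tibble::as_tibble(object$centroids)
  cent$label <- object$classes
  p <- ggplot2::ggplot(cent, ggplot2::aes(.data$LD1, .data$LD2,
                                          colour = .data$label))
  if (!is.null(newdata)) {
    sc <- project_lda(object, newdata)
    p <- p + ggplot2::geom_point(data = sc, alpha = 0.7)
  }
  p +
    ggplot2::geom_point(shape = 4, size = 4, stroke = 2) +
    ggplot2::labs(x = "LD1", y = "LD2", colour = "Class")
}

#' @rdname autoplot-methods
#' @method autoplot sers_importance
#' @export
autoplot.sers_importance <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber,
                                            abs(.data$normalized)))
  if ("retained" %in% names(object)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$retained), width = 2) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey80"))
  } else {
    p <- p + ggplot2::geom_col(width = 2)
  }
  p + ggplot2::facet_wrap(ggplot2::vars(.data$class), ncol = 1) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "|normalized importance|")
}

#' @rdname autoplot-methods
#' @method autoplot sers_accuracy_curve
#' @export
autoplot.sers_accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_accuracy - 2 * .data$sd_accuracy, 0),
      ymax = pmin(.data$mean_accuracy + 2 * .data$sd_accuracy, 1)
    ), fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Number of top-ranked features", y = "Mean accuracy")
}
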