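# ggplot2 helpers for paired points and model comparisons.

#' Plot paired points against the one-to-one line
#'
#' The canonical figure of the paired design: one point per study
#' (non-insular aggregate on x, insular-related aggregate on y), the
#' one-to-one null line, and optionally the taxon-averaged fitted curves of
#' selected models.
#'
#' @param points Paired points from [prepare_pairs()] (or either pairing
#'   function).
#' @param fits Optional named list of [gd_fit][fit_constrained_linear]
#'   objects whose curves to overlay.
#' @param models Subset of `names(fits)` to draw; defaults to all.
#' @return A ggplot object.
#' @export
plot_paired_points <- function(points, fits = NULL, models = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$taxon_group),
                        alpha = 0.8) +
    ggplot2::labs(
      x = "non-insular aggregate (standardized, shifted)",
      y = "insular-related aggregate (standardized, shifted)",
      colour = "taxon group"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    models <- models %||% names(fits)
    grid <- tibble::tibble(x = seq(min(points$x), max(points$x),
                                   length.out = 200))
    curves <- purrr::map_dfr(models, function(m) {
      tibble::tibble(model = m, x = grid$x, y = predict(fits[[m]], grid))
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$y, linetype = .data$model),
      colour = "grey20", inherit.aes = FALSE
    )
  }
  p
}

#' @method autoplot gd_comparison
#' @export
autoplot.gd_comparison <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
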