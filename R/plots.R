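#' Diagnostic plots
#'
#' Simple ggplot2 views of the pipeline's intermediate objects: contour
#' overlays, curvature profiles against the trim threshold, and
#' coefficient (forest) plots of fitted models.
#'
#' @name plots
NULL

#' Plot tongue contours
#'
#' @param contours Tibble with `token_id`, `point`, `x`, `y`.
#' @param tokens Optional token ids to include (default all).
#' @return A ggplot.
#' @export
plot_contours <- function(contours, tokens = NULL) {
  d <- if (is.null(tokens)) contours else filter(contours, .data$token_id %in% tokens)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$token_id,
    colour = .data$token_id)) +
    ggplot2::geom_path(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot curvature profiles with the trim threshold
#'
#' @param profiles Output of [curvature_profiles()].
#' @param tokens Optional token ids to include.
#' @return A ggplot; dashed lines mark the +/- trim threshold, the shaded
#'   bands the edge-excluded 5% at each end.
#' @export
plot_curvature <- function(profiles, tokens = NULL) {
  d <- if (is.null(tokens)) profiles else filter(profiles, .data$token_id %in% tokens)
  thr <- d$trim_threshold[1]
  ggplot2::ggplot(d, ggplot2::aes(.data$s, .data$kappa, group = .data$token_id,
    colour = .data$token_id)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 0.05, ymin = -Inf, ymax = Inf,
      alpha = 0.1) +
    ggplot2::annotate("rect", xmin = 0.95, xmax = 1, ymin = -Inf, ymax = Inf,
      alpha = 0.1) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
      colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "normalised arc length s",
      y = expression(kappa ~ "(normalised)")) +
    ggplot2::theme_minimal()
}

coef_plot <- function(co, title) {
  co$label <- factor(co$label, levels = rev(co$label))
  ggplot2::ggplot(co, ggplot2::aes(.data$estimate, .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' @method autoplot tsc_lmm
#' @export
autoplot.tsc_lmm <- function(object, ...) {
  coef_plot(object$coefficients, paste("MCI model:", object$design$analysis))
}

#' @method autoplot tsc_clmm
#' @export
autoplot.tsc_clmm <- function(object, ...) {
  coef_plot(object$coefficients, paste("NINFL model:", object$design$analysis))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
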