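#' Plot a spatial footprint (connectivity vs distance)
#'
#' @param object a [spatial_footprint()] tibble.
#' @param ... unused.
#' @return A ggplot of bin means with s.e.m. ribbons.
#' @export
autoplot.footprint <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "source-target distance", y = "mean connectivity") +
    ggplot2::theme_minimal()
}

#' Plot connectivity against perturbation effect
#'
#' @param object a [prediction_tests()] report.
#' @param ... unused.
#' @return A ggplot of IC against connectivity over ordered pairs with the
#'   fitted regression line; pairs with significant connectivity (when the
#'   mask exists) are highlighted.
#' @export
autoplot.cf_ic_report <- function(object, ...) {
  df <- object$pairs
  aes_pt <- if ("cf_sig" %in% names(df)) {
    ggplot2::aes(x = .data$cf, y = .data$ic, colour = .data$cf_sig)
  } else {
    ggplot2::aes(x = .data$cf, y = .data$ic)
  }
  ggplot2::ggplot(df, aes_pt) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(x = .data$cf, y = .data$ic),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", inherit.aes = FALSE) +
    ggplot2::labs(x = paste0("connectivity (", object$method, ")"),
                  y = "interventional connectivity (KS)",
                  colour = "connectivity\nsignificant") +
    ggplot2::theme_minimal()
}

#' Plot the causal-flow hierarchy projection
#'
#' @param scores a [cf_hierarchy_pca()] tibble.
#' @return A ggplot of the first two principal-component scores, coloured by
#'   cluster and shaped by subnetwork label when known.
#' @export
plot_hierarchy <- function(scores) {
  aes_pt <- if ("label" %in% names(scores)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2,
                 colour = factor(.data$cluster), shape = .data$label)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2,
                 colour = factor(.data$cluster))
  }
  ggplot2::ggplot(scores, aes_pt) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}
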