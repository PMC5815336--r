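#' Plot a diversity-area curve
#'
#' @param object A `sar_curve`.
#' @param fit Optional `sar_fit` drawn as a smooth line.
#' @param null Optional `sar_null` envelope drawn as a ribbon.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sar_curve <- function(object, fit = NULL, null = NULL, ...) {
  metric <- attr(object, "metric") %||% "value"
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$area, y = .data$value))
  if (!is.null(null)) {
    p <- p + ggplot2::geom_ribbon(
      data = tibble::as_tibble(null),
      ggplot2::aes(x = .data$area, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(
        data = tibble::as_tibble(null),
        ggplot2::aes(x = .data$area, y = .data$expected),
        inherit.aes = FALSE, linetype = 2)
  }
  if (!is.null(fit)) {
    grid <- tibble::tibble(area = exp(seq(log(min(object$area)),
                                          log(max(object$area)),
                                          length.out = 200)))
    grid$value <- predict(fit, grid)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = expression(Area ~ (m^2)), y = metric,
                  title = sprintf("%s-area curve", metric))
}

#' Plot an empirical semivariogram with an optional model fit
#'
#' Points are the binned semivariances (sized by pair count); the horizontal
#' dashed line is the overall sample variance of the variable.
#'
#' @param object An `empirical_variogram`.
#' @param fit Optional `variogram_fit` drawn as a curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.empirical_variogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$h, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$np), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::geom_hline(yintercept = attr(object, "variance"),
                        linetype = 2, colour = "grey40")
  if (!is.null(fit)) {
    grid <- tibble::tibble(h = seq(0, max(object$h), length.out = 200))
    grid$gamma <- variogram_predict(fit$model,
                                    c(c0 = fit$c0, c = fit$c, a = fit$a),
                                    grid$h)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p + ggplot2::labs(x = "Lag distance h (m)",
                    y = expression(gamma(h)),
                    title = attr(object, "metric") %||% "semivariogram")
}

#' Plot variance-partition fractions
#'
#' @param object A `varpart_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of the percentage fractions.
#' @export
autoplot.varpart_fit <- function(object, ...) {
  fr <- object$fractions[object$fractions$fraction != "abc", ]
  fr$fraction <- factor(fr$fraction, levels = c("a", "b", "c", "d"),
                        labels = c("[a] pure environment",
                                   "[b] spatially structured env.",
                                   "[c] pure space", "[d] residual"))
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$fraction, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of variance") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
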