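# ggplot2 front-ends for the map and model objects.

raster_gg <- function(tb, fill, name) {
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = name) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a functional diversity map
#'
#' @param object An `fd_map`.
#' @param layer `"fric"`, `"feve"` or `"n_points"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fd_map <- function(object, layer = c("fric", "feve", "n_points"),
                            ...) {
  layer <- match.arg(layer)
  raster_gg(tidy.fd_map(object), layer,
            c(fric = "functional\nrichness", feve = "functional\nevenness",
              n_points = "points")[layer])
}

#' Plot a drought response map
#'
#' @param object A `drought_response`.
#' @param layer `"resistance"`, `"recovery"` or `"resilience"`.
#' @param ... Unused.
#' @return A ggplot (response rendered in percent).
#' @export
autoplot.drought_response <- function(object,
                                      layer = c("resistance", "recovery",
                                                "resilience"), ...) {
  layer <- match.arg(layer)
  tb <- tidy.drought_response(object)
  tb[[layer]] <- 100 * tb[[layer]]
  raster_gg(tb, layer, paste0(layer, " (%)"))
}

#' Plot a binned series with the selected univariate fit
#'
#' @param object A `bef_unifit`.
#' @param ... Unused.
#' @return A ggplot: bin means sized by pixel count, with the chosen model's
#'   curve.
#' @export
autoplot.bef_unifit <- function(object, ...) {
  fit <- object$fits[[object$chosen]]
  d <- fit$model
  d$x <- d$x %||% exp(d[[2]]) # defensive; x is present for all forms
  grid <- data.frame(x = seq(min(d$x), max(d$x), length.out = 200))
  grid$yhat <- predict(fit, newdata = grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$`(weights)`),
                        alpha = 0.4, show.legend = FALSE) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$yhat),
                       color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "diversity (rescaled bin center)",
                  y = "mean drought response",
                  subtitle = sprintf("%s fit, r2 = %.3f", object$chosen,
                                     object$r2[object$chosen])) +
    ggplot2::theme_minimal()
}

#' Bar chart of sequential sum-of-squares percentages
#'
#' @param object A `bef_anova` (optionally after [conservative_f()]).
#' @param ... Unused.
#' @return A ggplot of each term's share of total SS (increments of multiple
#'   r-squared x 100).
#' @export
autoplot.bef_anova <- function(object, ...) {
  tb <- object$table[object$table$term != "Residuals", ]
  tb$term <- factor(tb$term, levels = rev(tb$term))
  ggplot2::ggplot(tb, ggplot2::aes(x = 100 * .data$r2_increment,
                                   y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "% of total SS (r2 increment x 100)", y = NULL,
                  subtitle = sprintf("%s: model r2 = %.3f", object$response,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}
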