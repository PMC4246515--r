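#' Plot a leaf growth fit
#'
#' Measured points with the fitted beta sigmoid curve and the fitted
#' parameters annotated in the subtitle.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- object$params
  grid <- tibble::tibble(t = seq(min(object$data$t, p$t0),
                                 max(object$data$t, p$te),
                                 length.out = 200))
  grid$length <- beta_length(p, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t,
                                            y = .data$length)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Thermal time (°Cd)", y = "Leaf length (mm)",
      title = "Beta sigmoid growth fit",
      subtitle = sprintf(
        "Lm = %.1f mm, tm = %.1f, te = %.1f °Cd, R² = %.4f",
        p$Lm, p$tm, p$te, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a cell-length profile fit
#'
#' @param object A `cell_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_fit
#' @export
autoplot.cell_fit <- function(object, ...) {
  pp <- object$data$position
  grid <- tibble::tibble(position = seq(min(pp), max(pp),
                                        length.out = 300))
  fn <- if (object$family == "beta") cell_length_at else sigmoid_at
  grid$cell_length <- fn(object$params, grid$position)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$position,
                               y = .data$cell_length)) +
    ggplot2::geom_line(data = grid, colour = "darkgreen") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "Position from leaf base (mm)",
                  y = "Cell length (µm)",
                  title = sprintf("Cell-length profile fit (%s)",
                                  object$family),
                  subtitle = sprintf("R² = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the elongation-rate curve of a growth fit
#'
#' The bell-shaped LER curve with the empirical finite-difference rates
#' overlaid, LERmax marked at `tm`.
#'
#' @param fit A `growth_fit`.
#' @return A ggplot object.
#' @export
plot_ler <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  p <- fit$params
  grid <- tibble::tibble(t = seq(p$t0, p$te, length.out = 300))
  grid$ler <- beta_rate(p, grid$t)
  emp <- empirical_ler(fit$data)
  mr <- beta_max_rate(p)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$ler)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = emp,
                        ggplot2::aes(x = .data$t_mid, y = .data$ler),
                        shape = 1) +
    ggplot2::annotate("point", x = mr$tm, y = mr$lermax,
                      colour = "firebrick") +
    ggplot2::labs(x = "Thermal time (°Cd)",
                  y = "LER (mm/°Cd)",
                  title = "Leaf elongation rate",
                  subtitle = sprintf(
                    "LERmax = %.2f mm/°Cd at tm = %.1f °Cd",
                    mr$lermax, mr$tm)) +
    ggplot2::theme_minimal()
}
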