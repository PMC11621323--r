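# ggplot2 visualisations for the main result types.

#' Plot a family of structure-factor curves
#'
#' @param curves named list of tibbles with columns `q`, `S` (names used as
#'   the legend, e.g. temperatures)
#' @param q_iso optional isosbestic wavevector to mark
#' @return a ggplot
#' @export
plot_sq_curves <- function(curves, q_iso = NULL) {
  if (is.null(names(curves))) names(curves) <- paste0("curve ", seq_along(curves))
  d <- purrr::imap_dfr(curves, function(cv, nm) {
    tibble(q = cv$q, S = cv$S, curve = nm)
  })
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$S,
                                       colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "S(q)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(q_iso) && is.finite(q_iso)) {
    p <- p + ggplot2::geom_vline(xintercept = q_iso, linetype = "dashed")
  }
  p
}

#' @export
autoplot.saxs_fit <- function(object, curve = NULL, n_grid = 400L, ...) {
  qr <- if (is.null(curve)) object$fit_window else range(curve$q)
  grid <- seq(qr[1], qr[2], length.out = n_grid)
  d <- tibble(
    q = rep(grid, 3),
    S = c(saxs_model(grid, object$R, object$eta, object$SA0, object$xi),
          percus_yevick_sq(grid, object$R, object$eta),
          ornstein_zernike(grid, object$SA0, object$xi)),
    component = rep(c("total", "normal (PY)", "anomalous (OZ)"), each = n_grid))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$S,
                                       linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "S(q)", linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_point(
      data = tibble(q = curve$q, S = curve$S),
      mapping = ggplot2::aes(x = .data$q, y = .data$S),
      inherit.aes = FALSE, alpha = 0.5, size = 0.8)
  }
  p
}

#' @export
autoplot.powerlaw_fit <- function(object, n_grid = 400L, ...) {
  d <- object$data
  grid <- seq(min(d$T), max(d$T), length.out = n_grid)
  eps <- (grid - object$T_s) / object$T_s
  fitline <- tibble(T = grid, value = object$amplitude * eps^(-object$exponent))
  ylab <- if (object$quantity == "kappa") expression(kappa[T]) else expression(xi ~ (ring(A)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$T, y = .data$value)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_line(data = fitline) +
    ggplot2::labs(x = "T (K)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cooling_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::transmute(object, time_ms = .data$time * 1e3,
                     `temperature (K)` = .data$temperature,
                     `radius (um)` = .data$radius_um,
                     `chi_g` = .data$chi_g),
    -"time_ms")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "flight time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an LSI population series with its crossing temperature
#'
#' @param series tibble with columns `T`, `fraction_hdl`, `fraction_ldl`
#' @param T_cross optional crossing temperature to mark
#' @return a ggplot
#' @export
plot_lsi_populations <- function(series, T_cross = NULL) {
  d <- tidyr::pivot_longer(series[, c("T", "fraction_hdl", "fraction_ldl")],
                           -"T", names_to = "population",
                           values_to = "fraction")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$T, y = .data$fraction,
                                       colour = .data$population)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "T (K)", y = "population fraction", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(T_cross) && is.finite(T_cross)) {
    p <- p + ggplot2::geom_vline(xintercept = T_cross, linetype = "dashed")
  }
  p
}
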