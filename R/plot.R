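#' Plot a benchmark error grid
#'
#' Mean localization error against SNR on log-log axes, one line per
#' method, faceted by particle radius (or by separation for overlap grids).
#' Error bars show one standard deviation (precision).
#'
#' @param object a `csym_grid` tibble from [run_grid()] or
#'   [run_overlap_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot csym_grid
#' @export
autoplot.csym_grid <- function(object, ...) {
  facet_var <- if ("separation_L" %in% names(object) &&
                   length(unique(object$separation_L)) > 1)
    "separation_L" else "radius"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$snr, y = .data$mean_error,
                               colour = .data$method,
                               group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_error - .data$sd_error, 1e-4),
                   ymax = .data$mean_error + .data$sd_error),
      width = 0.05, alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(facet_var, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "SNR", y = "mean error (px)", colour = "method")
}

#' Plot the symmetry profiles of a C-Sym localization
#'
#' Shows the discrete symmetry profiles `Sym_X` and `Sym_Y` (points), their
#' Hermite-interpolated continua (lines) and the refined subpixel center
#' (vertical line) for each axis.
#'
#' @param object a `csym_loc` from [locate_csym()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot csym_loc
#' @export
autoplot.csym_loc <- function(object, ...) {
  prof <- object$profiles
  pts <- dplyr::bind_rows(
    tibble(axis = "x", pos = prof$xs, value = prof$sym_x),
    tibble(axis = "y", pos = prof$ys, value = prof$sym_y))
  centers <- tibble(axis = c("x", "y"), center = c(object$x, object$y))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = centers,
                        ggplot2::aes(xintercept = .data$center),
                        linetype = 2, colour = "red") +
    ggplot2::facet_wrap("axis", scales = "free_x") +
    ggplot2::labs(x = "candidate position (px)", y = "symmetry correlation")
  if (!is.null(object$curves$x)) {
    crv <- dplyr::bind_rows(
      tibble(axis = "x", pos = object$curves$x$x, value = object$curves$x$y),
      tibble(axis = "y", pos = object$curves$y$x, value = object$curves$y$y))
    p <- p + ggplot2::geom_line(data = crv, alpha = 0.6)
  }
  p
}

#' Plot a fixed-period sinusoid fit
#'
#' Tracked displacements (points) with the fitted sinusoid (line), for the
#' first few periods.
#'
#' @param object a `sinusoid_fit` from [fit_sinusoid()].
#' @param n_show number of leading frames to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sinusoid_fit
#' @export
autoplot.sinusoid_fit <- function(object, n_show = 400L, ...) {
  d <- utils::head(object$data, n_show)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$displacement), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "frame", y = "displacement (px)")
}

#' Plot a projection calibration
#'
#' Calibration pairs and the fitted 5th-degree projection polynomial.
#'
#' @param object a `calibration_model` from [calibrate_projection()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  grid <- tibble(a = seq(min(object$data$a), max(object$data$a),
                         length.out = 256))
  grid$D_hat <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$a)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$D)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$D_hat),
                       colour = "red") +
    ggplot2::labs(x = "measured amplitude a (px)",
                  y = "real displacement D (nm)")
}
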