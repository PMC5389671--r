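#' Fit a fixed-period sinusoid to a displacement series
#'
#' Least-squares fit of
#' \deqn{f(i) = a \sin(2\pi i / b + 2\pi / c) + d}
#' to tracked positions, with the period `b` held fixed (it is known from
#' the camera sampling speed and the stage oscillation period, not fitted).
#' With `b` fixed the model is linear in `(a sin phase, a cos phase, d)`
#' via the harmonic-addition identity, so the fit is an exact closed-form
#' linear least squares — no starting values and no convergence issues.
#' The amplitude is reported nonnegative, absorbing the sign into the phase.
#'
#' @param data a data frame with columns `frame` (or `i`) and
#'   `displacement` (px); at least two periods of data are required.
#' @param period_b the fixed period in frames.
#' @return an object of class `sinusoid_fit`: amplitude `a` (px), period
#'   `b`, phase parameter `c` (such that the phase offset is `2*pi/c`),
#'   offset `d`, phase in radians, `residual` (RMS), `degenerate` flag and
#'   the data with fitted values.
#' @examples
#' i <- 0:1999
#' y <- 3 * sin(2 * pi * i / 500 + 2 * pi / 4) + 10
#' fit_sinusoid(data.frame(frame = i, displacement = y), period_b = 500)
#' @export
fit_sinusoid <- function(data, period_b) {
  stopifnot(is.data.frame(data), period_b > 0)
  i <- if ("frame" %in% names(data)) data$frame else data$i
  y <- data$displacement
  stopifnot(is.numeric(i), is.numeric(y), length(i) == length(y))
  if (diff(range(i)) < 2 * period_b)
    stop("need at least two periods of data", call. = FALSE)
  theta <- 2 * pi * i / period_b
  degenerate <- sd(y) == 0
  if (degenerate) {
    a <- 0; phase <- 0; d <- mean(y); fitted <- rep(d, length(y))
  } else {
    X <- cbind(sin(theta), cos(theta), 1)
    beta <- qr.solve(X, y)
    a <- sqrt(beta[1]^2 + beta[2]^2)
    phase <- atan2(beta[2], beta[1])
    d <- beta[3]
    fitted <- as.vector(X %*% beta)
  }
  structure(
    list(a = a, b = period_b, c = if (phase != 0) 2 * pi / phase else Inf,
         d = d, phase = phase,
         residual = sqrt(mean((y - fitted)^2)),
         degenerate = degenerate,
         data = tibble(frame = i, displacement = y, fitted = fitted)),
    class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> a = %.6g px, b = %g (fixed), phase = %.4g rad, d = %.6g, RMS residual %.3g%s\n",
    x$a, x$b, x$phase, x$d, x$residual,
    if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @rdname fit_sinusoid
#' @param x a `sinusoid_fit`.
#' @param ... unused.
#' @method tidy sinusoid_fit
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c", "d"),
         estimate = c(x$a, x$b, x$c, x$d),
         fixed = c(FALSE, TRUE, FALSE, FALSE))
}

#' @rdname fit_sinusoid
#' @method glance sinusoid_fit
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble(amplitude = x$a, period = x$b, offset = x$d,
         rms_residual = x$residual, n = nrow(x$data),
         degenerate = x$degenerate)
}

#' Sinusoidal oscillation tracking experiment on synthetic stacks
#'
#' Emulates the piezo-stage amplitude experiment: a particle oscillates
#' sinusoidally along x with known amplitude; each frame is rendered at the
#' exact continuous position (no pixel resampling), noise is injected at the
#' target SNR, a locator tracks the particle per frame, and the tracked
#' x-positions are fitted with [fit_sinusoid()] at the known period.
#'
#' @param amplitudes true oscillation amplitudes in px.
#' @param method locator, see [locate_particle()].
#' @param n_frames frames per stack (covering `n_frames / period` periods).
#' @param period oscillation period in frames (fixed in the fit).
#' @param radius particle radius in px.
#' @param snr per-frame SNR.
#' @param seed master seed.
#' @param width,height frame size; sized to hold the largest amplitude.
#' @param pattern pattern family; the default `"airy"` diffraction-limited
#'   bead image keeps subpixel locking well below the smallest amplitudes.
#' @return a tibble with one row per amplitude: `amplitude`, `a_hat`,
#'   `abs_error`, `rel_error`, `n_frames`, `failures`.
#' @export
run_sinusoid_experiment <- function(amplitudes, method = "csym",
                                    n_frames = 400L, period = 50,
                                    radius = 12, snr = 50, seed = 1L,
                                    width = NULL, height = NULL,
                                    pattern = "airy") {
  amax <- max(amplitudes)
  ext <- particle_extent(particle_spec(pattern, radius,
                                       center = c(radius * 2, radius * 2)))
  need <- ceiling(1.2 * ext) + 2 * ceiling(amax) + 16
  if (is.null(width)) width <- max(64L, as.integer(need))
  if (is.null(height)) height <- max(64L, as.integer(ceiling(1.2 * ext) + 16))
  seeds <- derive_seeds(seed, length(amplitudes))
  purrr::map_dfr(seq_along(amplitudes), function(k) {
    a <- amplitudes[k]
    i <- seq_len(n_frames) - 1L
    x0 <- (width + 1) / 2
    y0 <- (height + 1) / 2
    traj <- tibble(frame = i,
                   x = x0 + a * sin(2 * pi * i / period),
                   y = y0)
    stack <- make_motion_stack(traj, radius = radius, pattern = pattern,
                               width = width, height = height,
                               snr = snr, seed = seeds[k])
    xs <- purrr::map_dbl(stack, function(s) {
      loc <- locate_particle(s, method)
      if (isTRUE(loc$converged)) loc$x else NA_real_
    })
    ok <- is.finite(xs)
    fit <- fit_sinusoid(tibble(frame = i[ok], displacement = xs[ok]),
                        period_b = period)
    tibble(amplitude = a, a_hat = fit$a,
           abs_error = abs(fit$a - a),
           rel_error = abs(fit$a - a) / a,
           n_frames = sum(ok), failures = sum(!ok))
  })
}

#' Polynomial calibration from image amplitude to real displacement
#'
#' Imaging systems map real-space displacement to image-space amplitude
#' nonlinearly (plane misalignment, lens aberration); this models the
#' projection as a 5th-degree polynomial
#' \deqn{D = p_6 a^5 + p_5 a^4 + p_4 a^3 + p_3 a^2 + p_2 a + p_1,}
#' with `D` the real amplitude (nm) and `a` the measured image amplitude
#' (px), fitted by least squares to calibration pairs.  Reports the relative
#' projection error (mean and max of `|D_hat - D| / D`), the correlation
#' with the ground truth, and a numerical check that the fitted projection
#' is monotone over the calibrated amplitude range.
#'
#' @param pairs a data frame with columns `a` (px) and `D` (nm); at least 6
#'   pairs are required to determine the 6 coefficients.
#' @return an object of class `calibration_model` with coefficients
#'   `p` (`p1` ... `p6`), `rel_error_mean`, `rel_error_max`, `correlation`,
#'   `monotone`, and the training data with fitted values.
#' @export
calibrate_projection <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("a", "D") %in% names(pairs)))
  a <- pairs$a; D <- pairs$D
  if (length(a) < 6) stop("need at least 6 calibration pairs", call. = FALSE)
  fit <- lm(D ~ poly(a, 5, raw = TRUE))
  if (any(is.na(coef(fit))))
    stop("rank-deficient calibration design", call. = FALSE)
  Dhat <- unname(fitted(fit))
  rel <- abs(Dhat - D) / abs(D)
  grid <- seq(min(a), max(a), length.out = 512)
  dgrid <- unname(predict(fit, newdata = data.frame(a = grid)))
  structure(
    list(p = stats::setNames(unname(coef(fit)), paste0("p", 1:6)),
         rel_error_mean = mean(rel), rel_error_max = max(rel),
         correlation = cor(Dhat, D),
         monotone = all(diff(dgrid) > 0) || all(diff(dgrid) < 0),
         data = tibble(a = a, D = D, D_hat = Dhat)),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> degree-5 projection, mean rel. error %.3g%%, max %.3g%%, cor %.6f%s\n",
    100 * x$rel_error_mean, 100 * x$rel_error_max, x$correlation,
    if (x$monotone) "" else "  [NOT monotone]"))
  invisible(x)
}

#' Predict real displacement from measured image amplitude
#'
#' @param object a `calibration_model`.
#' @param newdata data frame with column `a`, or a numeric vector of
#'   amplitudes.
#' @param ... unused.
#' @return predicted real amplitudes `D` (nm).
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  a <- if (is.data.frame(newdata)) newdata$a else newdata
  p <- object$p
  p[["p1"]] + p[["p2"]] * a + p[["p3"]] * a^2 + p[["p4"]] * a^3 +
    p[["p5"]] * a^4 + p[["p6"]] * a^5
}

#' @rdname calibrate_projection
#' @param x a `calibration_model`.
#' @param ... unused.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(term = names(x$p), estimate = unname(x$p))
}

#' @rdname calibrate_projection
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(rel_error_mean = x$rel_error_mean,
         rel_error_max = x$rel_error_max,
         correlation = x$correlation, monotone = x$monotone,
         n = nrow(x$data))
}
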