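# Crop an ROI of odd side n around an integer guess, clamped to the image.
crop_roi <- function(px, guess, n) {
  n <- as.integer(n)
  h <- (n - 1L) %/% 2L
  cx <- as.integer(round(guess[1])); cy <- as.integer(round(guess[2]))
  x0 <- max(1L, cx - h); x1 <- min(ncol(px), cx + h)
  y0 <- max(1L, cy - h); y1 <- min(nrow(px), cy + h)
  if (x1 - x0 < 2L || y1 - y0 < 2L)
    stop("ROI does not fit inside the image", call. = FALSE)
  list(roi = px[y0:y1, x0:x1, drop = FALSE], x0 = x0, y0 = y0)
}

# Flip a dark-on-bright ROI so the particle mass is bright; locators that
# assume a bright particle (CoM, GFit initialization) use this polarity.
roi_polarity <- function(roi) {
  med <- median(roi)
  if (max(roi) - med >= med - min(roi)) 1 else -1
}

new_loc <- function(method, x, y, converged, extra = list()) {
  structure(c(list(x = x, y = y, converged = converged, method = method),
              extra),
            class = "particle_loc")
}

#' Center-of-mass (threshold centroid) locator
#'
#' The classical baseline: threshold the ROI into a binary mask and return
#' the intensity-weighted centroid of the above-threshold pixels, weighting
#' each pixel by its background-subtracted intensity.  Polarity is detected
#' from the ROI (a dark particle on a bright background is flipped before
#' thresholding).  The default threshold is Otsu's level computed within the
#' ROI; pass `threshold` (a fraction of the ROI dynamic range in `(0, 1)`)
#' for a fixed level.
#'
#' @param image numeric matrix or `scene_image`.
#' @param guess integer `(x, y)` initial estimate (defaults to the scene's).
#' @param roi_size odd ROI side in pixels (defaults as in [locate_csym()]).
#' @param threshold optional fixed relative threshold in `(0, 1)`.
#' @return a `particle_loc` with `method = "com"`.
#' @export
locate_com <- function(image, guess = NULL, roi_size = NULL,
                       threshold = NULL) {
  px <- scene_pixels(image)
  if (is.null(guess) && inherits(image, "scene_image"))
    guess <- image$initial_guess
  if (is.null(roi_size) && inherits(image, "scene_image"))
    roi_size <- default_roi_size(image$truth)
  cr <- crop_roi(px, guess, roi_size)
  roi <- cr$roi * roi_polarity(cr$roi)
  rng <- range(roi)
  if (rng[2] - rng[1] <= 0)
    return(new_loc("com", NA_real_, NA_real_, FALSE))
  u <- (roi - rng[1]) / (rng[2] - rng[1])
  thr <- if (is.null(threshold)) {
    stopifnot(requireNamespace("EBImage", quietly = TRUE))
    EBImage::otsu(u, range = c(0, 1))
  } else {
    stopifnot(threshold > 0, threshold < 1)
    threshold
  }
  mask <- u > thr
  if (!any(mask)) return(new_loc("com", NA_real_, NA_real_, FALSE))
  w <- (u - thr) * mask
  cols <- col(roi); rows <- row(roi)
  sx <- sum(w * cols) / sum(w)
  sy <- sum(w * rows) / sum(w)
  new_loc("com", cr$x0 + sx - 1, cr$y0 + sy - 1, TRUE,
          list(threshold = thr, n_mask = sum(mask)))
}

# Symmetry center of a 1-D profile from cross-correlation with its own
# reverse: the correlation over lag l peaks where the profile maps onto
# itself under reflection, i.e. at symmetry center (n + 1 + l) / 2.  The
# peak lag is refined with a 3-point quadratic fit, giving subpixel output.
profile_symmetry_center <- function(p, max_lag = NULL) {
  n <- length(p)
  p <- p - mean(p)
  if (sd(p) == 0) return(NA_real_)
  if (is.null(max_lag)) max_lag <- max(4L, ceiling(n / 4))
  lags <- (-max_lag):max_lag
  cc <- vapply(lags, function(l) {
    i <- seq_len(n)
    j <- n + 1L - i + l
    ok <- j >= 1L & j <= n
    sum(p[i[ok]] * p[j[ok]]) / sum(ok)
  }, numeric(1))
  k <- which.max(cc)
  if (k == 1L || k == length(lags)) return(NA_real_)
  # 3-point quadratic refinement of the peak lag
  denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
  delta <- if (denom < 0) 0.5 * (cc[k - 1] - cc[k + 1]) / denom else 0
  l_hat <- lags[k] + delta
  (n + 1 + l_hat) / 2
}

#' One-dimensional cross-correlation symmetry locator
#'
#' Projects the ROI onto its X and Y axes (column and row means) and finds,
#' per axis, the reflection point about which the projection best correlates
#' with its own mirror image; the peak lag of the cross-correlation between
#' the profile and its reverse is refined with a 3-point quadratic fit and
#' converted to a subpixel symmetry center (half-lag resolution).
#'
#' @inheritParams locate_com
#' @return a `particle_loc` with `method = "xcorr"`.
#' @export
locate_xcorr <- function(image, guess = NULL, roi_size = NULL) {
  px <- scene_pixels(image)
  if (is.null(guess) && inherits(image, "scene_image"))
    guess <- image$initial_guess
  if (is.null(roi_size) && inherits(image, "scene_image"))
    roi_size <- default_roi_size(image$truth)
  cr <- crop_roi(px, guess, roi_size)
  sx <- profile_symmetry_center(colMeans(cr$roi))
  sy <- profile_symmetry_center(rowMeans(cr$roi))
  if (!is.finite(sx) || !is.finite(sy))
    return(new_loc("xcorr", NA_real_, NA_real_, FALSE))
  new_loc("xcorr", cr$x0 + sx - 1, cr$y0 + sy - 1, TRUE)
}

#' Two-dimensional Gaussian fit locator
#'
#' Fits the elliptical Gaussian intensity model
#' \deqn{I(x, y) = b + g_0 \exp\{-((x-\mu_x)^2/\sigma_x^2 +
#'       (y-\mu_y)^2/\sigma_y^2)\}}
#' to the ROI by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nlsLM()]) and returns \eqn{(\mu_x, \mu_y)}.  Starting
#' values come from the guess, the ROI median (background) and second
#' moments (widths); polarity is detected so dark particles fit a negative
#' amplitude.  This is the maximum-likelihood locator when the particle
#' truly is Gaussian; on ring-shaped diffraction patterns the model is
#' misspecified and accuracy degrades.
#'
#' @inheritParams locate_com
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return a `particle_loc` with `method = "gfit"`, carrying the fitted
#'   `pars` (`bg`, `g0`, `mu_x`, `mu_y`, `sigma_x`, `sigma_y`).
#' @export
locate_gfit <- function(image, guess = NULL, roi_size = NULL,
                        max_iter = 100L) {
  px <- scene_pixels(image)
  if (is.null(guess) && inherits(image, "scene_image"))
    guess <- image$initial_guess
  if (is.null(roi_size) && inherits(image, "scene_image"))
    roi_size <- default_roi_size(image$truth)
  cr <- crop_roi(px, guess, roi_size)
  roi <- cr$roi
  df <- data.frame(z = as.vector(roi),
                   x = as.vector(col(roi)), y = as.vector(row(roi)))
  bg0 <- median(roi)
  pol <- roi_polarity(roi)
  g00 <- if (pol > 0) max(roi) - bg0 else min(roi) - bg0
  if (g00 == 0) g00 <- 1e-3
  s0 <- max(2, min(nrow(roi), ncol(roi)) / 5)
  start <- list(bg = bg0, g0 = g00,
                mx = unname(guess[1]) - cr$x0 + 1,
                my = unname(guess[2]) - cr$y0 + 1,
                sx = s0, sy = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ bg + g0 * exp(-((x - mx)^2 / sx^2 + (y - my)^2 / sy^2)),
      data = df, start = start,
      lower = c(-Inf, -Inf, 1, 1, 0.5, 0.5),
      upper = c(Inf, Inf, ncol(roi), nrow(roi), 10 * s0, 10 * s0),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new_loc("gfit", NA_real_, NA_real_, FALSE))
  p <- coef(fit)
  # a center pinned to the ROI boundary is a failed fit, not a location
  if (p[["mx"]] <= 1 + 1e-6 || p[["mx"]] >= ncol(roi) - 1e-6 ||
      p[["my"]] <= 1 + 1e-6 || p[["my"]] >= nrow(roi) - 1e-6)
    return(new_loc("gfit", NA_real_, NA_real_, FALSE))
  new_loc("gfit", cr$x0 + p[["mx"]] - 1, cr$y0 + p[["my"]] - 1, TRUE,
          list(pars = c(bg = p[["bg"]], g0 = p[["g0"]],
                        mu_x = cr$x0 + p[["mx"]] - 1,
                        mu_y = cr$y0 + p[["my"]] - 1,
                        sigma_x = p[["sx"]], sigma_y = p[["sy"]])))
}

#' Locate a particle with a named method
#'
#' Dispatcher used by the benchmark protocols.  Built-in methods are
#' `"csym"` ([locate_csym()]), `"com"`, `"xcorr"` and `"gfit"`; a function
#' `f(image, guess, roi_size, ...)` returning a `particle_loc` may be passed
#' directly as a plug-in (e.g. an external quadrant-interpolation or
#' circular-Hough locator).
#'
#' @param image numeric matrix or `scene_image`.
#' @param method method name or plug-in function.
#' @param guess,roi_size as in [locate_csym()].
#' @param ... passed to the underlying locator.
#' @return a `particle_loc`.
#' @export
locate_particle <- function(image, method = "csym", guess = NULL,
                            roi_size = NULL, ...) {
  if (is.function(method))
    return(method(image, guess = guess, roi_size = roi_size, ...))
  switch(match.arg(method, c("csym", "com", "xcorr", "gfit")),
         csym = locate_csym(image, guess, roi_size, ...),
         com = locate_com(image, guess, roi_size, ...),
         xcorr = locate_xcorr(image, guess, roi_size, ...),
         gfit = locate_gfit(image, guess, roi_size, ...))
}
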