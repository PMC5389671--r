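#' Parametric description of one synthetic particle
#'
#' A `particle_spec` captures everything needed to render a single radially
#' symmetric particle: the pattern family, its size, intensity amplitude,
#' polarity and anisotropic stretch, and the (possibly subpixel) ground-truth
#' center.
#'
#' Pattern families:
#' \describe{
#'   \item{`"rings"`}{an Airy-like diffraction pattern, the squared first-order
#'     Bessel profile \eqn{(2 J_1(kr)/(kr))^2} with \eqn{k} chosen so the first
#'     dark ring lies at `radius` pixels.}
#'   \item{`"gaussian"`}{an isotropic 2-D Gaussian with
#'     \eqn{\sigma_x = \sigma_y =} `radius` (a fluorescent point-spread
#'     surrogate), intensity `amplitude`
#'     \eqn{\cdot \exp(-((x-\mu_x)^2/\sigma_x^2 + (y-\mu_y)^2/\sigma_y^2))}.}
#'   \item{`"spot"`}{a compact smooth bump, `amplitude`
#'     \eqn{\cdot \cos^2(\pi r / 2R)} for \eqn{r \le R}, zero outside.}
#' }
#'
#' Coordinates are 1-based with `x` the column and `y` the row; integer
#' coordinates sit at pixel centers, subpixel positions are reals in the same
#' frame.
#'
#' @param pattern one of `"rings"`, `"airy"`, `"gaussian"`, `"spot"`.
#' @param radius particle radius in pixels (> 0); for `"gaussian"` this is the
#'   standard deviation \eqn{\sigma}.
#' @param center numeric length-2 `(x, y)` ground-truth center in pixels.
#' @param amplitude peak intensity above background, in `(0, 1]`.
#' @param inverted logical; `TRUE` renders a dark particle on a brighter
#'   background (color inversion).
#' @param stretch positive length-2 multiplier of the radial coordinate along
#'   x and y (profile scaling/stretching).
#' @return an object of class `particle_spec`.
#' @seealso [render_particle()], [make_trial()]
#' @export
particle_spec <- function(pattern = c("rings", "airy", "gaussian", "spot"),
                          radius, center, amplitude = 0.5,
                          inverted = FALSE, stretch = c(1, 1)) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius),
            is.numeric(center), length(center) == 2L, all(is.finite(center)),
            is.numeric(amplitude), length(amplitude) == 1L,
            is.logical(inverted), length(inverted) == 1L,
            is.numeric(stretch), length(stretch) == 2L, all(stretch > 0))
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (amplitude <= 0 || amplitude > 1)
    stop("`amplitude` must lie in (0, 1]", call. = FALSE)
  structure(
    list(pattern = pattern, radius = radius,
         center = c(x = unname(center[1]), y = unname(center[2])),
         amplitude = amplitude, inverted = inverted,
         stretch = c(x = unname(stretch[1]), y = unname(stretch[2]))),
    class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s, radius %.3g px, center (%.3f, %.3f), amplitude %.3g%s\n",
              x$pattern, x$radius, x$center[["x"]], x$center[["y"]],
              x$amplitude, if (x$inverted) ", inverted" else ""))
  invisible(x)
}

#' Nominal visible extent of a particle, in pixels
#'
#' The diameter used when sizing regions of interest: twice the radius for
#' `"rings"` (up to the first dark ring) and `"spot"`, and four standard
#' deviations for `"gaussian"` (the visually apparent diameter).
#'
#' @param spec a [particle_spec()].
#' @return a length-1 numeric, pixels.
#' @export
particle_extent <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  switch(spec$pattern,
         gaussian = 4 * spec$radius,
         2 * spec$radius)
}

#' Rayleigh limit of a diffraction pattern
#'
#' The classical two-point resolution distance, defined here as the radius of
#' the first dark ring of the rendered profile: `radius` itself for the
#' `"airy"` family (by construction of its Bessel argument) and the fixed
#' 5 px ring period for the multi-ring `"rings"` family.
#'
#' @param spec a [particle_spec()] with a ringed pattern.
#' @return the Rayleigh limit L in pixels.
#' @export
rayleigh_limit <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  switch(spec$pattern,
         airy = spec$radius,
         rings = .ring_period,
         stop("Rayleigh limit is defined for ringed patterns", call. = FALSE))
}

new_scene_image <- function(pixels, background, truth, initial_guess = NULL,
                            noise_sigma = 0, target_snr = NA_real_,
                            noiseless_range = range(pixels), extra = list()) {
  structure(
    c(list(pixels = pixels,
           width = ncol(pixels), height = nrow(pixels),
           background = background, truth = truth,
           initial_guess = initial_guess,
           noise_sigma = noise_sigma, target_snr = target_snr,
           noiseless_range = noiseless_range),
      extra),
    class = "scene_image")
}

#' @export
print.scene_image <- function(x, ...) {
  cat(sprintf("<scene_image> %d x %d px, background %.3f, noise sigma %.4g%s\n",
              x$width, x$height, x$background, x$noise_sigma,
              if (is.finite(x$target_snr)) sprintf(" (SNR %.3g)", x$target_snr) else ""))
  print(x$truth)
  if (!is.null(x$initial_guess))
    cat(sprintf("  initial guess (%d, %d)\n",
                as.integer(x$initial_guess[1]), as.integer(x$initial_guess[2])))
  invisible(x)
}

# Accept either a scene_image or a bare matrix wherever an image is expected.
scene_pixels <- function(image) {
  if (inherits(image, "scene_image")) image$pixels
  else if (is.matrix(image) && is.numeric(image)) image
  else stop("`image` must be a numeric matrix or a scene_image", call. = FALSE)
}
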