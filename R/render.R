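# First zero of the Bessel function J1; fixes the Airy first dark ring.
.j1_first_zero <- 3.831705970207512

# Diffraction ring period of a "rings" particle in pixels (set by the
# imaging optics, not the bead size: roughly wavelength/NA at typical
# magnification) and the width of the intensity falloff at the bead rim
# (the optical edge response, about half a ring period).
.ring_period <- 5
.rim_width <- 2.5

# Radial intensity profile of each pattern family, amplitude 1 at r = 0.
radial_profile <- function(pattern, r, radius) {
  switch(pattern,
    rings = {
      env <- (1 + tanh((radius - r) / .rim_width)) /
             (1 + tanh(radius / .rim_width))
      env * cos(pi * r / .ring_period)
    },
    airy = {
      k <- .j1_first_zero / radius
      x <- k * r
      out <- numeric(length(x))
      nz <- x > .Machine$double.eps
      out[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
      out[!nz] <- 1
      out
    },
    gaussian = exp(-(r / radius)^2),
    spot = {
      out <- numeric(length(r))
      inside <- r < radius
      out[inside] <- cos(pi * r[inside] / (2 * radius))^2
      out
    },
    stop("unknown pattern: ", pattern, call. = FALSE))
}

#' Render a noiseless synthetic particle image
#'
#' Evaluates the particle's radial profile at every pixel center of a
#' `width` x `height` frame on top of a uniform background.  For
#' `pattern = "gaussian"` the pixel at `(x, y)` has intensity exactly
#' \deqn{b + g_0 \exp\{-((x-\mu_x)^2/\sigma_x^2 + (y-\mu_y)^2/\sigma_y^2)\},}
#' the standard fluorescent point-spread surrogate; `"rings"` is the Airy-like
#' squared Bessel profile (see [particle_spec()]).  Anisotropic `stretch`
#' rescales the radial coordinate per axis; `inverted` subtracts the profile
#' from the background instead of adding it.  The image is exactly
#' mirror-symmetric about the ground-truth center up to pixel sampling.
#'
#' @param spec a [particle_spec()]; its center must sit inside the frame with
#'   a margin of at least `radius`.
#' @param width,height frame size in pixels; each must be at least
#'   `4 * radius` so the frame can contain the particle.
#' @param background uniform background intensity.
#' @return a `scene_image` with `noise_sigma = 0`.
#' @examples
#' sp <- particle_spec("gaussian", radius = 10, center = c(33, 30))
#' sc <- render_particle(sp, 64, 64, background = 0.25)
#' sc$pixels[30, 33]  # 0.25 + 0.5 at the center pixel
#' @export
render_particle <- function(spec, width, height, background = 0.5) {
  stopifnot(inherits(spec, "particle_spec"),
            is.numeric(width), is.numeric(height),
            length(background) == 1L, is.finite(background))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 4 * spec$radius || height < 4 * spec$radius)
    stop("frame must be at least 4 x radius in each dimension", call. = FALSE)
  cx <- spec$center[["x"]]; cy <- spec$center[["y"]]
  if (cx < spec$radius || cx > width - spec$radius + 1 ||
      cy < spec$radius || cy > height - spec$radius + 1)
    stop("particle center must lie inside the frame with margin >= radius",
         call. = FALSE)
  pixels <- background + particle_intensity(spec, width, height)
  new_scene_image(pixels, background = background, truth = spec)
}

# Signed intensity contribution of one particle over the full frame
# (no background), so overlapping particles can be summed before noise.
# The sharp-featured patterns (rings, spot) are integrated over each pixel
# area with a 3x3 midpoint rule, as a camera pixel does; the smooth airy
# and gaussian profiles are point-sampled at pixel centers (the gaussian
# thereby evaluates its closed form exactly).
particle_intensity <- function(spec, width, height) {
  sample_at <- function(ox, oy) {
    dx <- (seq_len(width) + ox - spec$center[["x"]]) / spec$stretch[["x"]]
    dy <- (seq_len(height) + oy - spec$center[["y"]]) / spec$stretch[["y"]]
    r <- sqrt(outer(dy^2, dx^2, `+`))
    a <- radial_profile(spec$pattern, r, spec$radius)
    dim(a) <- c(height, width)
    a
  }
  if (spec$pattern %in% c("rings", "spot")) {
    offs <- c(-1, 0, 1) / 3
    a <- 0
    for (ox in offs) for (oy in offs) a <- a + sample_at(ox, oy)
    a <- a / 9
  } else {
    a <- sample_at(0, 0)
  }
  a <- spec$amplitude * a
  if (spec$inverted) -a else a
}
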