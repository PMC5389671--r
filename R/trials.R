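#' Generate one randomized synthetic localization trial
#'
#' Emulates the randomized test-image design used throughout the benchmark:
#' a 512 x 512 frame with a single particle of the requested radius, uniform
#' random background intensity in `[0.25, 0.75]`, a random floating-point
#' ground-truth center drawn uniformly from the central 50% of the frame,
#' random nuisance variations of the pattern (color inversion with
#' probability 1/2, intensity amplitude in `[0.25, 0.75]`, isotropic profile
#' scaling in `[0.8, 1.2]` times anisotropic stretch in `[0.9, 1.1]` per
#' axis), an integer initial position estimate drawn uniformly from the
#' integers within 2 px of the truth per axis (simulated segmentation
#' error), and additive
#' zero-mean Gaussian noise calibrated to the target SNR
#' (see [add_noise_to_snr()]).  Fully reproducible from `seed`.
#'
#' @param radius particle radius in pixels.
#' @param snr target SNR (> 0), or `Inf` for a noiseless trial.
#' @param pattern pattern family, see [particle_spec()].
#' @param seed integer master seed for the trial.
#' @param width,height frame size in pixels.
#' @param randomize_pattern logical; set `FALSE` to suppress the nuisance
#'   variations (upright pattern, amplitude 0.5, no stretch).
#' @return a `scene_image` with `truth` and `initial_guess` filled in.
#' @export
make_trial <- function(radius, snr, pattern = "rings", seed = NULL,
                       width = 512L, height = 512L,
                       randomize_pattern = TRUE) {
  with_seed(seed, {
    background <- runif(1, 0.25, 0.75)
    center <- c(runif(1, width / 4, 3 * width / 4),
                runif(1, height / 4, 3 * height / 4))
    if (randomize_pattern) {
      spec <- particle_spec(pattern, radius = radius, center = center,
                            amplitude = runif(1, 0.25, 0.75),
                            inverted = runif(1) < 0.5,
                            stretch = runif(1, 0.8, 1.2) * runif(2, 0.9, 1.1))
    } else {
      spec <- particle_spec(pattern, radius = radius, center = center)
    }
    scene <- render_particle(spec, width, height, background)
    scene$initial_guess <- perturbed_guess(center)
    if (is.finite(snr)) scene <- add_noise_to_snr(scene, snr)
    scene
  })
}

# Integer initial estimate within Chebyshev distance 2 of the true center,
# uniform over the qualifying integers per axis (simulated labeling error).
perturbed_guess <- function(center, max_err = 2) {
  g <- vapply(center, function(c1) {
    lo <- ceiling(c1 - max_err); hi <- floor(c1 + max_err)
    if (lo >= hi) lo else sample(lo:hi, 1)
  }, numeric(1))
  c(x = unname(g[1]), y = unname(g[2]))
}

#' Generate a randomized trial with two overlapping diffraction patterns
#'
#' Renders two identical Airy-profile (Bessel-function) particles whose
#' intensities interfere (sum) before noise is added, separated by
#' `separation_L` multiples of the Rayleigh limit L (the first-dark-ring
#' radius, equal to `radius`).  The pair is centered at a random position in
#' the central 50% of the frame with a random orientation; both ground-truth
#' centers are recorded, and the initial guess targets the first particle.
#'
#' @param radius particle radius (= Rayleigh limit L) in pixels.
#' @param separation_L center-to-center distance in multiples of L,
#'   typically in `[1, 3]`.
#' @param snr target SNR, or `Inf` for noiseless.
#' @param seed integer master seed.
#' @param width,height frame size in pixels.
#' @return a `scene_image` whose `truth` is the first particle and which
#'   carries `truth2` (the second particle) and `separation_L`.
#' @export
make_pair_trial <- function(radius, separation_L, snr, seed = NULL,
                            width = 512L, height = 512L) {
  stopifnot(separation_L > 0)
  with_seed(seed, {
    background <- runif(1, 0.25, 0.75)
    amplitude <- runif(1, 0.25, 0.75)
    sep <- separation_L * radius
    mid <- c(runif(1, width / 4, 3 * width / 4),
             runif(1, height / 4, 3 * height / 4))
    theta <- runif(1, 0, pi)
    d <- sep / 2 * c(cos(theta), sin(theta))
    c1 <- mid - d
    c2 <- mid + d
    margin <- radius
    if (any(c(c1, c2) < margin) ||
        any(c(c1[1], c2[1]) > width - margin + 1) ||
        any(c(c1[2], c2[2]) > height - margin + 1))
      stop("separation pushes a particle outside the frame", call. = FALSE)
    s1 <- particle_spec("airy", radius = radius, center = c1,
                        amplitude = amplitude)
    s2 <- particle_spec("airy", radius = radius, center = c2,
                        amplitude = amplitude)
    pixels <- background +
      particle_intensity(s1, width, height) +
      particle_intensity(s2, width, height)
    scene <- new_scene_image(pixels, background = background, truth = s1,
                             extra = list(truth2 = s2,
                                          separation_L = separation_L))
    scene$initial_guess <- perturbed_guess(c1)
    if (is.finite(snr)) scene <- add_noise_to_snr(scene, snr)
    scene
  })
}

#' Simulate an image stack of one particle in motion
#'
#' Renders a fresh frame per time step with the particle's continuous center
#' following the supplied trajectory (no pixel resampling, so subpixel motion
#' is exact).  Used by the sinusoidal-amplitude and ROI-correlation
#' benchmark protocols.
#'
#' @param trajectory a data frame with columns `frame`, `x`, `y` (pixel
#'   positions of the particle center per frame).
#' @param radius particle radius in pixels.
#' @param pattern pattern family, see [particle_spec()].
#' @param width,height frame size.
#' @param background uniform background intensity.
#' @param amplitude intensity amplitude.
#' @param snr per-frame target SNR, or `Inf` for noiseless frames.
#' @param seed integer master seed (one sub-seed per frame).
#' @return a list of `scene_image` frames, in `frame` order.
#' @export
make_motion_stack <- function(trajectory, radius, pattern = "rings",
                              width = 64L, height = 64L, background = 0.5,
                              amplitude = 0.5, snr = Inf, seed = NULL) {
  stopifnot(is.data.frame(trajectory),
            all(c("frame", "x", "y") %in% names(trajectory)))
  trajectory <- trajectory[order(trajectory$frame), ]
  seeds <- if (is.finite(snr)) derive_seeds(seed, nrow(trajectory)) else NULL
  purrr::map(seq_len(nrow(trajectory)), function(i) {
    spec <- particle_spec(pattern, radius = radius,
                          center = c(trajectory$x[i], trajectory$y[i]),
                          amplitude = amplitude)
    scene <- render_particle(spec, width, height, background)
    scene$initial_guess <- round(c(x = trajectory$x[i], y = trajectory$y[i]))
    if (is.finite(snr)) scene <- add_noise_to_snr(scene, snr, seed = seeds[i])
    scene
  })
}

#' Ground-truth table for a set of trials
#'
#' Collects the per-trial ground truth and generator metadata into the tidy
#' sidecar schema written next to exported image stacks.
#'
#' @param scenes a list of `scene_image` objects.
#' @param seeds optional integer vector of the per-trial seeds.
#' @return a tibble with columns `trial_id`, `pattern`, `radius`, `snr`,
#'   `seed`, `truth_x`, `truth_y`, `guess_x`, `guess_y`, `background`,
#'   `sigma`.
#' @export
ground_truth_table <- function(scenes, seeds = NULL) {
  stopifnot(is.list(scenes))
  purrr::imap_dfr(scenes, function(s, i) {
    tibble(trial_id = as.integer(i),
           pattern = s$truth$pattern,
           radius = s$truth$radius,
           snr = s$target_snr,
           seed = if (is.null(seeds)) NA_integer_ else as.integer(seeds[i]),
           truth_x = s$truth$center[["x"]],
           truth_y = s$truth$center[["y"]],
           guess_x = if (is.null(s$initial_guess)) NA_real_ else s$initial_guess[["x"]],
           guess_y = if (is.null(s$initial_guess)) NA_real_ else s$initial_guess[["y"]],
           background = s$background,
           sigma = s$noise_sigma)
  })
}
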