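loc_error <- function(loc, truth) {
  if (!isTRUE(loc$converged) || !is.finite(loc$x) || !is.finite(loc$y))
    return(NA_real_)
  sqrt((loc$x - truth[["x"]])^2 + (loc$y - truth[["y"]])^2)
}

#' Accuracy/precision grid over particle radius and SNR
#'
#' The central benchmark protocol: for every `(radius, snr)` cell it
#' generates `n_trials` seeded randomized trials ([make_trial()]), runs each
#' requested locator with ROI = 1.2 x the particle's nominal extent, and
#' accumulates the Euclidean distance between estimate and ground truth.
#' Accuracy is the per-cell mean error and precision its standard deviation.
#' Trials are shared across methods within a cell, so method comparisons are
#' paired; localization failures are excluded from the mean but counted.
#' The full run is reproducible from `seed`.
#'
#' The reference study design is 1000 trials per cell over radii 10-100 px
#' (10 steps) and SNR 0.1-100 (11 steps); the defaults here are a desk-scale
#' subset.
#'
#' @param radii particle radii (px) to test.
#' @param snrs SNR levels to test (may include `Inf` for noiseless).
#' @param n_trials trials per cell.
#' @param methods character vector of locator names (and/or plug-in
#'   functions in a list), see [locate_particle()].
#' @param seed master seed.
#' @param pattern pattern family for the trials.
#' @param ... further arguments passed to every locator.
#' @return a tibble with one row per `(method, radius, snr)`:
#'   `mean_error`, `sd_error`, `n` (converged trials), `failures`.
#' @export
run_grid <- function(radii, snrs, n_trials = 200L, methods = "csym",
                     seed = 1L, pattern = "rings", ...) {
  cells <- tidyr::expand_grid(radius = radii, snr = snrs)
  seeds <- matrix(derive_seeds(seed, nrow(cells) * n_trials),
                  nrow = nrow(cells))
  purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    radius <- cells$radius[ci]; snr <- cells$snr[ci]
    errs <- matrix(NA_real_, n_trials, length(methods))
    for (t in seq_len(n_trials)) {
      scene <- make_trial(radius, snr, pattern = pattern,
                          seed = seeds[ci, t])
      for (m in seq_along(methods)) {
        loc <- locate_particle(scene, methods[[m]], ...)
        errs[t, m] <- loc_error(loc, scene$truth$center)
      }
    }
    purrr::map_dfr(seq_along(methods), function(m) {
      e <- errs[, m]
      tibble(method = if (is.function(methods[[m]])) "plugin"
                      else methods[[m]],
             radius = radius, snr = snr,
             mean_error = mean(e, na.rm = TRUE),
             sd_error = sd(e, na.rm = TRUE),
             n = sum(!is.na(e)), failures = sum(is.na(e)))
    })
  }) |> structure(class = c("csym_grid", "tbl_df", "tbl", "data.frame"))
}

#' Accuracy grid for overlapping particle pairs
#'
#' As [run_grid()], but each trial contains two identical interfering
#' diffraction patterns ([make_pair_trial()]) separated by a multiple of the
#' Rayleigh limit L; the error is measured for the targeted (first) particle
#' of the pair.
#'
#' @param separations_L center separations in multiples of L (typically
#'   1 to 3).
#' @param snrs SNR levels.
#' @param n_trials trials per cell.
#' @param methods locators to compare.
#' @param seed master seed.
#' @param radius particle radius (= L) in pixels.
#' @param ... passed to the locators.
#' @return a tibble with one row per `(method, separation_L, snr)` plus the
#'   same error columns as [run_grid()].
#' @export
run_overlap_grid <- function(separations_L, snrs, n_trials = 200L,
                             methods = "csym", seed = 1L, radius = 20,
                             ...) {
  cells <- tidyr::expand_grid(separation_L = separations_L, snr = snrs)
  seeds <- matrix(derive_seeds(seed, nrow(cells) * n_trials),
                  nrow = nrow(cells))
  purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    sepL <- cells$separation_L[ci]; snr <- cells$snr[ci]
    errs <- matrix(NA_real_, n_trials, length(methods))
    for (t in seq_len(n_trials)) {
      scene <- make_pair_trial(radius, sepL, snr, seed = seeds[ci, t])
      for (m in seq_along(methods)) {
        loc <- locate_particle(scene, methods[[m]], ...)
        errs[t, m] <- loc_error(loc, scene$truth$center)
      }
    }
    purrr::map_dfr(seq_along(methods), function(m) {
      e <- errs[, m]
      tibble(method = if (is.function(methods[[m]])) "plugin"
                      else methods[[m]],
             separation_L = sepL, radius = radius, snr = snr,
             mean_error = mean(e, na.rm = TRUE),
             sd_error = sd(e, na.rm = TRUE),
             n = sum(!is.na(e)), failures = sum(is.na(e)))
    })
  }) |> structure(class = c("csym_grid", "tbl_df", "tbl", "data.frame"))
}

#' Consecutive-ROI correlation series of a tracked stack
#'
#' A model-free robustness metric for tracking without ground truth: locate
#' the particle in every frame, cut a fixed-size ROI centered on the rounded
#' detected position, and Pearson-correlate each ROI with the next frame's.
#' A locator that keeps the particle centered yields correlations near 1;
#' jitter in the detected positions decorrelates consecutive ROIs.  With
#' `snr` set, calibrated noise is injected per frame, localization runs on
#' the noisy frame, and the ROI is cut from the original clean frame at the
#' detected position — isolating the effect of noise on localization from
#' the effect of noise on the correlation itself.
#'
#' @param frames list of `scene_image` frames (e.g. [make_motion_stack()]).
#' @param method locator, see [locate_particle()].
#' @param roi_size odd ROI side for both localization and correlation;
#'   defaults from the first frame's truth.
#' @param snr optional injected SNR per frame.
#' @param seed master seed for the injected noise.
#' @param ... passed to the locator.
#' @return a tibble with columns `frame`, `correlation` (between ROI of
#'   `frame` and `frame + 1`; `NA` and `missing = TRUE` where localization
#'   failed), `converged`.
#' @export
roi_correlation_series <- function(frames, method = "csym", roi_size = NULL,
                                   snr = NULL, seed = NULL, ...) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  if (is.null(roi_size))
    roi_size <- default_roi_size(frames[[1]]$truth)
  seeds <- if (!is.null(snr)) derive_seeds(seed, length(frames)) else NULL
  rois <- vector("list", length(frames))
  conv <- logical(length(frames))
  for (i in seq_along(frames)) {
    clean <- frames[[i]]
    target <- if (is.null(snr)) clean
              else add_noise_to_snr(clean, snr, seed = seeds[i])
    loc <- locate_particle(target, method, ...)
    conv[i] <- isTRUE(loc$converged) && is.finite(loc$x) && is.finite(loc$y)
    if (conv[i]) {
      cr <- tryCatch(crop_roi(clean$pixels, c(loc$x, loc$y), roi_size),
                     error = function(e) NULL)
      if (!is.null(cr)) rois[[i]] <- cr$roi else conv[i] <- FALSE
    }
  }
  n <- length(frames) - 1L
  corr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (conv[i] && conv[i + 1] &&
        all(dim(rois[[i]]) == dim(rois[[i + 1]])))
      corr[i] <- cor(as.vector(rois[[i]]), as.vector(rois[[i + 1]]))
  }
  tibble(frame = seq_len(n), correlation = corr,
         converged = conv[seq_len(n)] & conv[seq_len(n) + 1L])
}
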