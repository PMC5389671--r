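#' Correlation maps over a search area
#'
#' For every integer candidate `(x, y)` in a square search area centered on
#' the initial estimate, builds the four mirror templates
#' (see [extract_templates()]) and computes
#' `Corr_X(x, y) = cor(T_L, T_R)` (vertical symmetry) and
#' `Corr_Y(x, y) = cor(T_T, T_B)` (horizontal symmetry), using the sample
#' Pearson correlation so every entry lies in `[-1, 1]`.  A candidate whose
#' ROI would exit the image is dropped by clamping the candidate rectangle
#' (border policy: no padding, which would inject artificial symmetry);
#' degenerate candidates (a zero-variance template, e.g. flat background)
#' get correlation 0 and are flagged.
#'
#' @param image numeric matrix or `scene_image`.
#' @param center integer `(x, y)` center of the search area (the initial
#'   position estimate).
#' @param n odd template side (ROI size) in pixels.
#' @param half_width half-width of the square search area in pixels; the
#'   candidate grid is `(2 * half_width + 1)^2` points before clamping.
#' @return an object of class `csym_maps`: list with matrices `corr_x`,
#'   `corr_y` (rows indexed by candidate `ys`, columns by candidate `xs`),
#'   the candidate coordinates `xs`, `ys`, and a logical `degenerate` matrix.
#' @export
correlation_maps <- function(image, center, n, half_width = 3L) {
  px <- scene_pixels(image)
  n <- as.integer(n)
  if (n %% 2L == 0L) stop("`n` must be odd", call. = FALSE)
  half_width <- as.integer(half_width)
  stopifnot(half_width >= 1L)
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  h <- (n - 1L) %/% 2L
  xs <- (cx - half_width):(cx + half_width)
  ys <- (cy - half_width):(cy + half_width)
  xs <- xs[xs - h >= 1L & xs + h <= ncol(px)]
  ys <- ys[ys - h >= 1L & ys + h <= nrow(px)]
  if (length(xs) == 0L || length(ys) == 0L)
    stop("no candidate ROI fits inside the image (ROI side ", n, ")",
         call. = FALSE)
  corr_x <- matrix(NA_real_, length(ys), length(xs))
  corr_y <- matrix(NA_real_, length(ys), length(xs))
  degen <- matrix(FALSE, length(ys), length(xs))
  for (j in seq_along(xs)) {
    for (i in seq_along(ys)) {
      tq <- extract_templates(px, xs[j], ys[i], n)
      vx <- template_correlation(tq$T_L, tq$T_R)
      vy <- template_correlation(tq$T_T, tq$T_B)
      if ((sd(tq$T_L) == 0 || sd(tq$T_R) == 0) ||
          (sd(tq$T_T) == 0 || sd(tq$T_B) == 0)) degen[i, j] <- TRUE
      corr_x[i, j] <- vx
      corr_y[i, j] <- vy
    }
  }
  structure(list(corr_x = corr_x, corr_y = corr_y,
                 xs = xs, ys = ys, degenerate = degen),
            class = "csym_maps")
}

#' Reduce correlation maps to one-dimensional symmetry profiles
#'
#' Applies the dimensional (average) filter: `Sym_X(x)` is the mean of
#' `Corr_X(x, y)` over all candidate rows `y`, and `Sym_Y(y)` the mean of
#' `Corr_Y(x, y)` over candidate columns.  Averaging across the orthogonal
#' axis suppresses noise in the individual correlations; the profile maximum
#' marks the axis of mirror symmetry, i.e. the particle center coordinate.
#'
#' @param maps a `csym_maps` object from [correlation_maps()].
#' @return an object of class `csym_profiles`: list with numeric vectors
#'   `sym_x` (over candidate columns `xs`) and `sym_y` (over candidate rows
#'   `ys`).
#' @export
symmetry_profiles <- function(maps) {
  stopifnot(inherits(maps, "csym_maps"))
  structure(list(sym_x = colMeans(maps$corr_x),
                 sym_y = rowMeans(maps$corr_y),
                 xs = maps$xs, ys = maps$ys),
            class = "csym_profiles")
}

# Hermite slopes: three-point centered finite differences in the interior,
# one-sided differences at the ends.
hermite_slopes <- function(x, v) {
  k <- length(v)
  m <- numeric(k)
  m[1] <- (v[2] - v[1]) / (x[2] - x[1])
  m[k] <- (v[k] - v[k - 1]) / (x[k] - x[k - 1])
  if (k > 2) {
    i <- 2:(k - 1)
    m[i] <- (v[i + 1] - v[i - 1]) / (x[i + 1] - x[i - 1])
  }
  m
}

#' Piecewise cubic Hermite interpolation of a symmetry profile
#'
#' Interpolates the discrete profile with one cubic per knot interval,
#' \deqn{p_k(t) = (2t^3-3t^2+1)\,v_k + (t^3-2t^2+t)\,h m_k +
#'       (-2t^3+3t^2)\,v_{k+1} + (t^3-t^2)\,h m_{k+1},}
#' where \eqn{t \in [0,1]} is the normalized coordinate within the interval
#' of width \eqn{h} and \eqn{m_k} is the tangent slope at knot \eqn{k}
#' (centered finite differences in the interior, one-sided at the ends).
#' The resulting curve is C1-continuous and passes through every sample
#' exactly; it is evaluated on a dense grid of spacing `step`.
#'
#' With `monotone = TRUE` the slopes are instead limited Fritsch-Carlson
#' style (via [stats::splinefun()] `method = "monoH.FC"`), which preserves
#' local monotonicity at the cost of slightly blunted extrema.
#'
#' @param values numeric profile samples (length >= 3).
#' @param positions knot positions, strictly increasing; defaults to
#'   `seq_along(values)`.
#' @param step dense sampling interval in pixels (default 0.01).
#' @param monotone use monotonicity-limited slopes instead of centered
#'   differences.
#' @return an object of class `hermite_curve`: list with dense `x`, `y`, the
#'   knots (`knot_x`, `knot_y`) and slopes `m`.
#' @export
hermite_interpolate <- function(values, positions = seq_along(values),
                                step = 0.01, monotone = FALSE) {
  stopifnot(is.numeric(values), is.numeric(positions),
            length(values) == length(positions), step > 0)
  k <- length(values)
  if (k < 3) stop("profile must have at least 3 samples", call. = FALSE)
  if (any(diff(positions) <= 0))
    stop("`positions` must be strictly increasing", call. = FALSE)
  xd <- seq(positions[1], positions[k], by = step)
  if (xd[length(xd)] < positions[k]) xd <- c(xd, positions[k])
  if (monotone) {
    f <- splinefun(positions, values, method = "monoH.FC")
    return(structure(list(x = xd, y = f(xd), knot_x = positions,
                          knot_y = values, m = NULL),
                     class = "hermite_curve"))
  }
  m <- hermite_slopes(positions, values)
  idx <- pmin(findInterval(xd, positions), k - 1L)
  h <- positions[idx + 1L] - positions[idx]
  t <- (xd - positions[idx]) / h
  t2 <- t * t; t3 <- t2 * t
  yd <- (2 * t3 - 3 * t2 + 1) * values[idx] +
        (t3 - 2 * t2 + t) * h * m[idx] +
        (-2 * t3 + 3 * t2) * values[idx + 1L] +
        (t3 - t2) * h * m[idx + 1L]
  structure(list(x = xd, y = yd, knot_x = positions, knot_y = values, m = m),
            class = "hermite_curve")
}

# Least-squares quadratic q1 x^2 + q2 x + q3 through (xs, ys) via the
# Vandermonde design, solved about the window center for conditioning.
# Returns the vertex and the (centered) coefficients.
quad_vertex <- function(xs, ys) {
  x0 <- xs[ceiling(length(xs) / 2)]
  V <- cbind((xs - x0)^2, xs - x0, 1)
  q <- qr.solve(V, ys)
  list(center = x0 - q[2] / (2 * q[1]), q = unname(q), x0 = x0)
}

#' Refine a symmetry-profile peak to subpixel precision
#'
#' Locates the discrete maximum of the interpolated curve (or, with
#' `hermite = FALSE`, of the raw profile), then least-squares fits a
#' second-degree polynomial through a window of samples around it — 500
#' interpolated samples at 0.01 px spacing by default, or 5 discrete samples
#' in the non-interpolated variant — and returns the vertex
#' \eqn{c = -q_2 / (2 q_1)}.  Ties between equal discrete maxima are broken
#' toward the window center, then toward the smaller index.
#'
#' The fit is flagged not-converged when the discrete profile peak sits on
#' the search-area boundary (the true center then likely lies outside the
#' area), when the fitted parabola opens upward (`q1 >= 0`, no maximum), or
#' when the vertex falls outside the candidate range by more than 0.5 px.
#'
#' @param profile numeric symmetry-profile samples.
#' @param positions knot positions of the profile samples.
#' @param hermite interpolate with [hermite_interpolate()] before fitting.
#' @param step dense sampling interval (px) of the interpolated curve.
#' @param n_fit number of interpolated samples in the fitting window.
#' @param monotone passed to [hermite_interpolate()].
#' @return list with `center` (real px), `q` (quadratic coefficients about
#'   the window center), `peak_value`, `converged` flag, and the dense
#'   `curve` when interpolation is on.
#' @export
peak_refine <- function(profile, positions = seq_along(profile),
                        hermite = TRUE, step = 0.01, n_fit = 500L,
                        monotone = FALSE) {
  stopifnot(length(profile) >= 3)
  k_peak <- which(profile == max(profile))
  if (length(k_peak) > 1) {
    mid <- (length(profile) + 1) / 2
    k_peak <- k_peak[order(abs(k_peak - mid), k_peak)]
  }
  k_peak <- k_peak[1]
  on_boundary <- k_peak == 1L || k_peak == length(profile)
  if (hermite) {
    curve <- hermite_interpolate(profile, positions, step = step,
                                 monotone = monotone)
    # anchor the window at the discrete profile peak (its dense-grid index),
    # symmetric about it with n_fit/2 samples per side; prefer keeping the
    # window inside the interior knot intervals, since the one-sided slope
    # rule of the end intervals breaks the interpolant's symmetry and an
    # asymmetric window biases the vertex even on a symmetric peak
    i_peak <- which.min(abs(curve$x - positions[k_peak]))
    k <- length(positions)
    interior <- min(
      round((positions[k_peak] - positions[2]) / step),
      round((positions[k - 1] - positions[k_peak]) / step))
    half <- min(n_fit %/% 2L, i_peak - 1L, length(curve$x) - i_peak)
    if (interior >= max(2L, round(1 / step))) half <- min(half, interior)
    if (half < 2L)
      return(list(center = curve$x[i_peak], q = c(NA_real_, NA_real_, NA_real_),
                  peak_value = curve$y[i_peak], converged = FALSE,
                  curve = curve))
    win <- (i_peak - half):(i_peak + half)
    fit <- quad_vertex(curve$x[win], curve$y[win])
    peak_value <- curve$y[i_peak]
  } else {
    curve <- NULL
    half <- 2L
    win <- max(1L, k_peak - half):min(length(profile), k_peak + half)
    if (length(win) < 3)
      stop("profile too short for the 5-point quadratic fit", call. = FALSE)
    fit <- quad_vertex(positions[win], profile[win])
    peak_value <- profile[k_peak]
  }
  in_range <- is.finite(fit$center) &&
    fit$center >= positions[1] - 0.5 &&
    fit$center <= positions[length(positions)] + 0.5
  # q1 within rounding of zero means no usable curvature (e.g. flat profile)
  converged <- !on_boundary && fit$q[1] < -1e-12 && in_range
  list(center = fit$center, q = fit$q, peak_value = peak_value,
       converged = converged, curve = curve)
}

# Next odd integer >= 1.2 x the particle's nominal extent.
default_roi_size <- function(spec, factor = 1.2) {
  n <- ceiling(factor * particle_extent(spec))
  as.integer(if (n %% 2 == 0) n + 1 else n)
}

#' Locate a particle center by circular symmetry (C-Sym)
#'
#' Runs the full C-Sym pipeline: mirror-template extraction over the search
#' area, normalized correlation maps, dimensional filtering to the symmetry
#' profiles `Sym_X` / `Sym_Y`, piecewise cubic Hermite interpolation at
#' 0.01 px resolution, and quadratic peak refinement — independently for the
#' X and Y axes.  The method uses only the spatial symmetry of the intensity
#' pattern, so it is invariant to affine intensity changes (background level,
#' contrast, polarity) and needs no model of the particle profile.  The
#' pipeline contains no randomness.
#'
#' @param image numeric matrix or `scene_image`.
#' @param guess integer `(x, y)` initial estimate of the center; defaults to
#'   the scene's recorded `initial_guess`.
#' @param roi_size odd ROI side in pixels, or `NULL` to use 1.2 times the
#'   particle's nominal extent (rounded up to odd) when `image` is a scene
#'   with known truth.
#' @param search_half_width half-width of the candidate search area (default
#'   3 px, covering the up-to-2-px initial-guess error with margin).
#' @param hermite set `FALSE` to skip Hermite interpolation and fit the
#'   quadratic to 5 discrete profile samples instead (ablation variant).
#' @param step,n_fit,monotone peak-refinement controls, see [peak_refine()].
#' @return an object of class `csym_loc` (inherits `particle_loc`): fields
#'   `x`, `y`, `converged`, `peak_corr_x`, `peak_corr_y`, per-axis quadratic
#'   coefficients, the `profiles` and dense `curves`, and `method = "csym"`.
#' @examples
#' sp <- particle_spec("gaussian", radius = 8, center = c(32.0, 31.0))
#' sc <- render_particle(sp, 64, 64, background = 0.3)
#' loc <- locate_csym(sc, guess = c(33, 30))
#' c(loc$x, loc$y)  # recovers (32, 31) to sub-millipixel accuracy
#' @export
locate_csym <- function(image, guess = NULL, roi_size = NULL,
                        search_half_width = 3L, hermite = TRUE,
                        step = 0.01, n_fit = 500L, monotone = FALSE) {
  if (is.null(guess) && inherits(image, "scene_image"))
    guess <- image$initial_guess
  if (is.null(guess)) stop("`guess` is required", call. = FALSE)
  if (is.null(roi_size)) {
    if (!inherits(image, "scene_image"))
      stop("`roi_size` is required for a bare image", call. = FALSE)
    roi_size <- default_roi_size(image$truth)
  }
  maps <- correlation_maps(image, guess, n = roi_size,
                           half_width = search_half_width)
  prof <- symmetry_profiles(maps)
  rx <- peak_refine(prof$sym_x, prof$xs, hermite = hermite, step = step,
                    n_fit = n_fit, monotone = monotone)
  ry <- peak_refine(prof$sym_y, prof$ys, hermite = hermite, step = step,
                    n_fit = n_fit, monotone = monotone)
  structure(
    list(x = rx$center, y = ry$center,
         converged = rx$converged && ry$converged,
         peak_corr_x = rx$peak_value, peak_corr_y = ry$peak_value,
         quad_x = rx$q, quad_y = ry$q,
         profiles = prof, curves = list(x = rx$curve, y = ry$curve),
         roi_size = as.integer(roi_size), method = "csym"),
    class = c("csym_loc", "particle_loc"))
}

#' @export
print.particle_loc <- function(x, ...) {
  cat(sprintf("<%s> center (%.4f, %.4f)%s\n", x$method, x$x, x$y,
              if (isTRUE(x$converged)) "" else "  [not converged]"))
  invisible(x)
}

#' @rdname locate_csym
#' @param x a `particle_loc` object.
#' @param ... unused.
#' @return `tidy()` returns a one-row tibble with `method`, `x`, `y`,
#'   `converged` and the peak correlations (when available).
#' @method tidy particle_loc
#' @export
tidy.particle_loc <- function(x, ...) {
  loc <- x
  tibble(method = loc$method, x = loc$x, y = loc$y,
         converged = loc$converged,
         peak_corr_x = if (is.null(loc$peak_corr_x)) NA_real_
                       else loc$peak_corr_x,
         peak_corr_y = if (is.null(loc$peak_corr_y)) NA_real_
                       else loc$peak_corr_y)
}
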