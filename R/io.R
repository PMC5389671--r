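#' Read an image or image stack as float matrices
#'
#' Reads a (multi-page) TIFF or a PNG into a list of numeric matrices in
#' `[0, 1]`-scaled float form: integer samples are divided by their dtype
#' maximum (so 8-bit 255 reads as 1.0, stable across frames), while float
#' samples pass through untouched.  Color images are converted to grayscale
#' by channel averaging.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return a list of numeric matrices, one per frame, in page order.
#' @export
read_image_stack <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    a
  }
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    lapply(frames, to_gray)
  } else if (ext == "png") {
    list(to_gray(png::readPNG(path)))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

#' Write frames as a 32-bit TIFF stack
#'
#' Writes one or more numeric matrices to a single (multi-page) TIFF with
#' 32-bit samples; values in `[0, 1]` round-trip to within one part in
#' \eqn{2^{31}}.  Because noisy scenes are unclipped floats, a stack with
#' values outside `[0, 1]` is first mapped linearly onto `[0, 1]`; the
#' applied mapping (`offset`, `scale`, with original = offset + scale *
#' stored) is returned so callers can record it in a sidecar and undo it
#' after reading.
#'
#' @param frames a numeric matrix, a `scene_image`, or a list of either.
#' @param path output path.
#' @return invisibly, a list with `path`, `offset` and `scale`.
#' @export
write_image_stack <- function(frames, path) {
  if (is.matrix(frames) || inherits(frames, "scene_image"))
    frames <- list(frames)
  frames <- lapply(frames, scene_pixels)
  rng <- range(unlist(lapply(frames, range)))
  offset <- 0; scale <- 1
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.eps)
    frames <- lapply(frames, function(m) (m - offset) / scale)
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(list(path = path, offset = offset, scale = scale))
}

#' Write a results table to CSV
#'
#' Deterministic CSV export of a benchmark or localization table: columns in
#' their existing order, rows in their existing order, full double precision
#' (15 significant digits).  An empty table produces a header-only file.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run configuration files
#'
#' A `run_config` bundles everything needed to reproduce a run: locator
#' method, ROI policy, search half-width, interpolation switch, master seed,
#' grid definition and I/O paths.  Configurations round-trip losslessly
#' through YAML.
#'
#' @param method locator name.
#' @param roi_size odd ROI side (px) or `NULL` for the 1.2x-extent policy.
#' @param search_half_width search-area half-width (px).
#' @param hermite logical, Hermite interpolation on/off.
#' @param seed integer master seed.
#' @param radii,snrs grid definition for benchmark runs.
#' @param n_trials trials per grid cell.
#' @param input,output optional I/O paths.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(method = "csym", roi_size = NULL,
                       search_half_width = 3L, hermite = TRUE, seed = 1L,
                       radii = c(10, 50, 100), snrs = c(0.1, 1, 10, 100),
                       n_trials = 200L, input = NULL, output = NULL) {
  structure(list(method = method, roi_size = roi_size,
                 search_half_width = as.integer(search_half_width),
                 hermite = isTRUE(hermite), seed = as.integer(seed),
                 radii = as.numeric(radii), snrs = as.numeric(snrs),
                 n_trials = as.integer(n_trials),
                 input = input, output = output),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
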